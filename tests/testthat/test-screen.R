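test_that("log2 CPM normalisation matches hand computation", {
  counts <- tibble::tibble(gene = c("g1", "g2"),
                           s1 = c(10, 90), s2 = c(20, 80))
  out <- normalize_log2(counts)
  expect_equal(out$s1, log2(1e6 * c(10, 90) / 100 + 1))
  expect_equal(out$s2, log2(1e6 * c(20, 80) / 100 + 1))
  # zero count maps to log2(pseudocount) = 0
  z <- normalize_log2(tibble::tibble(gene = c("g1", "g2"),
                                     s1 = c(0, 100), s2 = c(5, 95)))
  expect_equal(z$s1[1], 0)
  expect_error(normalize_log2(tibble::tibble(gene = "g", s1 = 0)), "library")
})

test_that("F-test matches the frozen two-group example and lm oracle", {
  expr <- tibble::tibble(gene = "g1", a1 = 1, a2 = 2, a3 = 3,
                         b1 = 4, b2 = 5, b3 = 6)
  groups <- setNames(rep(c("a", "b"), each = 3), names(expr)[-1])
  de <- differential_f_test(expr, groups)
  expect_equal(de$f_statistic, 13.5, tolerance = 1e-9)
  expect_equal(de$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(de$log2_fc, 3)

  # random 3-group data against anova(lm()) per gene
  set.seed(17)
  x <- matrix(rnorm(20 * 9), 20)
  colnames(x) <- paste0("s", 1:9)
  g <- rep(c("u", "v", "w"), each = 3)
  expr_r <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:20)),
                             tibble::as_tibble(x))
  de_r <- differential_f_test(expr_r, setNames(g, colnames(x)))
  oracle <- t(apply(x, 1, function(y) {
    a <- stats::anova(stats::lm(y ~ factor(g)))
    c(a$`F value`[1], a$`Pr(>F)`[1])
  }))
  expect_equal(de_r$f_statistic, oracle[, 1], tolerance = 1e-9)
  expect_equal(de_r$p_value, oracle[, 2], tolerance = 1e-9)

  # permuting samples within groups leaves statistics unchanged
  perm <- expr_r[c("gene", "s2", "s3", "s1", "s6", "s4", "s5", "s9", "s7", "s8")]
  de_p <- differential_f_test(perm, setNames(g, names(perm)[-1]))
  expect_equal(de_p$f_statistic, de_r$f_statistic, tolerance = 1e-12)
})

test_that("degenerate genes and undersized groups are handled", {
  expr <- tibble::tibble(gene = "flat", a1 = 2, a2 = 2, b1 = 2, b2 = 2)
  groups <- setNames(c("a", "a", "b", "b"), names(expr)[-1])
  de <- differential_f_test(expr, groups)
  expect_true(de$degenerate)
  expect_true(is.na(de$f_statistic))
  expect_equal(de$p_value, 1)
  expect_error(
    differential_f_test(expr, setNames(c("a", "b", "b", "b"), names(expr)[-1])),
    ">= 2 samples")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.32), 0.32)      # m = 1: adjusted = raw
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing along sorted raw p, never below raw
  set.seed(18)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
})

test_that("candidate filter returns exactly the planted pass set", {
  fx <- simulate_screen_fixture(n_pass = 5, n_fail = 95, seed = 1)
  de <- differential_f_test(fx$expr, fx$groups)
  screened <- screen_candidates(de, fx$go)
  expect_setequal(screened$gene[screened$pass], fx$truth_pass)
  # removing any one predicate yields a superset
  for (flag in c("pass_fc", "pass_q", "pass_go", "pass_expr")) {
    others <- setdiff(c("pass_fc", "pass_q", "pass_go", "pass_expr"), flag)
    relaxed <- screened$gene[Reduce(`&`, screened[others])]
    expect_true(all(screened$gene[screened$pass] %in% relaxed))
    expect_gte(length(relaxed), sum(screened$pass))
  }
})

test_that("fold-change boundary is strict and empty GO map empties the list", {
  de <- tibble::tibble(gene = c("exact", "above"),
                       mean_a = c(5, 5), mean_b = c(8, 8.5),
                       log2_fc = c(3, 3.5),
                       f_statistic = c(100, 100), p_value = c(1e-6, 1e-6),
                       degenerate = FALSE)
  go <- tibble::tibble(gene = c("exact", "above"), term = "GO:0009986")
  screened <- screen_candidates(de, go)
  expect_false(screened$pass[screened$gene == "exact"])
  expect_true(screened$pass[screened$gene == "above"])
  none <- screen_candidates(de, tibble::tibble(gene = character(0),
                                               term = character(0)))
  expect_equal(sum(none$pass), 0)
})

test_that("signature scores are z-normalised and find the planted naive stage", {
  panel_genes <- sprintf("gene_%03d", 181:190)
  panels <- list(naive = list(
    genes = 181:190,
    stage_effects = c(A = 0, B = 0, C = 3, D = 0, E = 0, F = 0, G = 0)))
  sim <- simulate_expression(expression_sim_config(
    n_genes = 400, signature_panels = panels, seed = 19))
  sc <- signature_score(sim$log2, sim$samples, panel_genes, subset = "Vg1.1")
  expect_equal(sc$population[which.max(sc$score)], "C")
  z <- attr(sc, "gene_z")
  per_gene <- z |>
    dplyr::group_by(gene) |>
    dplyr::summarise(m = mean(z), s = sd(z))
  expect_true(all(abs(per_gene$m) < 1e-12))
  expect_true(all(abs(per_gene$s - 1) < 1e-9))

  one <- signature_score(sim$log2, sim$samples, panel_genes[1],
                         subset = "Vg1.1")
  gz <- attr(one, "gene_z")
  expect_equal(one$score, gz$z[match(one$population, gz$population)])
})
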