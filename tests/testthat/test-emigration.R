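test_that("fold changes are exact ratios with replicate averaging", {
  counts <- tibble::tibble(
    stage = rep(c("C", "D"), each = 3),
    group = rep(c("untreated", "FTY720_5d", "FTY720_10d"), 2),
    count = c(10, 33, 100, 50, 75, 80))
  folds <- fold_changes(counts)
  expect_equal(folds$fold[folds$stage == "C" & folds$group == "FTY720_10d"], 10)
  expect_equal(folds$fold[folds$stage == "C" & folds$group == "untreated"], 1)
  expect_equal(folds$fold[folds$stage == "D" & folds$group == "FTY720_5d"], 1.5)

  # replicate rows are averaged before ratios
  reps <- tibble::tibble(stage = "C", group = rep(c("untreated", "t"), each = 2),
                         replicate = c(1, 2, 1, 2), count = c(8, 12, 30, 50))
  f <- fold_changes(reps)
  expect_equal(f$fold[f$group == "t"], 4)

  zero <- tibble::tibble(stage = "C", group = c("untreated", "t"),
                         count = c(0, 5))
  expect_error(fold_changes(zero), "pseudocount")
})

test_that("fold changes are scale-equivariant within a group", {
  counts <- tibble::tibble(stage = rep(gd_stages(), 2),
                           group = rep(c("untreated", "t"), each = 7),
                           count = c(rep(10, 7), 7:1 * 10))
  f1 <- fold_changes(counts)
  counts2 <- dplyr::mutate(counts,
                           count = ifelse(group == "t", count * 3, count))
  f2 <- fold_changes(counts2)
  expect_equal(f2$fold[f2$group == "t"], f1$fold[f1$group == "t"] * 3)
})

test_that("terminal calling separates sustained from stalled accumulation", {
  folds <- tibble::tibble(
    stage = rep(c("C", "D", "E", "F", "G"), each = 2),
    group = rep(c("FTY720_5d", "FTY720_10d"), 5),
    count = 0,
    fold = c(3.3, 10, 1.5, 1.6, 2.5, 5, 1.4, 1.8, 3.3, 10))
  called <- call_terminal_stages(folds)
  expect_setequal(terminal_stages(called), c("C", "E", "G"))

  flat <- dplyr::mutate(folds, fold = 1)
  expect_equal(length(terminal_stages(call_terminal_stages(flat))), 0)
  degenerate <- call_terminal_stages(folds, min_fold = 0,
                                     min_growth_ratio = 0)
  expect_setequal(terminal_stages(degenerate), c("C", "D", "E", "F", "G"))
})

test_that("terminal calling is monotone in both thresholds", {
  folds <- tibble::tibble(
    stage = rep(gd_stages(), each = 2),
    group = rep(c("FTY720_5d", "FTY720_10d"), 7),
    count = 0,
    fold = c(1, 1, 1.2, 2, 3.3, 10, 1.5, 1.6, 2.5, 5, 1.4, 1.8, 3.3, 10))
  base <- terminal_stages(call_terminal_stages(folds))
  for (mf in c(2, 4, 8)) {
    for (gr in c(1.2, 2, 3)) {
      got <- terminal_stages(call_terminal_stages(folds, min_fold = mf,
                                                  min_growth_ratio = gr))
      if (mf >= 3 && gr >= 1.5) expect_true(all(got %in% base))
    }
  }
  expect_warning(
    called <- call_terminal_stages(dplyr::filter(folds,
                                                 group == "FTY720_10d")),
    "skipped")
  expect_true(attr(called, "ratio_skipped"))
})

test_that("planted accumulation on C, E, G is recovered end to end", {
  ev <- small_events(n = 10000, seed = 22,
                     treatment = blockade_treatment_effects())
  staged <- assign_stages(ev, fit_positivity_thresholds(ev, "valley"))
  comp <- stage_composition(staged, by = "meta_group", as = "count")
  folds <- fold_changes(dplyr::rename(comp, group = "meta_group"),
                        count_col = "n")
  expect_setequal(terminal_stages(call_terminal_stages(folds)),
                  c("C", "E", "G"))
  # planted folds recovered within Poisson sampling error (+-15%)
  f10 <- folds[folds$group == "FTY720_10d", ]
  planted <- blockade_treatment_effects()$FTY720_10d
  expect_true(all(abs(f10$fold / planted[f10$stage] - 1) < 0.15))
})

test_that("Student t test matches closed-form values and symmetries", {
  res <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)

  swap <- student_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p_value, res$p_value)

  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  paired <- student_t_test(c(1, 2, 3), c(2, 3, 5), paired = TRUE)
  expect_equal(paired$df, 2)
  expect_error(student_t_test(c(1, 2), c(1, 2, 3), paired = TRUE), "equal-length")
  expect_error(student_t_test(c(2, 2, 2), c(2, 2, 2)), "pooled variance")
  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("two-group F equals squared equal-variance t across modules", {
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5, mean = 1)
    expr <- dplyr::bind_cols(tibble::tibble(gene = "g"),
                             tibble::as_tibble(matrix(c(a, b), nrow = 1,
                                                      dimnames = list(NULL, paste0("s", 1:9)))))
    groups <- setNames(rep(c("a", "b"), c(4, 5)), paste0("s", 1:9))
    f <- differential_f_test(expr, groups)$f_statistic
    t <- student_t_test(a, b)$t
    expect_equal(f, t^2, tolerance = 1e-9)
  }
})
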