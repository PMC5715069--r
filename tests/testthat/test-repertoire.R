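test_that("clonotype TSV round trip and validation", {
  sim <- simulate_clonotypes(repertoire_sim_config(total_reads = 800, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotypes(sim$table, path)
  back <- read_clonotypes(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$table),
               ignore_attr = TRUE)

  # inconsistent freq column triggers recomputation with a warning
  bad <- sim$table
  bad$freq[1] <- bad$freq[1] + 0.01
  write_clonotypes(bad, path)
  expect_warning(fixed <- read_clonotypes(path), "recomputed")
  expect_equal(fixed$freq, fixed$count / sum(fixed$count))

  noaa <- dplyr::select(sim$table, -cdr3aa)
  write_clonotypes(noaa, path)
  expect_error(read_clonotypes(path), "cdr3aa")
})

test_that("frame filtering removes stops, frameshifts and off-frame lengths", {
  tbl <- tibble::tibble(
    count = c(5, 3, 2, 1),
    freq = c(5, 3, 2, 1) / 11,
    cdr3nt = c(strrep("ACG", 4), strrep("ACG", 5), strrep("ACG", 4),
               paste0(strrep("ACG", 4), "A")),
    cdr3aa = c("CALDF", "CAL*W", "CGGGF", "CALD_"),
    v = "TRDV5", d = "TRDD1", j = "TRDJ1")
  kept <- filter_in_frame(tbl)
  expect_equal(kept$cdr3aa, c("CALDF", "CGGGF"))
  expect_equal(sum(kept$freq), 1)

  clean <- simulate_clonotypes(repertoire_sim_config(
    out_of_frame_fraction = 0, total_reads = 500, seed = 8))$table
  expect_equal(nrow(filter_in_frame(clean)), nrow(clean))

  planted <- simulate_clonotypes(repertoire_sim_config(
    out_of_frame_fraction = 0.3, total_reads = 10000, seed = 9))$table
  removed <- 1 - sum(filter_in_frame(planted)$count) / sum(planted$count)
  expect_lt(abs(removed - 0.3), 0.014)   # 3 binomial SE

  allbad <- tbl[2, ]
  expect_warning(empty <- filter_in_frame(allbad), "no in-frame")
  expect_equal(nrow(empty), 0)
})

test_that("downsampling hits the target exactly and is unbiased", {
  sim <- simulate_clonotypes(repertoire_sim_config(total_reads = 2000,
                                                   seed = 10))
  down <- downsample_reads(sim$table, 1200, seed = 1)
  expect_equal(sum(down$count), 1200)
  expect_true(all(down$count >= 1))
  expect_identical(downsample_reads(sim$table, 1200, seed = 1), down)
  expect_identical(downsample_reads(sim$table, sum(sim$table$count)),
                   sim$table)
  expect_error(downsample_reads(sim$table, 5000), "below the target")

  # a 50% clone keeps its expected share: mean over 200 seeds within 0.01
  toy <- tibble::tibble(count = c(500, 300, 200), freq = c(0.5, 0.3, 0.2),
                        cdr3nt = c("AAA", "CCC", "GGG"),
                        cdr3aa = c("K", "P", "G"), v = "V1", d = "D1", j = "J1")
  fr <- vapply(1:200, function(s) {
    d <- downsample_reads(toy, 100, seed = s)
    sum(d$count[d$cdr3nt == "AAA"]) / 100
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.01)
})

test_that("downsampling matches an explicit expand-and-shuffle oracle", {
  # distribution check on a 3-clone toy: chi-square GoF of clone-1 counts
  # against the exact hypergeometric pmf, over 1000 seeds
  toy <- tibble::tibble(count = c(6, 3, 3), freq = c(0.5, 0.25, 0.25),
                        cdr3nt = c("AAA", "CCC", "GGG"),
                        cdr3aa = c("K", "P", "G"), v = "V1", d = "D1", j = "J1")
  draws <- vapply(1:1000, function(s) {
    sum(downsample_reads(toy, 6, seed = s)$count[toy$cdr3nt == "AAA"])
  }, numeric(1))
  observed <- tabulate(draws + 1, 7)
  expected <- stats::dhyper(0:6, 6, 6, 6) * 1000
  keep <- expected > 1
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi2, stats::qchisq(0.999, sum(keep) - 1))
})

test_that("motif fractions are exact arithmetic with regex matching", {
  tbl <- tibble::tibble(count = c(3, 4, 3), freq = c(0.3, 0.4, 0.3),
                        cdr3nt = strrep("ACG", 5:7),
                        cdr3aa = c("CALWELGF", "CGGGDTF", "CXXWELYF"),
                        v = "V1", d = "D1", j = "J1")
  expect_equal(motif_fraction(tbl, "WEL"), 0.6)
  expect_equal(motif_fraction(tbl, "wel"), 0.6)   # case-insensitive
  expect_equal(motif_fraction(tbl, "^CAL.*F$"), 0.3)
  expect_equal(motif_fraction(tbl, "ZZZZ"), 0)
  expect_error(motif_fraction(tbl, "(unclosed"), "invalid motif")
  mf <- motif_fractions(tbl, c(a = "WEL", b = "ZZZZ"))
  expect_equal(mf$fraction, c(0.6, 0))
})

test_that("segment usage conserves reads and sums to one", {
  tbl <- tibble::tibble(count = c(6, 4), freq = c(0.6, 0.4),
                        cdr3nt = c("AAA", "CCC"), cdr3aa = c("K", "P"),
                        v = c("TRDV4", "TRDV4"), d = "D1",
                        j = c("TRDJ1", "TRDJ2"))
  expect_equal(segment_usage(tbl, "v")$fraction, 1)
  ju <- segment_usage(tbl, "j")
  expect_equal(sum(ju$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(ju$reads), 10)
})

test_that("inverse Simpson equals brute force and is maximal when uniform", {
  uniform <- tibble::tibble(count = rep(3, 9))
  expect_equal(inverse_simpson(uniform), 9, tolerance = 1e-12)
  expect_equal(inverse_simpson(tibble::tibble(count = c(2, 1, 1))), 1 / 0.375,
               tolerance = 1e-12)
  expect_equal(inverse_simpson(tibble::tibble(count = 7)), 1)
  expect_error(inverse_simpson(tibble::tibble(count = integer(0))), "empty")

  # exhaustive search over all compositions of n <= 8 reads into <= 4 clones
  for (n in 3:8) {
    for (k in 2:min(4, n - 1)) {
      parts <- expand.grid(rep(list(1:n), k))
      parts <- parts[rowSums(parts) == n, , drop = FALSE]
      d_max <- max(apply(parts, 1, function(cc) {
        inverse_simpson(tibble::tibble(count = cc))
      }))
      d_uniform <- inverse_simpson(tibble::tibble(count = rep(n / k, k)))
      expect_lte(d_max, d_uniform + 1e-9)
      if (n %% k == 0) expect_equal(d_max, d_uniform, tolerance = 1e-9)
    }
  }
})

test_that("oligoclonal libraries score lower diversity than polyclonal ones", {
  oligo <- simulate_clonotypes(repertoire_sim_config(
    n_clones = 50, clone_size_law = 2.5, total_reads = 2000, seed = 11))
  poly <- simulate_clonotypes(repertoire_sim_config(
    n_clones = 50, clone_size_law = 0.1, total_reads = 2000, seed = 11))
  expect_lt(inverse_simpson(filter_in_frame(oligo$table)),
            inverse_simpson(filter_in_frame(poly$table)))
})
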