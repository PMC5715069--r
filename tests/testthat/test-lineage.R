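test_that("distance matrix reproduces hand values and the brute-force oracle", {
  # identical profiles and a 3-4-5 triangle
  expr <- tibble::tibble(gene = c("g1", "g2"),
                         s1 = c(0, 3), s2 = c(0, 3), s3 = c(4, 0))
  samples <- tibble::tibble(sample = c("s1", "s2", "s3"), subset = "Vg1.1",
                            stage = c("A", "B", "C"), replicate = 1)
  dm <- distance_matrix(expr, samples)
  expect_equal(dm["A", "B"], 0)
  expect_equal(dm["A", "C"], 5)
  expect_equal(diag(unclass(dm)), setNames(rep(0, 3), c("A", "B", "C")))

  # random 7 x 500 matrix against an explicit pairwise loop
  set.seed(14)
  profiles <- matrix(rnorm(7 * 500), 7, dimnames = list(gd_stages(), NULL))
  expr_r <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%03d", 1:500)),
    tibble::as_tibble(t(profiles), .name_repair = ~ paste0("s", 1:7)))
  samples_r <- tibble::tibble(sample = paste0("s", 1:7), subset = "Vg1.1",
                              stage = gd_stages(), replicate = 1)
  dm_r <- distance_matrix(expr_r, samples_r)
  oracle <- brute_force_distances(profiles)
  expect_lt(max(abs(unclass(dm_r) - oracle)), 1e-9)
  expect_lt(max(abs(unclass(dm_r) - t(unclass(dm_r)))), 1e-12)
})

test_that("distances are invariant to gene and sample order; exclusions apply", {
  sim <- simulate_expression(expression_sim_config(n_genes = 200, seed = 5))
  dm <- distance_matrix(sim$log2, sim$samples, subset = "Vg2")
  perm_genes <- sim$log2[sample(nrow(sim$log2)), ]
  perm_samples <- sim$samples[sample(nrow(sim$samples)), ]
  dm_perm <- distance_matrix(perm_genes, perm_samples, subset = "Vg2")
  expect_equal(unclass(dm), unclass(dm_perm)[rownames(dm), colnames(dm)],
               tolerance = 1e-9, ignore_attr = TRUE)

  excl <- sim$log2$gene[1:50]
  dm_ex <- distance_matrix(sim$log2, sim$samples, subset = "Vg2",
                           exclude_genes = excl)
  expect_false(isTRUE(all.equal(unclass(dm), unclass(dm_ex))))
})

test_that("MST matches brute force on 3 nodes and the Prufer oracle on 7", {
  d3 <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  g3 <- build_lineage_graph(d3, method = "mst")
  expect_setequal(edge_key(g3$edges), c("A B", "B C"))
  expect_equal(sum(g3$edges$weight), 3)

  set.seed(15)
  for (rep in 1:3) {
    pts <- matrix(rnorm(7 * 4), 7, dimnames = list(gd_stages(), NULL))
    dm <- brute_force_distances(pts)
    mst <- build_lineage_graph(dm, method = "mst")
    oracle <- brute_force_mst_weight(dm)
    expect_equal(sum(mst$edges$weight), oracle$weight, tolerance = 1e-9)
    expect_setequal(edge_key(mst$edges), edge_key(oracle$edges))
  }
})

test_that("chain-structured distances give a path with exactly 2 leaves", {
  pos <- setNames(1:7, gd_stages())
  dm <- abs(outer(pos, pos, "-"))
  g <- build_lineage_graph(dm, method = "mst")
  expect_equal(sort(g$leaves), c("A", "G"))
  expect_equal(length(g$branch_points), 0)
  expect_equal(nrow(g$edges), 6)
})

test_that("MST annotates leaves and branch points of the designed tree", {
  sim <- simulate_expression(expression_sim_config(seed = 8))
  dm <- distance_matrix(sim$log2, sim$samples, subset = "Vg1.1")
  g <- build_lineage_graph(dm)
  expect_setequal(g$leaves, c("A", "C", "E", "G"))
  expect_setequal(g$branch_points, c("B", "F"))
  expect_error(build_lineage_graph(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("knn graph connects each node to its nearest neighbours", {
  pos <- setNames(c(1, 2, 3, 10, 11, 12, 30), gd_stages())
  dm <- abs(outer(pos, pos, "-"))
  g <- build_lineage_graph(dm, method = "knn", k = 1)
  expect_true("A B" %in% edge_key(g$edges))   # symmetrised union
  expect_true(all(g$degrees >= 1))
})

test_that("population PCA is centred, ordered and reconstructive", {
  # exact line in gene space: PC1 carries all variance
  t_par <- seq(-3, 3, length.out = 8)
  line <- outer(c(1, 2, -1, 0.5), t_par)       # genes x samples
  expr <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:4)),
                           tibble::as_tibble(line, .name_repair = ~ paste0("s", 1:8)))
  samples <- tibble::tibble(sample = paste0("s", 1:8), subset = "Vg1.1",
                            stage = c(gd_stages(), "A"), replicate = 1)
  fit <- pca_populations(expr, samples, n_components = 2)
  expect_equal(fit$explained_variance[1], 1, tolerance = 1e-9)
  expect_equal(mean(fit$scores$PC1), 0, tolerance = 1e-12)

  # reconstruction with all components reproduces the centred data
  set.seed(16)
  x <- matrix(rnorm(6 * 10), 10)                # genes x samples -> 6 samples
  expr2 <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:10)),
                            tibble::as_tibble(x, .name_repair = ~ paste0("s", 1:6)))
  samples2 <- tibble::tibble(sample = paste0("s", 1:6), subset = "Vg1.1",
                             stage = gd_stages()[1:6], replicate = 1)
  fit2 <- pca_populations(expr2, samples2, n_components = 6)
  centred <- scale(t(x), scale = FALSE)
  scores <- as.matrix(fit2$scores[paste0("PC", 1:ncol(fit2$rotation))])
  recon <- scores %*% t(fit2$rotation)
  expect_lt(max(abs(recon - centred)), 1e-8)

  const <- expr2
  const[paste0("s", 1:6)] <- 1
  expect_error(pca_populations(const, samples2), "constant")
})
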