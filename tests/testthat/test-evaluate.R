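test_that("holdout folds are an exact stratified partition", {
  # a gene with 10 non-zero spots splits into five folds of two
  counts <- matrix(0, 12, 3)
  counts[1:10, 1] <- 5
  counts[1:12, 2] <- 3
  counts[1:5, 3] <- 2                   # expressed in 41% < 50% -> excluded
  d <- STData(counts, data.frame(x = rep(1:4, 3), y = rep(1:3, each = 4)))
  f <- make_holdout_folds(d, seed = 2)
  expect_equal(f$eligible_genes, c(1L, 2L))
  g1_sizes <- vapply(f$folds, function(m) sum(m[, 2] == 1), integer(1))
  expect_equal(g1_sizes, rep(2L, 5))

  all_idx <- do.call(rbind, f$folds)
  expect_equal(nrow(all_idx), 10 + 12)
  expect_equal(anyDuplicated(all_idx), 0)
  # union equals the non-zero entries of eligible genes
  expect_true(all(d$counts[all_idx] > 0))
  expect_equal(nrow(all_idx), sum(d$counts[, 1:2] > 0))

  # per-gene fold sizes differ by at most one on a random fixture
  fx <- small_fixture()
  ff <- make_holdout_folds(fx$data, seed = 3)
  for (g in sample(ff$eligible_genes, 10)) {
    sz <- vapply(ff$folds, function(m) sum(m[, 2] == g), integer(1))
    expect_lte(diff(range(sz)), 1)
  }
  # determinism
  ff2 <- make_holdout_folds(fx$data, seed = 3)
  expect_identical(ff$folds, ff2$folds)

  expect_error(make_holdout_folds(
    STData(diag(4), data.frame(x = rep(1:2, 2), y = rep(1:2, each = 2)))),
    "no gene")
})

test_that("apply_holdout masks exactly one fold", {
  fx <- small_fixture()
  f <- make_holdout_folds(fx$data, seed = 4)
  h <- apply_holdout(fx$data, f, 2)
  idx <- f$folds[[2]]
  expect_true(all(h$counts[idx] == 0))
  rest <- h$counts
  rest[idx] <- fx$data$counts[idx]      # restore from truth
  expect_identical(rest, fx$data$counts)
})

test_that("rmse, pcc and spearman match their formulas", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(pcc(1:5, 1:5), 1)
  expect_equal(pcc(c(3, 2, 1), c(1, 2, 3)), -1)
  expect_equal(rmse(c(3, 2, 1), c(1, 2, 3)), sqrt(8 / 3))

  set.seed(17)
  x <- rnorm(100); y <- x * 0.5 + rnorm(100)
  expect_equal(rmse(x, y), sqrt(sum((x - y)^2) / 100), tolerance = 1e-12)
  expect_equal(pcc(x, y),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  sp <- spearman(x, y)
  rx <- rank(x); ry <- rank(y)
  d2 <- sum((rx - ry)^2)
  expect_equal(sp$rho, 1 - 6 * d2 / (100 * (100^2 - 1)), tolerance = 1e-12)
  tstat <- sp$rho * sqrt(98 / (1 - sp$rho^2))
  expect_equal(sp$p_value, 2 * pt(-abs(tstat), 98), tolerance = 1e-12)

  expect_error(pcc(rep(1, 5), 1:5), "constant")
  expect_error(spearman(rep(1, 5), 1:5), "constant")

  # scale equivariance / invariance
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y), tolerance = 1e-12)
  expect_equal(pcc(2 * x + 5, y), pcc(x, y), tolerance = 1e-12)
  expect_equal(spearman(2 * x + 5, y)$rho, spearman(x, y)$rho,
               tolerance = 1e-12)
})

test_that("silhouette scores match a brute-force double loop", {
  set.seed(18)
  pcs <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 12), 20, 2))
  labels <- rep(1:2, each = 20)
  coords <- data.frame(x = c(1:20, 101:120), y = rep(1, 40))
  a <- structure(list(labels = labels, regions = list(1:20, 21:40)),
                 class = "RegionAssignment")
  emb <- structure(list(pcs = pcs, p = 2), class = "Embedding")
  s <- silhouette_scores(a, emb, coords)
  expect_gt(s$TSC, 0.8)                  # well-separated clouds
  expect_equal(s$TSC, brute_silhouette(pcs, labels), tolerance = 1e-10)
  expect_equal(s$SSC, brute_silhouette(as.matrix(coords), labels),
               tolerance = 1e-10)
  expect_equal(s$CSC, s$TSC + s$SSC)
  expect_true(abs(s$TSC) <= 1 && abs(s$SSC) <= 1)

  # pairwise label swaps reduce the transcriptomic score
  lab2 <- labels
  swap <- c(1, 3, 5, 7)
  lab2[swap] <- 2; lab2[swap + 20] <- 1
  a2 <- structure(list(labels = lab2,
                       regions = split(seq_len(40), lab2)),
                  class = "RegionAssignment")
  s2 <- silhouette_scores(a2, emb, coords)
  expect_lt(s2$TSC, s$TSC)

  # isolated spots are excluded from scoring
  lab3 <- labels; lab3[1:5] <- NA
  a3 <- structure(list(labels = lab3,
                       regions = list(6:20, 21:40)),
                  class = "RegionAssignment")
  s3 <- silhouette_scores(a3, emb, coords)
  expect_equal(s3$TSC, brute_silhouette(pcs[-(1:5), ], labels[-(1:5)]),
               tolerance = 1e-10)

  a1 <- structure(list(labels = rep(1L, 40), regions = list(1:40)),
                  class = "RegionAssignment")
  expect_error(silhouette_scores(a1, emb, coords), ">= 2 regions")
})

test_that("adjusted Rand index matches pair counting", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 7, 7)), 1)
  # one-cluster labeling vs a balanced split is chance level
  expect_equal(adjusted_rand_index(rep(1, 8), rep(1:2, each = 4)), 0)
  set.seed(19)
  for (rep in 1:5) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_ari(a, b),
                 tolerance = 1e-10)
  }
})

test_that("per-gene recovery reports sparsity and correlation", {
  set.seed(20)
  ref <- matrix(rexp(200) + 1, 20, 10)
  obs <- ref * (matrix(runif(200), 20, 10) > 0.3)
  den <- ref + matrix(rnorm(200, sd = 0.01), 20, 10)
  rep <- per_gene_recovery(den, ref, obs)
  expect_equal(nrow(rep), 10)
  expect_equal(rep$sparsity, colMeans(obs == 0))
  expect_true(all(rep$spearman_rho > 0.9))
})

test_that("denoising improves per-gene Spearman recovery of held-out values", {
  fx <- small_fixture()
  f <- make_holdout_folds(fx$data, seed = 6)
  held <- apply_holdout(fx$data, f, 1)
  a <- detect_regions(held)
  res <- suppressWarnings(impute_mist(held, a, k = 2, rng_seed = 6))
  # reference is the dense pre-dropout truth on the CPM scale: in this
  # world every zero of the observed data is a dropout to be repaired
  dense <- fx$sim$truth$dense_expr
  ref <- dense * 1e6 / rowSums(dense)
  before <- per_gene_recovery(held$counts, ref, held$counts)
  after <- per_gene_recovery(res$denoised, ref, held$counts)
  expect_gte(median(after$spearman_rho, na.rm = TRUE),
             median(before$spearman_rho, na.rm = TRUE))
})

test_that("benchmark_holdout reports per-fold metrics and per-gene RMSE", {
  fx <- small_fixture()
  f <- make_holdout_folds(fx$data, n_folds = 2, seed = 8)
  b <- suppressWarnings(
    benchmark_holdout(fx$data, f, k = 1, n_extra = 10, rng_seed = 8))
  expect_equal(nrow(b), 4)              # 2 folds x 2 methods
  expect_true(all(b$rmse[b$method == "mist"] < b$rmse[b$method == "spknn"]))
  pg <- attr(b, "per_gene")
  expect_s3_class(pg, "data.frame")
  expect_true(all(pg$rmse >= 0))
  expect_true(all(pg$gene %in% fx$data$gene_ids))
  expect_true(is.factor(pg$sparsity_bin))
})
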