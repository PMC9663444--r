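test_that("select_hvg ranks by dispersion and honours the fraction", {
  fx <- small_fixture()
  expect_equal(length(select_hvg(fx$data, 1)), ncol(fx$data$counts))
  set.seed(8)
  counts <- cbind(matrix(rexp(40, 1 / 100) + 1, 10, 4), rep(7, 10))
  d <- STData(counts, data.frame(x = rep(1:5, 2), y = rep(1:2, each = 5)))
  expect_equal(length(select_hvg(d, 0.8)), 4)   # 5 genes -> ceil(4)
  # the constant gene has zero dispersion and ranks last
  expect_equal(select_hvg(d, 1)[5], 5L)
  expect_error(select_hvg(d, 0), "fraction")
  expect_error(select_hvg(d, 1.2), "fraction")
})

test_that("embed_pca is exact on low rank input and deterministic", {
  set.seed(9)
  U <- exp(matrix(rnorm(30 * 2), 30, 2))
  V <- exp(matrix(rnorm(8 * 2), 8, 2))
  x <- U %*% t(V)                      # positive, exactly rank 2
  x <- x * 1e6 / rowSums(x)            # row scaling preserves the rank
  d <- STData(x, data.frame(x = rep(1:6, 5), y = rep(1:5, each = 6)),
              normalized = TRUE)
  emb <- embed_pca(d, p = 8, log1p = FALSE)
  recon <- emb$pcs[, 1:8] %*% t(emb$rotation[, 1:8])
  recon <- sweep(recon, 2, emb$center, `+`)
  expect_equal(recon, unname(x), tolerance = 1e-8)
  expect_true(all(diff(emb$sdev) <= 1e-12))

  emb2 <- embed_pca(d, p = 8, log1p = FALSE)
  expect_identical(emb$pcs, emb2$pcs)
  expect_error(embed_pca(d, p = 50), "exceeds")

  # default p is 30 when the data allow it
  fx <- quadrant_fixture()
  expect_equal(embed_pca(fx$data, select_hvg(fx$data))$p, 30)
})

test_that("build_weighted_graph builds lattice edges with correlation weights", {
  coords <- expand.grid(x = 1:3, y = 1:3)
  d <- STData(matrix(1:81, 9, 9), coords)
  set.seed(1)
  emb <- structure(list(pcs = matrix(rnorm(9 * 4), 9, 4), p = 4),
                   class = "Embedding")
  g <- build_weighted_graph(d, emb, "square4")
  expect_equal(nrow(g$edges), 12)      # 2*r*c - r - c for r = c = 3
  # weights equal cor() of the PC rows
  for (e in seq_len(nrow(g$edges)))
    expect_equal(g$weights[e],
                 cor(emb$pcs[g$edges[e, 1], ], emb$pcs[g$edges[e, 2], ]),
                 tolerance = 1e-12)

  emb$pcs[2, ] <- emb$pcs[1, ]                 # identical vectors
  emb$pcs[4, ] <- c(1, 0, -1, 0)
  emb$pcs[5, ] <- c(-1, 0, 1, 0)               # perfectly anti-correlated
  g <- build_weighted_graph(d, emb, "square4")
  w12 <- g$weights[g$edges[, 1] == 1 & g$edges[, 2] == 2]
  w45 <- g$weights[g$edges[, 1] == 4 & g$edges[, 2] == 5]
  expect_equal(w12, 1)
  expect_equal(w45, -1)

  emb$pcs[3, ] <- 5                            # zero variance row
  expect_warning(g <- build_weighted_graph(d, emb, "square4"),
                 "zero-variance")
  expect_true(all(g$weights[g$edges[, 1] == 3 | g$edges[, 2] == 3] == 0))
})

test_that("prune_and_components matches a union-find oracle", {
  # planted two-block fixture: strong within-block, weak across
  coords <- expand.grid(x = 1:6, y = 1:4)
  block <- ifelse(coords$x <= 3, 1, 2)
  edges <- NULL; w <- NULL
  for (i in seq_len(23)) for (j in (i + 1):24) {
    adjacent <- abs(coords$x[i] - coords$x[j]) +
      abs(coords$y[i] - coords$y[j]) == 1
    if (adjacent) {
      edges <- rbind(edges, c(i, j))
      w <- c(w, if (block[i] == block[j]) 0.9 else 0.1)
    }
  }
  g <- manual_graph(24, edges, w)
  a <- prune_and_components(g, 0.5, q = 3)
  expect_equal(length(a$regions), 2)
  expect_equal(sort(lengths(a$regions)), c(12, 12))
  expect_equal(as.vector(tapply(block, a$labels,
                              function(b) length(unique(b)))), c(1, 1))

  # oracle agreement on random graphs at random thresholds
  set.seed(21)
  for (rep in 1:5) {
    wr <- runif(nrow(edges), -1, 1)
    gr <- manual_graph(24, edges, wr)
    eps <- runif(1, -0.5, 0.8)
    ar <- prune_and_components(gr, eps, q = 1)
    keep <- edges[wr >= eps, , drop = FALSE]
    comp <- uf_components(24, keep)
    # same partition (up to labels): every detected region is one component
    for (reg in ar$regions)
      expect_equal(length(unique(comp[reg])), 1)
    sizes <- table(comp)
    expect_equal(sort(lengths(ar$regions)),
                 sort(unname(as.integer(sizes[sizes > 1]))))
  }

  # full pruning and no pruning
  a_hi <- prune_and_components(g, 0.95, q = 1)
  expect_equal(length(a_hi$regions), 0)
  expect_true(all(is.na(a_hi$labels)))
  a_lo <- prune_and_components(g, 0.05, q = 3)
  expect_equal(length(a_lo$regions), 1)
  expect_equal(lengths(a_lo$regions), 24)
})

test_that("pruning is monotone in the threshold", {
  fx <- small_fixture()
  emb <- embed_pca(fx$data, select_hvg(fx$data),
                   p = min(30, nrow(fx$data$counts)))
  g <- build_weighted_graph(fx$data, emb, "square4")
  prev_edges <- Inf; prev_comp <- 0
  for (eps in seq(0.1, 0.9, by = 0.1)) {
    ne <- sum(g$weights >= eps)
    a <- prune_and_components(g, eps, q = 1)
    ncomp <- length(a$regions) + sum(is.na(a$labels))
    expect_lte(ne, prev_edges)
    expect_gte(ncomp, prev_comp)
    prev_edges <- ne; prev_comp <- ncomp
  }
})

test_that("region_objective matches closed form and brute force", {
  # two regions with intra-correlation 1, cross-correlation -1, full
  # coverage: objective = 1 - (-1) + sigma * 1 = 2.1
  v <- c(1, 0, -1, 0.5)
  pcs <- rbind(v, v, v, -v, -v, -v)
  a <- structure(list(labels = c(1L, 1L, 1L, 2L, 2L, 2L),
                      regions = list(1:3, 4:6)),
                 class = "RegionAssignment")
  emb <- structure(list(pcs = pcs, p = 4), class = "Embedding")
  expect_equal(region_objective(a, emb, sigma = 0.1), 2.1, tolerance = 1e-12)
  # sigma enters through the coverage term only; full coverage adds sigma
  expect_equal(region_objective(a, emb, sigma = 0) + 0.25,
               region_objective(a, emb, sigma = 0.25), tolerance = 1e-12)

  set.seed(31)
  pcs <- matrix(rnorm(30 * 6), 30, 6)
  regions <- list(1:11, 12:20, 21:26)   # spots 27:30 isolated
  labels <- rep(NA_integer_, 30)
  for (k in 1:3) labels[regions[[k]]] <- k
  a <- structure(list(labels = labels, regions = regions),
                 class = "RegionAssignment")
  emb <- structure(list(pcs = pcs, p = 6), class = "Embedding")
  expect_equal(region_objective(a, emb, 0.1),
               brute_objective(regions, pcs, 0.1), tolerance = 1e-10)

  # invariance to region relabeling and spot order permutation
  perm <- sample(30)
  inv <- integer(30); inv[perm] <- seq_len(30)
  a2 <- structure(list(labels = labels[perm],
                       regions = lapply(rev(regions), function(r) inv[r])),
                  class = "RegionAssignment")
  emb2 <- structure(list(pcs = pcs[perm, ], p = 6), class = "Embedding")
  expect_equal(region_objective(a2, emb2, 0.1), region_objective(a, emb, 0.1),
               tolerance = 1e-12)

  # zero regions -> -Inf sentinel
  a0 <- structure(list(labels = rep(NA_integer_, 30), regions = list()),
                  class = "RegionAssignment")
  expect_identical(region_objective(a0, emb, 0.1), -Inf)
})

test_that("detect_regions recovers planted quadrants and is self-consistent", {
  fx <- quadrant_fixture()
  a <- detect_regions(fx$data)
  expect_equal(a$q, 20L)               # < 500 spots -> q = 20
  expect_gte(length(a$regions), 2)

  # returned objective equals a recomputation on the returned assignment
  expect_equal(a$objective, region_objective(a, a$embedding, a$sigma),
               tolerance = 1e-12)

  # assigned non-boundary spots recover the planted partition
  tr <- fx$sim$truth
  sel <- !is.na(a$labels) & !tr$boundary
  expect_gte(adjusted_rand_index(a$labels[sel], tr$region_labels[sel]), 0.9)

  # q = 40 branch for slides with >= 500 spots
  big <- cached("big500", {
    sim <- generate_synthetic_st(rows = 23, cols = 23, n_genes = 120,
                                 seed = 6)
    normalize_cpm(sim$data)
  })
  a2 <- detect_regions(big)
  expect_equal(a2$q, 40L)

  # no detectable region -> informative failure
  set.seed(2)
  noise <- matrix(rexp(64 * 40) + 0.1, 64, 40)
  dn <- normalize_cpm(STData(noise, expand.grid(x = 1:8, y = 1:8)))
  expect_error(detect_regions(dn, grid = c(0.95, 0.99), q = 60),
               "no threshold produced a region")
})

test_that("region export writes CSV plus JSON sidecar", {
  fx <- quadrant_fixture()
  a <- detect_regions(fx$data)
  p <- file.path(withr::local_tempdir(), "regions.csv")
  write_regions(a, fx$data, p)
  tab <- read.csv(p)
  expect_equal(nrow(tab), nrow(fx$data$counts))
  expect_true(all(c("spot_id", "x", "y", "region_label") %in% colnames(tab)))
  expect_equal(sum(tab$region_label == "ISOLATED"), sum(is.na(a$labels)))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", p))
  expect_equal(side$epsilon, a$threshold)
  expect_equal(side$q, a$q)
})
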