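#' Per-gene stratified holdout folds
#'
#' Genes expressed in at least `min_frac` of the spots are eligible; each
#' eligible gene's non-zero entries are randomly partitioned into
#' `n_folds` groups whose sizes differ by at most one.
#'
#' @param data an [STData] (normally CPM-normalized).
#' @param n_folds number of folds (default 5).
#' @param min_frac minimum fraction of spots a gene must be expressed in
#'   (default 0.5).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list of class `HoldoutFolds`: `folds` (list of `n_folds`
#'   two-column index matrices, columns spot/gene), `eligible_genes`
#'   (column indices), `n_folds`, `seed`.
#' @export
make_holdout_folds <- function(data, n_folds = 5, min_frac = 0.5, seed = 1) {
  stopifnot(inherits(data, "STData"), n_folds >= 2)
  M <- nrow(data$counts)
  eligible <- unname(which(colSums(data$counts > 0) >= min_frac * M))
  if (length(eligible) == 0)
    stop("make_holdout_folds: no gene expressed in >= ",
         min_frac * 100, "% of spots")
  folds <- replicate(n_folds, vector("list", length(eligible)),
                     simplify = FALSE)
  with_seed(seed, function() {
    for (gi in seq_along(eligible)) {
      g <- eligible[gi]
      idx <- which(data$counts[, g] > 0)
      perm <- sample(idx)
      fid <- rep(seq_len(n_folds), length.out = length(perm))
      for (f in seq_len(n_folds)) {
        sel <- perm[fid == f]
        folds[[f]][[gi]] <<- cbind(sel, rep.int(g, length(sel)))
      }
    }
  })
  folds <- lapply(folds, function(l) do.call(rbind, l))
  structure(list(folds = folds, eligible_genes = eligible,
                 n_folds = n_folds, seed = seed),
            class = "HoldoutFolds")
}

#' Mask one holdout fold
#'
#' Returns a copy of the data with the fold's entries set to zero (the
#' imputers treat zeros as missing); all other entries are untouched.
#'
#' @param data the [STData] the folds were built on.
#' @param folds a [HoldoutFolds][make_holdout_folds()].
#' @param fold_id which fold to mask, in `1..n_folds`.
#' @return the masked [STData].
#' @export
apply_holdout <- function(data, folds, fold_id) {
  stopifnot(inherits(folds, "HoldoutFolds"),
            fold_id >= 1, fold_id <= folds$n_folds)
  data$counts[folds$folds[[fold_id]]] <- 0
  data
}

#' Root-mean-square error
#'
#' `sqrt(mean((x - y)^2))`.
#'
#' @param estimates,truth numeric vectors of equal length.
#' @return numeric scalar.
#' @export
rmse <- function(estimates, truth) {
  stopifnot(length(estimates) == length(truth), length(truth) >= 1)
  sqrt(mean((estimates - truth)^2))
}

#' Pearson correlation coefficient
#'
#' @param estimates,truth numeric vectors of equal length (>= 2,
#'   non-constant).
#' @return numeric scalar.
#' @export
pcc <- function(estimates, truth) {
  stopifnot(length(estimates) == length(truth), length(truth) >= 2)
  if (sd(estimates) == 0 || sd(truth) == 0)
    stop("pcc: undefined for constant input")
  cor(estimates, truth)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of the ranks; the p-value comes from the
#' standard t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom (two-sided).
#'
#' @param estimates,truth numeric vectors of equal length (>= 3,
#'   non-constant).
#' @return list with `rho` and `p_value`.
#' @export
spearman <- function(estimates, truth) {
  stopifnot(length(estimates) == length(truth), length(truth) >= 3)
  if (sd(estimates) == 0 || sd(truth) == 0)
    stop("spearman: undefined for constant input")
  rho <- cor(rank(estimates), rank(truth))
  n <- length(truth)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

# Mean silhouette width for a labelled feature matrix, Euclidean distance.
# Singleton clusters score 0.
silhouette_mean <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  labs <- unique(labels)
  if (length(labs) < 2) stop("silhouette: need >= 2 clusters")
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (n_own - 1)
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette scores of a region assignment
#'
#' TSC is the mean silhouette width of the region labels in PC space, SSC
#' the same in (x, y) coordinate space, and CSC their sum.  Isolated spots
#' have no cluster membership and are excluded.  Euclidean distance is
#' used for both.
#'
#' @param assignment a `RegionAssignment` with at least two regions.
#' @param emb the `Embedding` used for detection.
#' @param coords data.frame of spot coordinates (columns `x`, `y`).
#' @return list with `TSC`, `SSC`, `CSC`.
#' @export
silhouette_scores <- function(assignment, emb, coords) {
  keep <- !is.na(assignment$labels)
  labels <- assignment$labels[keep]
  if (length(unique(labels)) < 2)
    stop("silhouette_scores: need >= 2 regions")
  tsc <- silhouette_mean(emb$pcs[keep, , drop = FALSE], labels)
  ssc <- silhouette_mean(as.matrix(coords[keep, c("x", "y")]), labels)
  list(TSC = tsc, SSC = ssc, CSC = tsc + ssc)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return numeric scalar (1 for identical partitions, ~0 at chance).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)     # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Holdout benchmark of the ensemble imputer against spKNN
#'
#' For each fold: mask the fold, re-detect regions on the masked data,
#' impute with the mini-batch ensemble and with the spatial-neighbour
#' baseline, and score recovery of the held-out values.
#'
#' @param data a normalized [STData].
#' @param folds a [HoldoutFolds][make_holdout_folds()] built on `data`.
#' @param layout lattice adjacency convention.
#' @param k,n_extra,rng_seed ensemble controls, see [impute_mist()].
#' @param q,p,sigma detection controls, see [detect_regions()].
#' @param methods character subset of `c("mist", "spknn", "global")`;
#'   `"global"` is a single whole-matrix completion without mini-batches.
#' @return data.frame with one row per (fold, method): `rmse`, `pcc`,
#'   `spearman_rho`, `n` (held-out entries).
#' @export
benchmark_holdout <- function(data, folds, layout = c("square4", "hex6"),
                              k = 5, n_extra = NULL, rng_seed = 1,
                              q = NULL, p = 30, sigma = 0.1,
                              methods = c("mist", "spknn")) {
  layout <- match.arg(layout)
  methods <- match.arg(methods, c("mist", "spknn", "global"),
                       several.ok = TRUE)
  rows <- list()
  gene_sq <- gene_n <- setNames(numeric(ncol(data$counts)), data$gene_ids)
  for (f in seq_len(folds$n_folds)) {
    idx <- folds$folds[[f]]
    truth <- data$counts[idx]
    held <- apply_holdout(data, folds, f)
    assignment <- detect_regions(held, sigma = sigma, q = q, p = p,
                                 layout = layout)
    for (m in methods) {
      est_mat <- switch(m,
        mist = impute_mist(held, assignment, k = k, n_extra = n_extra,
                           rng_seed = rng_seed)$denoised,
        spknn = impute_spknn(held, assignment$graph),
        global = {
          fit <- cpp_svt_ladder(held$counts, (held$counts != 0) * 1L,
                                lam_final = -1, err_target = 1e-12,
                                alpha = 1, decfac = 0.7, tol_path = 1e-4,
                                tol_final = 1e-6, max_iter = 500,
                                lam_init = -1)
          pmax(fit$X, 0)
        })
      est <- est_mat[idx]
      if (m == "mist") {                # per-gene error ledger
        sq <- tapply((est - truth)^2, idx[, 2], sum)
        gi <- as.integer(names(sq))
        gene_sq[gi] <- gene_sq[gi] + sq
        gene_n[gi] <- gene_n[gi] + tabulate(idx[, 2], ncol(data$counts))[gi]
      }
      rows[[length(rows) + 1]] <- data.frame(
        fold = f, method = m, rmse = rmse(est, truth),
        pcc = pcc(est, truth), spearman_rho = spearman(est, truth)$rho,
        n = length(truth))
    }
  }
  out <- do.call(rbind, rows)
  if ("mist" %in% methods) {
    scored <- gene_n > 0
    sparsity <- colMeans(data$counts == 0)
    attr(out, "per_gene") <- data.frame(
      gene = data$gene_ids[scored],
      sparsity = sparsity[scored],
      sparsity_bin = cut(sparsity[scored], c(-Inf, .2, .3, .4, .5, .6, Inf),
                         labels = c("<=20%", "20-30%", "30-40%", "40-50%",
                                    "50-60%", ">60%")),
      rmse = sqrt(gene_sq[scored] / gene_n[scored]), row.names = NULL)
  }
  out
}

#' Per-gene recovery report
#'
#' Spearman correlation between denoised and reference values gene by
#' gene, plus each gene's observed sparsity, for before/after comparisons
#' of expression-pattern recovery.
#'
#' @param denoised,reference matrices of identical shape.
#' @param observed the matrix the imputer saw (defines sparsity).
#' @return data.frame with `gene`, `sparsity`, `spearman_rho`.
#' @export
per_gene_recovery <- function(denoised, reference, observed) {
  stopifnot(all(dim(denoised) == dim(reference)))
  res <- lapply(seq_len(ncol(reference)), function(g) {
    ref <- reference[, g]
    est <- denoised[, g]
    rho <- if (sd(ref) == 0 || sd(est) == 0) NA_real_ else
      spearman(est, ref)$rho
    data.frame(gene = g, sparsity = mean(observed[, g] == 0),
               spearman_rho = rho)
  })
  do.call(rbind, res)
}
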