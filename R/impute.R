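#' Nuclear-norm matrix completion by singular-value soft-thresholding
#'
#' Treats zeros of `Y` as missing and estimates them under a low-rank
#' assumption by minimizing `||P_obs(Y - X)||_F^2 + lambda * ||X||_nuc`.
#' Each iteration takes a data-consistency step
#' `B <- X + (1/alpha) * P_obs(Y - X)` and soft-thresholds the singular
#' values of `B` at `lambda / 2`; iteration stops when the relative
#' Frobenius change of `X` drops below `tol` or after `max_iter`
#' iterations.
#'
#' By default (`continuation = TRUE`) the solver descends a warm-started
#' geometric ladder of regularization strengths from `2 * sigma_max(Y)`
#' down to `lambda` (ratio `decfac`), which is how this family of
#' completion algorithms is run in practice: a cold start at a small
#' `lambda` stalls at the zero-filled matrix, while the warm-started path
#' tracks the low-rank solution.  `continuation = FALSE` runs the plain
#' fixed-`lambda` iteration from `X0`.
#'
#' @param Y numeric matrix; zeros are treated as missing.
#' @param lambda regularization strength (> 0).
#' @param alpha step-size parameter, >= 1 (the sampling projector has unit
#'   operator norm, so `alpha = 1` guarantees descent).
#' @param max_iter,tol stopping rule per ladder rung (defaults 500 and
#'   1e-6).
#' @param continuation use the warm-started ladder (default TRUE).
#' @param decfac ladder ratio (default 0.7).
#' @param tol_path relative-change tolerance for intermediate ladder rungs
#'   (the final rung always uses `tol`).
#' @param X0 optional start for `continuation = FALSE`.
#' @param trace with `continuation = FALSE`, record the objective value at
#'   every iteration (attribute `"objective"`).
#' @return the completed matrix, with attributes `"lambda"`, `"err"` (sum
#'   of absolute differences on observed entries), and `"iters"`.  Rows or
#'   columns of `Y` that contain no observed entry are returned as zeros,
#'   with a warning.
#' @export
svt_complete <- function(Y, lambda, alpha = 1, max_iter = 500, tol = 1e-6,
                         continuation = TRUE, decfac = 0.7,
                         tol_path = 1e-4, X0 = NULL, trace = FALSE) {
  Y <- as.matrix(Y)
  stopifnot(lambda > 0, alpha >= 1)
  obs <- Y != 0
  if (!any(obs)) stop("svt_complete: no observed entries")
  empty_row <- rowSums(obs) == 0
  empty_col <- colSums(obs) == 0
  if (any(empty_row) || any(empty_col))
    warning("svt_complete: fully unobserved row(s)/column(s) returned as zeros")
  if (continuation) {
    fit <- cpp_svt_ladder(Y, obs * 1L, lam_final = lambda, err_target = -1,
                          alpha = alpha, decfac = decfac,
                          tol_path = tol_path, tol_final = tol,
                          max_iter = max_iter, lam_init = -1)
  } else {
    sigma_ref <- svd(Y, nu = 0, nv = 0)$d[1]
    fit <- cpp_svt_fixed(Y, obs * 1L, lambda = lambda, alpha = alpha,
                         max_iter = max_iter, tol = tol, X0 = X0,
                         sigma_ref = sigma_ref, trace = trace)
    if (fit$iters >= max_iter)
      warning("svt_complete: not converged within max_iter; ",
              "returning last iterate")
  }
  X <- fit$X
  X[empty_row, ] <- 0
  X[, empty_col] <- 0
  dimnames(X) <- dimnames(Y)
  attr(X, "lambda") <- lambda
  attr(X, "err") <- fit$err
  attr(X, "iters") <- fit$iters
  if (trace && !continuation) attr(X, "objective") <- fit$objective
  X
}

#' Select the regularization strength by the observed-error rule
#'
#' Descends a warm-started geometric ladder of `lambda` values starting at
#' `2 * sigma_max` of the zero-filled `Y` (ratio `decfac`) and returns the
#' largest `lambda` whose converged solution has a sum of absolute
#' differences on observed entries at most `err_target`, refined by one
#' bisection step between the last failing and first passing rung.  Because
#' the observed-entry error of the converged solution shrinks with
#' `lambda` -- reaching zero exactly once the threshold falls below the
#' representable perturbation of the spectrum -- the ladder always
#' terminates; if no rung passes before the machine-precision floor the
#' smallest tested `lambda` is returned with a warning.
#'
#' @param Y numeric matrix; zeros are treated as missing.
#' @param err_target maximum tolerated observed-entry absolute error sum
#'   (default 1e-12).
#' @param alpha,tol,max_iter,decfac as in [svt_complete()].
#' @return the selected `lambda` (numeric scalar) with attributes `"err"`
#'   (its observed error) and `"sigma_max"`.
#' @export
select_lambda <- function(Y, err_target = 1e-12, alpha = 1, tol = 1e-6,
                          max_iter = 500, decfac = 0.7) {
  Y <- as.matrix(Y)
  obs <- Y != 0
  if (!any(obs)) stop("select_lambda: no observed entries")
  fit <- cpp_svt_ladder(Y, obs * 1L, lam_final = -1, err_target = err_target,
                        alpha = alpha, decfac = decfac, tol_path = 1e-4,
                        tol_final = tol, max_iter = max_iter, lam_init = -1)
  lam <- fit$lambda
  err <- fit$err
  if (err > err_target) {
    warning(sprintf(
      "select_lambda: no lambda reached err <= %g (best err %g at lambda %g)",
      err_target, err, lam))
    return(structure(lam, err = err, sigma_max = fit$sigma_max))
  }
  # candidates are validated through the same lam_final-mode ladder used
  # when replaying svt_complete(lambda), so the returned lambda is
  # guaranteed to reproduce err <= err_target
  replay <- function(l) {
    cpp_svt_ladder(Y, obs * 1L, lam_final = l, err_target = -1,
                   alpha = alpha, decfac = decfac, tol_path = 1e-4,
                   tol_final = tol, max_iter = max_iter, lam_init = -1)$err
  }
  nr <- length(fit$rung_lambda)
  cands <- fit$lambda
  if (nr >= 2)                          # one bisection step (geometric)
    cands <- c(sqrt(fit$lambda * fit$rung_lambda[nr - 1]), cands)
  for (cand in cands) {
    e <- replay(cand)
    if (e <= err_target)
      return(structure(cand, err = e, sigma_max = fit$sigma_max))
  }
  # rare: path sensitivity at the boundary; descend until the replay passes
  cand <- fit$lambda
  repeat {
    cand <- cand * decfac
    e <- replay(cand)
    if (e <= err_target || cand < 1e-3 * .Machine$double.eps * fit$sigma_max)
      return(structure(cand, err = e, sigma_max = fit$sigma_max))
  }
}

#' Build one region-centred mini-batch
#'
#' A batch holds every spot of the core region plus `floor(n_extra / 2)`
#' isolated spots and `ceiling(n_extra / 2)` spots drawn from the other
#' regions, both sampled without replacement (pools smaller than requested
#' are taken whole).
#'
#' @param assignment a `RegionAssignment`.
#' @param core region id to centre the batch on.
#' @param n_extra total number of extra spots to draw.
#' @param rng_seed optional seed; given a seed the batch is deterministic
#'   and the caller's RNG state is untouched.
#' @return integer vector of spot indices (core first).
#' @export
make_minibatch <- function(assignment, core, n_extra, rng_seed = NULL) {
  stopifnot(inherits(assignment, "RegionAssignment"))
  if (core < 1 || core > length(assignment$regions))
    stop("make_minibatch: invalid core region id")
  core_idx <- assignment$regions[[core]]
  iso_pool <- which(is.na(assignment$labels))
  for_pool <- which(!is.na(assignment$labels) & assignment$labels != core)
  n_iso <- min(floor(n_extra / 2), length(iso_pool))
  n_for <- min(ceiling(n_extra / 2), length(for_pool))
  draw <- function() {
    iso <- if (n_iso > 0) sample(iso_pool, n_iso) else integer(0)
    fo <- if (n_for > 0) sample(for_pool, n_for) else integer(0)
    c(core_idx, iso, fo)
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw)
}

#' Region-based mini-batch ensemble imputation
#'
#' For every detected region, `k` mini-batches are built, each holding the
#' whole region core, a chunk of the shuffled isolated pool (the pool is
#' partitioned across the `k` batches so that every isolated spot is
#' processed exactly once per region), and `ceiling(n_extra / 2)` spots
#' sampled from the other regions.  Each batch's sub-matrix is completed
#' by [svt_complete()] run down the regularization ladder until the
#' observed-error rule (`err_target`) is met, and the region's spots
#' receive the element-wise mean over its `k` batches.  Each isolated spot
#' is estimated by averaging one contribution per region, so its final
#' value aggregates as many results as there are regions.  Negative
#' completed values are clipped to zero, and observed non-zero entries are
#' restored to their input values, making the observation constraint
#' exact.
#'
#' @param data a normalized [STData].
#' @param assignment a `RegionAssignment` from [detect_regions()] on the
#'   same data.
#' @param k number of mini-batches per region (default 5).
#' @param n_extra governs the foreign-region sample per batch
#'   (`ceiling(n_extra / 2)` spots); default `min(100, floor(M / 5))`.
#' @param rng_seed seed governing all batch sampling.
#' @param err_target observed-error rule for the ladder (default 1e-12).
#' @param alpha,tol,max_iter,decfac solver controls, as in
#'   [svt_complete()].
#' @return list of class `ImputationResult`: `denoised` (M x N matrix),
#'   `k`, `n_extra`, `lambdas` (per region x batch), `n_contrib` (how many
#'   batch estimates were averaged per spot).
#' @export
impute_mist <- function(data, assignment, k = 5, n_extra = NULL,
                        rng_seed = 1, err_target = 1e-12, alpha = 1,
                        tol = 1e-6, max_iter = 500, decfac = 0.7) {
  stopifnot(inherits(data, "STData"), inherits(assignment, "RegionAssignment"))
  K <- length(assignment$regions)
  if (K == 0) stop("impute_mist: assignment contains zero regions")
  Y <- data$counts
  M <- nrow(Y)
  if (is.null(n_extra)) n_extra <- min(100, floor(M / 5))

  acc <- matrix(0, M, ncol(Y))          # running sums of estimates
  nb <- integer(M)                      # per-spot batch appearance count
  iso_acc <- matrix(0, M, ncol(Y))      # per-region means for isolated spots
  iso_nr <- integer(M)
  lambdas <- matrix(NA_real_, K, k)

  iso_pool <- which(is.na(assignment$labels))
  with_seed(rng_seed, function() {
    for (r in seq_len(K)) {
      core_idx <- assignment$regions[[r]]
      for_pool <- which(!is.na(assignment$labels) &
                          assignment$labels != r)
      # every isolated spot contributes once per region: the shuffled
      # isolated pool is partitioned round-robin across the k batches
      iso_chunks <- if (length(iso_pool) > 0)
        split(sample(iso_pool), rep_len(seq_len(k), length(iso_pool)))
      else NULL
      n_for <- min(ceiling(n_extra / 2), length(for_pool))
      r_acc <- matrix(0, length(core_idx), ncol(Y))
      i_acc <- matrix(0, M, ncol(Y))
      i_cnt <- integer(M)
      for (b in seq_len(k)) {
        iso_b <- if (is.null(iso_chunks) || b > length(iso_chunks))
          integer(0) else iso_chunks[[b]]
        for_b <- if (n_for > 0) sample(for_pool, n_for) else integer(0)
        batch <- c(core_idx, iso_b, for_b)
        sub <- Y[batch, , drop = FALSE]
        fit <- cpp_svt_ladder(sub, (sub != 0) * 1L, lam_final = -1,
                              err_target = err_target, alpha = alpha,
                              decfac = decfac, tol_path = 1e-4,
                              tol_final = tol, max_iter = max_iter,
                              lam_init = -1)
        X <- pmax(fit$X, 0)             # expression is non-negative
        lambdas[r, b] <<- fit$lambda
        r_acc <- r_acc + X[seq_along(core_idx), , drop = FALSE]
        iso_in <- which(is.na(assignment$labels[batch]))
        if (length(iso_in) > 0) {
          sp <- batch[iso_in]
          i_acc[sp, ] <- i_acc[sp, ] + X[iso_in, , drop = FALSE]
          i_cnt[sp] <- i_cnt[sp] + 1L
        }
      }
      acc[core_idx, ] <<- acc[core_idx, ] + r_acc
      nb[core_idx] <<- nb[core_idx] + k
      got <- which(i_cnt > 0)           # one contribution per region
      if (length(got) > 0) {
        iso_acc[got, ] <<- iso_acc[got, ] + i_acc[got, ] / i_cnt[got]
        iso_nr[got] <<- iso_nr[got] + 1L
      }
    }
  })

  denoised <- Y
  in_region <- nb > 0
  denoised[in_region, ] <- acc[in_region, ] / nb[in_region]
  iso_done <- iso_nr > 0
  denoised[iso_done, ] <- iso_acc[iso_done, ] / iso_nr[iso_done]
  never <- which(is.na(assignment$labels) & !iso_done)
  if (length(never) > 0)
    warning(sprintf(
      "impute_mist: %d isolated spot(s) never sampled; left at observed values",
      length(never)))
  obs <- Y != 0
  denoised[obs] <- Y[obs]               # exact observation constraint
  structure(list(denoised = denoised, k = k, n_extra = n_extra,
                 lambdas = lambdas, n_contrib = nb + iso_nr),
            class = "ImputationResult")
}

#' Spatial nearest-neighbour baseline imputer (spKNN)
#'
#' Replaces every zero entry (spot s, gene g) with the mean of gene g over
#' s's lattice neighbours, zeros included.  Non-zero entries are left
#' untouched; spots with no neighbour keep their zeros.
#'
#' @param data an [STData].
#' @param graph a [SpatialGraph][build_weighted_graph()] on the same spots.
#' @return the denoised matrix.
#' @export
impute_spknn <- function(data, graph) {
  stopifnot(inherits(data, "STData"), inherits(graph, "SpatialGraph"))
  Y <- data$counts
  M <- nrow(Y)
  A <- Matrix::sparseMatrix(i = c(graph$edges[, 1], graph$edges[, 2]),
                            j = c(graph$edges[, 2], graph$edges[, 1]),
                            x = 1, dims = c(M, M))
  deg <- Matrix::rowSums(A)
  nbmean <- as.matrix(A %*% Y) / pmax(deg, 1)
  out <- Y
  z <- Y == 0
  out[z] <- nbmean[z]                   # deg-0 rows have nbmean 0: left at 0
  dimnames(out) <- dimnames(Y)
  out
}
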