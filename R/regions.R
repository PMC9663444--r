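#' Highly variable gene selection
#'
#' Ranks genes by dispersion (variance over mean of the normalized values)
#' and keeps the top `ceiling(fraction * N)`, in the order of decreasing
#' dispersion with stable ties.  Genes with zero mean get dispersion 0 and
#' rank last.
#'
#' @param data a normalized [STData].
#' @param fraction fraction of genes to keep, in (0, 1]; default 0.8.
#' @return integer vector of gene column indices.
#' @export
select_hvg <- function(data, fraction = 0.8) {
  stopifnot(inherits(data, "STData"))
  if (!(fraction > 0 && fraction <= 1))
    stop("select_hvg: fraction must be in (0, 1]")
  mu <- colMeans(data$counts)
  v <- apply(data$counts, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_keep <- ceiling(fraction * ncol(data$counts))
  order(disp, decreasing = TRUE)[seq_len(n_keep)]
}

#' PCA embedding of the HVG sub-matrix
#'
#' Mean-centred PCA of the normalized expression restricted to `genes`,
#' optionally log1p-transformed first (`log1p = TRUE`; the default works on
#' the CPM scale, where uniform dropout perturbs the embedding far less
#' than in log space).  A deterministic sign convention is applied: within
#' each component the loading of largest magnitude is made positive, so the
#' embedding is bit-reproducible across runs.
#'
#' @param data a normalized [STData].
#' @param genes gene column indices (e.g. from [select_hvg()]).
#' @param p number of components (default 30); must be
#'   `<= min(M, length(genes))`.
#' @param log1p apply `log1p` before PCA (default FALSE).
#' @return list of class `Embedding`: `pcs` (M x p score matrix), `sdev`
#'   (component standard deviations), `rotation` (loadings), `center`
#'   (column means of the input), `p`.
#' @export
embed_pca <- function(data, genes = seq_len(ncol(data$counts)), p = 30,
                      log1p = FALSE) {
  stopifnot(inherits(data, "STData"))
  x <- data$counts[, genes, drop = FALSE]
  if (log1p) x <- log1p(x)
  if (p > min(nrow(x), ncol(x)))
    stop("embed_pca: p exceeds min(spots, genes)")
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = p)
  flip <- vapply(seq_len(p), function(k) {
    l <- pr$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  pcs <- sweep(pr$x[, seq_len(p), drop = FALSE], 2, flip, `*`)
  rot <- sweep(pr$rotation[, seq_len(p), drop = FALSE], 2, flip, `*`)
  structure(list(pcs = unname(pcs), sdev = pr$sdev[seq_len(p)],
                 rotation = unname(rot), center = unname(pr$center), p = p),
            class = "Embedding")
}

# Row-standardize the PC matrix so that tcrossprod gives the Pearson
# correlation between spots' PC vectors.  Zero-variance rows become zero
# rows (their correlations are defined as 0) with a warning.
standardize_rows <- function(pcs) {
  mu <- rowMeans(pcs)
  ctr <- pcs - mu
  ss <- sqrt(rowSums(ctr^2))
  if (any(ss == 0))
    warning("spot(s) with zero-variance PC vector; their similarity is 0")
  ss[ss == 0] <- Inf
  ctr / ss
}

#' Lattice graph weighted by transcriptomic similarity
#'
#' One edge per pair of lattice-adjacent spots; the weight is the Pearson
#' correlation between the two spots' p-dimensional PC vectors.
#'
#' @param data an [STData] (supplies the coordinates).
#' @param emb an `Embedding` from [embed_pca()].
#' @param layout adjacency convention, `"square4"` or `"hex6"`.
#' @return list of class `SpatialGraph`: `edges` (E x 2 integer matrix,
#'   first column < second), `weights` (length E, in `[-1, 1]`), `M`,
#'   `layout`.
#' @export
build_weighted_graph <- function(data, emb, layout = c("square4", "hex6")) {
  layout <- match.arg(layout)
  stopifnot(inherits(emb, "Embedding"))
  coords <- data$coords
  M <- nrow(coords)
  key <- paste(coords$x, coords$y)
  idx_of <- setNames(seq_len(M), key)
  off <- layout_offsets(layout)
  eu <- integer(0); ev <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- idx_of[paste(coords$x + off[k, 1], coords$y + off[k, 2])]
    hit <- which(!is.na(nb))
    u <- hit; v <- unname(nb[hit])
    sel <- u < v                       # each unordered pair once
    eu <- c(eu, u[sel]); ev <- c(ev, v[sel])
  }
  z <- standardize_rows(emb$pcs)
  w <- rowSums(z[eu, , drop = FALSE] * z[ev, , drop = FALSE])
  structure(list(edges = cbind(eu, ev, deparse.level = 0),
                 weights = unname(w), M = M, layout = layout),
            class = "SpatialGraph")
}

# Iterative depth-first search over an adjacency list; returns a component
# id per node.
dfs_components <- function(adj, M) {
  comp <- integer(M)
  cur <- 0L
  for (s in seq_len(M)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

#' Prune weak edges and extract regions
#'
#' Removes edges with weight strictly below `epsilon`, finds connected
#' components by depth-first search, and promotes components with more
#' than `q` spots to regions (ids assigned in decreasing size order).  All
#' remaining spots are isolated (`NA` label).
#'
#' @param graph a [SpatialGraph][build_weighted_graph()].
#' @param epsilon pruning threshold; edges with `weight >= epsilon` are
#'   kept.
#' @param q minimum region size (a component must have *more* than `q`
#'   spots).
#' @return list of class `RegionAssignment`: `labels` (integer per spot,
#'   `NA` = isolated), `regions` (list of spot index vectors), `threshold`,
#'   `q`, `objective` (filled by [detect_regions()]).
#' @export
prune_and_components <- function(graph, epsilon, q) {
  stopifnot(inherits(graph, "SpatialGraph"), q >= 1)
  keep <- graph$weights >= epsilon
  adj <- vector("list", graph$M)
  if (any(keep)) {
    e <- graph$edges[keep, , drop = FALSE]
    adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]),
                                           levels = seq_len(graph$M)))
  } else {
    adj <- rep(list(integer(0)), graph$M)
  }
  comp <- dfs_components(adj, graph$M)
  sizes <- tabulate(comp)
  big <- which(sizes > q)
  big <- big[order(sizes[big], decreasing = TRUE)]
  labels <- rep(NA_integer_, graph$M)
  regions <- vector("list", length(big))
  for (i in seq_along(big)) {
    idx <- which(comp == big[i])
    labels[idx] <- i
    regions[[i]] <- idx
  }
  structure(list(labels = labels, regions = regions, threshold = epsilon,
                 q = q, objective = NA_real_),
            class = "RegionAssignment")
}

#' @export
print.RegionAssignment <- function(x, ...) {
  cat(sprintf(
    "RegionAssignment: %d region(s), %d isolated spot(s), threshold %.3g\n",
    length(x$regions), sum(is.na(x$labels)), x$threshold))
  if (length(x$regions) > 0)
    cat("  sizes:", paste(lengths(x$regions), collapse = ", "), "\n")
  invisible(x)
}

#' Region-quality objective
#'
#' Scores an assignment as (mean over regions of the mean pairwise
#' intra-region similarity) minus (mean over region pairs of the mean
#' cross-region similarity) plus `sigma` times the fraction of spots
#' covered by regions.  Similarity between two spots is the Pearson
#' correlation of their PC vectors, over *all* pairs, not only adjacent
#' ones.  With zero regions the score is `-Inf`; with one region the
#' inter-region term is 0.
#'
#' @param assignment a [RegionAssignment][prune_and_components()].
#' @param emb the `Embedding` the similarities are computed from.
#' @param sigma coverage weight (default 0.1).
#' @return numeric scalar.
#' @export
region_objective <- function(assignment, emb, sigma = 0.1) {
  z <- suppressWarnings(standardize_rows(emb$pcs))
  region_objective_z(assignment, z, sigma)
}

# Internal: objective from pre-standardized rows.  Pairwise sums are
# obtained from region-summed vectors: sum_{i,j in r, i != j} C_ij =
# |T_r|^2 - sum_{i in r} |z_i|^2, and the cross sum for (r, r') is
# T_r . T_r'.
region_objective_z <- function(assignment, z, sigma = 0.1) {
  regions <- assignment$regions
  K <- length(regions)
  if (K == 0) return(-Inf)
  M <- nrow(z)
  Tm <- t(vapply(regions, function(idx) colSums(z[idx, , drop = FALSE]),
                 numeric(ncol(z))))
  sq <- vapply(regions, function(idx) sum(z[idx, , drop = FALSE]^2),
               numeric(1))
  n <- lengths(regions)
  intra <- (rowSums(Tm^2) - sq) / (n * (n - 1))
  intra[n < 2] <- 0                      # degenerate single-spot region
  term1 <- mean(intra)
  term2 <- 0
  if (K > 1) {
    G <- tcrossprod(Tm)                   # K x K cross sums
    num <- G[upper.tri(G)]
    den <- outer(n, n)[upper.tri(G)]
    term2 <- mean(num / den)
  }
  coverage <- sum(n) / M
  term1 - term2 + sigma * coverage
}

#' Detect molecular regions
#'
#' Runs the full chain: HVG selection, PCA embedding, weighted lattice
#' graph, then a grid search over pruning thresholds, keeping the
#' assignment that maximizes [region_objective()].  Ties break toward the
#' smaller threshold.
#'
#' @param data a normalized [STData].
#' @param sigma coverage weight of the objective (default 0.1).
#' @param grid candidate thresholds (default `seq(0.1, 0.9, by = 0.05)`).
#' @param q minimum region size; `NULL` selects 40 when the slide has at
#'   least 500 spots and 20 otherwise.
#' @param p number of principal components (default 30).
#' @param hvg_fraction fraction of highly variable genes (default 0.8).
#' @param layout lattice adjacency convention.
#' @param log1p log-transform before PCA (default FALSE).
#' @return a `RegionAssignment` with `objective`, `sigma`, `p`, `layout`
#'   and the `Embedding` (field `embedding`) and `SpatialGraph` (field
#'   `graph`) attached for downstream use.
#' @export
detect_regions <- function(data, sigma = 0.1,
                           grid = seq(0.1, 0.9, by = 0.05), q = NULL,
                           p = 30, hvg_fraction = 0.8,
                           layout = c("square4", "hex6"), log1p = FALSE) {
  layout <- match.arg(layout)
  stopifnot(inherits(data, "STData"))
  if (!data$normalized) stop("detect_regions: data must be CPM-normalized")
  M <- nrow(data$counts)
  if (is.null(q)) q <- if (M >= 500) 40L else 20L
  genes <- select_hvg(data, hvg_fraction)
  p_use <- min(p, M, length(genes))
  emb <- embed_pca(data, genes, p = p_use, log1p = log1p)
  graph <- build_weighted_graph(data, emb, layout)
  z <- suppressWarnings(standardize_rows(emb$pcs))

  best <- NULL
  best_obj <- -Inf
  for (eps in grid) {
    a <- prune_and_components(graph, eps, q)
    obj <- region_objective_z(a, z, sigma)
    a$objective <- obj
    if (obj > best_obj) {               # strict: ties keep the smaller eps
      best <- a
      best_obj <- obj
    }
  }
  if (is.null(best) || length(best$regions) == 0)
    stop(sprintf(paste0(
      "detect_regions: no threshold produced a region ",
      "(edge weights: min %.3f, median %.3f, max %.3f; q = %d)"),
      min(graph$weights), stats::median(graph$weights),
      max(graph$weights), q))
  best$sigma <- sigma
  best$p <- p_use
  best$layout <- layout
  best$hvg <- genes
  best$embedding <- emb
  best$graph <- graph
  best
}

#' Export a region assignment as CSV plus JSON sidecar
#'
#' @param assignment a `RegionAssignment` from [detect_regions()].
#' @param data the [STData] it was computed on.
#' @param path output CSV path; the sidecar takes the same path with
#'   extension `.json`.
#' @export
write_regions <- function(assignment, data, path) {
  lab <- ifelse(is.na(assignment$labels), "ISOLATED",
                as.character(assignment$labels))
  write.csv(data.frame(spot_id = data$spot_ids, x = data$coords$x,
                       y = data$coords$y, region_label = lab),
            path, row.names = FALSE)
  side <- list(epsilon = assignment$threshold, sigma = assignment$sigma,
               q = assignment$q, p = assignment$p,
               objective = assignment$objective,
               n_regions = length(assignment$regions))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
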