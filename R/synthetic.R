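#' Full lattice of spot coordinates
#'
#' @param rows,cols lattice dimensions (both >= 2).
#' @param layout `"square4"` (rook adjacency) or `"hex6"` (axial hexagon
#'   coordinates with six neighbours).
#' @return data.frame with columns `x`, `y`; `rows * cols` rows.
#' @export
generate_lattice <- function(rows, cols, layout = c("square4", "hex6")) {
  layout <- match.arg(layout)
  stopifnot(rows >= 2, cols >= 2)
  g <- expand.grid(x = seq_len(cols), y = seq_len(rows))
  attr(g, "layout") <- layout
  g
}

# Neighbour offsets per adjacency convention.  hex6 uses axial coordinates.
layout_offsets <- function(layout) {
  switch(layout,
    square4 = cbind(c(1, -1, 0, 0), c(0, 0, 1, -1)),
    hex6 = cbind(c(1, -1, 0, 0, 1, -1), c(0, 0, 1, -1, -1, 1)),
    stop("unknown layout: ", layout))
}

# Partition lattice coordinates into contiguous planted regions.
plant_regions <- function(coords, n_regions, shape = c("quadrant", "stripes")) {
  shape <- match.arg(shape)
  if (shape == "quadrant") {
    if (n_regions != 4) stop("quadrant layout requires n_regions = 4")
    mx <- stats::median(range(coords$x))
    my <- stats::median(range(coords$y))
    1L + (coords$x > mx) + 2L * (coords$y > my)
  } else {
    band <- cut(coords$y, breaks = n_regions, labels = FALSE)
    as.integer(band)
  }
}

#' Synthetic ST slide with planted regions, low-rank expression and dropout
#'
#' Every region shares a log-normal baseline expression profile but
#' up-regulates its own block of marker genes (disjoint blocks, boost
#' `marker_boost`), emulating regions that carry distinct expression
#' programs spread across many genes.  Within region `r` the dense
#' (pre-dropout) matrix is `U_r V_r^T` with strictly positive factors: the
#' first factor column is the baseline-plus-markers profile, the remaining
#' `rank - 1` columns are small log-normal perturbation factors, so the
#' region sub-matrix has exact rank `rank` when `noise_sd = 0`.
#' Multiplicative log-normal noise (`noise_sd`) and a per-spot log-normal
#' library-size factor are then applied, and independent
#' Bernoulli(`dropout_rate`) dropout zeroes entries.
#'
#' @param rows,cols lattice dimensions.
#' @param n_genes number of genes.
#' @param n_regions number of planted regions.
#' @param rank factor rank per region; must be < min(region size, n_genes).
#' @param dropout_rate Bernoulli zeroing probability in `[0, 1)`.
#' @param noise_sd standard deviation (log scale) of multiplicative
#'   entry-level noise.
#' @param seed integer seed; output is deterministic given the seed.
#' @param layout lattice adjacency convention.
#' @param shape `"quadrant"` (axis-aligned blocks, n_regions = 4) or
#'   `"stripes"` (horizontal bands).
#' @param marker_boost fold elevation of a region's marker block over the
#'   baseline profile.
#' @param base_sd log-scale spread of the baseline profile across genes.
#' @param spot_sd log-scale spread of per-spot factor weights.
#' @param pert_weight,pert_sd weight and log-scale spread of the `rank - 1`
#'   perturbation factors.
#' @param lib_sd standard deviation (log scale) of the per-spot
#'   library-size factor.
#' @param base_scale multiplier setting the overall count magnitude.
#' @return list with `data` (an [STData], raw observed counts) and `truth`
#'   (class `SyntheticTruth`): `dense_expr` (pre-dropout matrix),
#'   `region_labels` (integer per spot), `boundary` (logical per spot, TRUE
#'   for spots lattice-adjacent to another region), `dropout_mask` (logical
#'   matrix, TRUE = zeroed by dropout), `rank_per_region`.
#' @export
generate_synthetic_st <- function(rows = 20, cols = 20, n_genes = 200,
                                  n_regions = 4, rank = 3,
                                  dropout_rate = 0.3, noise_sd = 0.05,
                                  seed = 1, layout = c("square4", "hex6"),
                                  shape = c("quadrant", "stripes"),
                                  marker_boost = 6, base_sd = 0.1,
                                  spot_sd = 0.1, pert_weight = 0.02,
                                  pert_sd = 0.3, lib_sd = 0.2,
                                  base_scale = 10) {
  layout <- match.arg(layout)
  shape <- match.arg(shape)
  stopifnot(dropout_rate >= 0, dropout_rate < 1, noise_sd >= 0)
  coords <- generate_lattice(rows, cols, layout)
  M <- nrow(coords)
  labels <- plant_regions(coords, n_regions, shape)
  sizes <- tabulate(labels, n_regions)
  if (rank >= min(sizes) || rank >= n_genes)
    stop("generate_synthetic_st: rank must be < min(region size, n_genes)")

  with_seed(seed, function() {
    base <- exp(rnorm(n_genes, sd = base_sd))
    markers <- split(seq_len(n_genes),
                     rep(seq_len(n_regions), length.out = n_genes))
    dense <- matrix(0, M, n_genes)
    for (r in seq_len(n_regions)) {
      idx <- which(labels == r)
      v1 <- base
      v1[markers[[r]]] <- v1[markers[[r]]] * marker_boost
      V <- cbind(v1, pert_weight *
                   exp(matrix(rnorm(n_genes * (rank - 1), sd = pert_sd),
                              n_genes, rank - 1)))
      U <- cbind(exp(rnorm(length(idx), sd = spot_sd)),
                 exp(matrix(rnorm(length(idx) * (rank - 1), sd = spot_sd),
                            length(idx), rank - 1)))
      dense[idx, ] <- U %*% t(V) * base_scale
    }
    if (noise_sd > 0)
      dense <- dense * exp(matrix(rnorm(M * n_genes, sd = noise_sd),
                                  M, n_genes))
    if (lib_sd > 0)
      dense <- dense * exp(rnorm(M, sd = lib_sd))
    mask <- matrix(runif(M * n_genes) < dropout_rate, M, n_genes)
    observed <- dense
    observed[mask] <- 0

    spot_ids <- sprintf("s%04d", seq_len(M))
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    data <- STData(observed, coords, gene_ids = gene_ids,
                   spot_ids = spot_ids)
    boundary <- boundary_spots(coords, labels, layout)
    truth <- structure(list(dense_expr = dense, region_labels = labels,
                            boundary = boundary, dropout_mask = mask,
                            rank_per_region = rank, marker_genes = markers,
                            layout = layout, seed = seed),
                       class = "SyntheticTruth")
    list(data = data, truth = truth)
  })
}

# Spots lattice-adjacent to a spot of another region.
boundary_spots <- function(coords, labels, layout) {
  key <- paste(coords$x, coords$y)
  lab_of <- setNames(labels, key)
  off <- layout_offsets(layout)
  out <- logical(nrow(coords))
  for (k in seq_len(nrow(off))) {
    nb_key <- paste(coords$x + off[k, 1], coords$y + off[k, 2])
    nb_lab <- lab_of[nb_key]
    out <- out | (!is.na(nb_lab) & nb_lab != labels)
  }
  unname(out)
}

#' Write a synthetic fixture to disk
#'
#' Emits the observed counts in both accepted on-disk formats (dense CSV
#' and Visium-style directory) plus a `truth.csv` with per-spot planted
#' labels/boundary flags and a `dropout_mask.csv`.
#'
#' @param sim result of [generate_synthetic_st()].
#' @param dir output directory.
#' @export
write_synthetic_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_st_csv(sim$data, file.path(dir, "counts.csv"))
  write_visium(sim$data, file.path(dir, "visium"))
  write.csv(data.frame(spot_id = sim$data$spot_ids,
                       x = sim$data$coords$x, y = sim$data$coords$y,
                       region = sim$truth$region_labels,
                       boundary = sim$truth$boundary),
            file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(sim$truth$dropout_mask * 1L, file.path(dir, "dropout_mask.csv"),
            row.names = FALSE)
  invisible(dir)
}
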