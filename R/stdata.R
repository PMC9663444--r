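#' Spot-by-gene expression container
#'
#' The carrier object used throughout the pipeline: a dense spot-by-gene
#' matrix of non-negative values together with integer lattice coordinates
#' for every spot.  Counts are raw until [normalize_cpm()] sets the
#' `normalized` flag, after which every row sums to one million.
#'
#' @param counts numeric matrix, M spots x N genes, all entries >= 0.
#' @param coords data.frame with numeric columns `x` and `y`, one row per
#'   spot, in lattice (array) units.  No two spots may share a coordinate.
#' @param gene_ids,spot_ids character vectors of unique identifiers; default
#'   to the dimnames of `counts`.
#' @param normalized logical; `TRUE` once the matrix holds counts-per-million.
#' @return An object of class `STData`: a list with elements `counts`,
#'   `coords`, `gene_ids`, `spot_ids`, `normalized`.
#' @export
STData <- function(counts, coords, gene_ids = colnames(counts),
                   spot_ids = rownames(counts), normalized = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  coords <- as.data.frame(coords)
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  rownames(coords) <- spot_ids
  obj <- structure(list(counts = counts, coords = coords,
                        gene_ids = as.character(gene_ids),
                        spot_ids = as.character(spot_ids),
                        normalized = isTRUE(normalized)),
                   class = "STData")
  validate_stdata(obj)
  obj
}

validate_stdata <- function(x, check_cpm = TRUE) {
  stopifnot(inherits(x, "STData"))
  if (any(x$counts < 0)) stop("STData: negative entries in counts")
  if (anyDuplicated(x$gene_ids)) stop("STData: duplicated gene_ids")
  if (anyDuplicated(x$spot_ids)) stop("STData: duplicated spot_ids")
  if (nrow(x$coords) != nrow(x$counts))
    stop("STData: coords must have one row per spot")
  if (!all(c("x", "y") %in% colnames(x$coords)))
    stop("STData: coords needs columns x and y")
  if (anyDuplicated(x$coords[, c("x", "y")]))
    stop("STData: two spots share a coordinate")
  if (x$normalized && check_cpm) {
    rs <- rowSums(x$counts)
    if (any(abs(rs - 1e6) > 1e-9 * 1e6))
      stop("STData: normalized flag set but row sums differ from 1e6")
  }
  invisible(x)
}

#' @export
print.STData <- function(x, ...) {
  cat(sprintf("STData: %d spots x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "CPM" else "raw counts"))
  cat(sprintf("  x range [%g, %g], y range [%g, %g]\n",
              min(x$coords$x), max(x$coords$x),
              min(x$coords$y), max(x$coords$y)))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$counts == 0)))
  invisible(x)
}

#' @export
dim.STData <- function(x) dim(x$counts)

# Subset spots (i) and/or genes (j) keeping metadata in step.
subset_stdata <- function(x, i = NULL, j = NULL) {
  if (!is.null(i)) {
    x$counts <- x$counts[i, , drop = FALSE]
    x$coords <- x$coords[i, , drop = FALSE]
    x$spot_ids <- x$spot_ids[i]
  }
  if (!is.null(j)) {
    x$counts <- x$counts[, j, drop = FALSE]
    x$gene_ids <- x$gene_ids[j]
  }
  x
}
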