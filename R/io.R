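#' Read a 10x Visium-style directory
#'
#' Expects the plain-file layout: a MatrixMarket count matrix
#' (`matrix.mtx`, genes x barcodes), `barcodes.tsv`, `features.tsv` (or
#' `genes.tsv`), and a tissue-position table `tissue_positions_list.csv`
#' (or `tissue_positions.csv`) with columns barcode, in_tissue flag, array
#' row, array column (extra pixel columns ignored; a header line is
#' detected and skipped).  Only in-tissue spots are kept.
#'
#' Visium array coordinates satisfy the parity convention that
#' `array_col - array_row` is even; when that holds, coordinates are
#' converted to axial hexagon units `x = (col - row) / 2`, `y = row`, so
#' that the `hex6` adjacency offsets apply directly.  Otherwise the raw
#' (col, row) pair is kept.
#'
#' @param path directory containing the files above.
#' @return An [STData] with raw counts.
#' @export
read_visium <- function(path) {
  need <- function(cands) {
    for (f in cands) {
      fp <- file.path(path, f)
      if (file.exists(fp)) return(fp)
    }
    stop("read_visium: missing file ", cands[1], " in ", path)
  }
  f_mtx <- need(c("matrix.mtx", "matrix.mtx.gz"))
  f_bar <- need(c("barcodes.tsv", "barcodes.tsv.gz"))
  f_fea <- need(c("features.tsv", "features.tsv.gz", "genes.tsv"))
  f_pos <- need(c("tissue_positions_list.csv", "tissue_positions.csv"))

  m <- Matrix::readMM(f_mtx)               # genes x barcodes
  barcodes <- read.delim(f_bar, header = FALSE)[[1]]
  features <- read.delim(f_fea, header = FALSE)
  if (nrow(features) != nrow(m))
    stop("read_visium: feature list length does not match matrix rows")
  if (length(barcodes) != ncol(m))
    stop("read_visium: barcode list length does not match matrix columns")

  first <- readLines(f_pos, n = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  pos <- read.csv(f_pos, header = has_header)
  pos <- pos[, 1:4]
  colnames(pos) <- c("barcode", "in_tissue", "array_row", "array_col")

  missing_bc <- setdiff(barcodes, pos$barcode)
  if (length(missing_bc) > 0)
    stop("read_visium: barcodes absent from position table: ",
         paste(utils::head(missing_bc, 5), collapse = ", "))
  pos <- pos[match(barcodes, pos$barcode), ]
  keep <- pos$in_tissue == 1
  if (!any(keep)) stop("read_visium: no in-tissue spots")

  counts <- t(as.matrix(m))[keep, , drop = FALSE]   # spots x genes
  row <- pos$array_row[keep]
  col <- pos$array_col[keep]
  if (all((col - row) %% 2 == 0)) {
    coords <- data.frame(x = (col - row) / 2, y = row)
  } else {
    coords <- data.frame(x = col, y = row)
  }
  gene_ids <- make.unique(as.character(features[[1]]))
  STData(counts, coords, gene_ids = gene_ids,
         spot_ids = as.character(barcodes[keep]))
}

#' Read a dense spot-by-gene CSV table
#'
#' Legacy ST format: rows are spots labelled `"<x>x<y>"` (any of the
#' separators `x`, `X`, `_` between the two numbers), columns are genes.
#'
#' @param path CSV file path.
#' @param sep_pattern regular expression splitting the row label into the
#'   two coordinates.
#' @return An [STData] with raw counts.
#' @export
read_st_csv <- function(path, sep_pattern = "[xX_]") {
  tab <- read.csv(path, row.names = 1, check.names = FALSE)
  labs <- rownames(tab)
  if (anyDuplicated(labs))
    stop("read_st_csv: duplicate row label ", labs[duplicated(labs)][1])
  parts <- strsplit(labs, sep_pattern)
  bad <- which(vapply(parts, length, 1L) != 2L)
  xy <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))))
  bad <- union(bad, which(apply(!is.finite(xy), 1, any)))
  if (length(bad) > 0)
    stop("read_st_csv: cannot parse row label '", labs[bad[1]],
         "' as <x>x<y>")
  counts <- as.matrix(tab)
  if (any(counts < 0))
    stop("read_st_csv: negative entry in table (counts must be >= 0)")
  STData(counts, data.frame(x = xy[, 1], y = xy[, 2]),
         gene_ids = colnames(tab), spot_ids = labs)
}

#' Write an STData (or denoised matrix) as a dense CSV
#'
#' Row labels are `"<x>x<y>"`, matching [read_st_csv()].
#'
#' @param data an [STData].
#' @param path output file.
#' @param matrix optional replacement matrix (e.g. a denoised matrix) with
#'   the same shape as `data$counts`.
#' @export
write_st_csv <- function(data, path, matrix = NULL) {
  m <- if (is.null(matrix)) data$counts else matrix
  out <- as.data.frame(m)
  rownames(out) <- paste0(data$coords$x, "x", data$coords$y)
  write.csv(out, path, row.names = TRUE)
  invisible(path)
}

#' Write an STData as a Visium-style plain-file directory
#'
#' Emits `matrix.mtx` (genes x barcodes), `barcodes.tsv`, `features.tsv`
#' and `tissue_positions_list.csv`, the layout accepted by [read_visium()].
#' Axial coordinates are converted back to the Visium parity convention
#' (`array_row = y`, `array_col = 2x + y`).
#'
#' @param data an [STData].
#' @param path output directory (created if needed).
#' @param matrix optional replacement matrix, as in [write_st_csv()].
#' @export
write_visium <- function(data, path, matrix = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- if (is.null(matrix)) data$counts else matrix
  Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  writeLines(data$spot_ids, file.path(path, "barcodes.tsv"))
  write.table(data.frame(id = data$gene_ids, name = data$gene_ids,
                         type = "Gene Expression"),
              file.path(path, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  pos <- data.frame(barcode = data$spot_ids, in_tissue = 1L,
                    array_row = data$coords$y,
                    array_col = 2 * data$coords$x + data$coords$y)
  write.table(pos, file.path(path, "tissue_positions_list.csv"),
              sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Quality-control filter on raw counts
#'
#' Genes observed (non-zero) in fewer than `min_spots_per_gene` spots are
#' removed first; then spots with total counts below `min_umi`, or with a
#' mitochondrial count fraction above `max_mito_frac`, are removed.  Spot
#' totals are computed after the gene filter; the gene filter is not
#' re-applied afterwards (single pass).
#'
#' @param data an [STData] with raw counts.
#' @param min_spots_per_gene minimum number of spots a gene must appear in
#'   (default 10).
#' @param min_umi minimum per-spot total count (default 1500).
#' @param max_mito_frac maximum mitochondrial fraction per spot (default
#'   0.3).
#' @param mito_prefix gene-name prefixes marking mitochondrial genes.
#' @return the filtered [STData].
#' @export
qc_filter <- function(data, min_spots_per_gene = 10, min_umi = 1500,
                      max_mito_frac = 0.3, mito_prefix = c("MT-", "mt-")) {
  stopifnot(inherits(data, "STData"))
  if (data$normalized) stop("qc_filter: expects raw counts, not CPM")
  keep_g <- colSums(data$counts > 0) >= min_spots_per_gene
  if (!any(keep_g)) stop("qc_filter: empty matrix after QC (all genes removed)")
  data <- subset_stdata(data, j = which(keep_g))
  tot <- rowSums(data$counts)
  mito <- grepl(paste0("^(", paste(mito_prefix, collapse = "|"), ")"),
                data$gene_ids)
  mito_frac <- if (any(mito))
    rowSums(data$counts[, mito, drop = FALSE]) / pmax(tot, 1) else
    rep(0, nrow(data$counts))
  keep_s <- tot >= min_umi & mito_frac <= max_mito_frac
  if (!any(keep_s)) stop("qc_filter: empty matrix after QC (all spots removed)")
  subset_stdata(data, i = which(keep_s))
}

#' Counts-per-million normalization
#'
#' Scales every spot to a library size of one million:
#' `cpm = raw * 1e6 / spot_total`.
#'
#' @param data an [STData] with raw counts; every spot total must be > 0.
#' @return the normalized [STData] (flag set).
#' @export
normalize_cpm <- function(data) {
  stopifnot(inherits(data, "STData"))
  if (data$normalized) stop("normalize_cpm: already normalized")
  tot <- rowSums(data$counts)
  if (any(tot <= 0))
    stop("normalize_cpm: zero-total spot present (run qc_filter first)")
  data$counts <- data$counts * (1e6 / tot)
  data$normalized <- TRUE
  validate_stdata(data)
  data
}
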