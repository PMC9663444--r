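# Two-sided Wilcoxon rank-sum test, normal approximation with tie
# correction, no continuity correction.  Returns the rank-sum statistic W
# (sum of ranks of x in the pooled sample) and the p-value.
ranksum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(statistic = W, p.value = 1))
  z <- (W - mu) / sqrt(v)
  list(statistic = W, p.value = 2 * pnorm(-abs(z)))
}

#' Regional marker genes by Wilcoxon rank-sum
#'
#' For every region, each gene is tested (two-sided rank-sum, normal
#' approximation with tie correction) for the region's spots against the
#' spots of all other regions; isolated spots are excluded from both
#' groups.  P-values are Benjamini-Hochberg adjusted across genes within
#' each region.  Two effect sizes are reported: `fold_change`, the ratio
#' of group means on the expression scale (used for filtering:
#' `fold_change > 1 + fc_min`), and `log_diff`, the difference of group
#' means of `log1p` expression.  Only upregulated genes passing both the
#' fold-change and adjusted-p filters are returned, sorted by adjusted p
#' within region.
#'
#' @param data a normalized [STData].
#' @param assignment a `RegionAssignment` with at least two regions.
#' @param fc_min minimum relative increase (default 0.5, i.e. ratio >
#'   1.5).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param min_spots regions with fewer spots are skipped with a warning
#'   (default 3).
#' @return data.frame of class `MarkerTable` with columns `region`,
#'   `gene`, `fold_change`, `log_diff`, `raw_p`, `adjusted_p`,
#'   `direction`; attributes `fc_min` and `alpha` record the thresholds.
#' @export
regional_markers <- function(data, assignment, fc_min = 0.5, alpha = 0.01,
                             min_spots = 3) {
  stopifnot(inherits(data, "STData"), inherits(assignment, "RegionAssignment"))
  K <- length(assignment$regions)
  if (K < 2) stop("regional_markers: need >= 2 regions")
  labels <- assignment$labels
  rows <- list()
  for (r in seq_len(K)) {
    in_r <- which(labels == r)
    out_r <- which(!is.na(labels) & labels != r)
    if (length(in_r) < min_spots) {
      warning("regional_markers: region ", r, " has < ", min_spots,
              " spots; skipped")
      next
    }
    res <- lapply(seq_len(ncol(data$counts)), function(g) {
      xi <- data$counts[in_r, g]
      yo <- data$counts[out_r, g]
      t <- ranksum_test(xi, yo)
      mi <- mean(xi); mo <- mean(yo)
      data.frame(region = r, gene = data$gene_ids[g],
                 fold_change = if (mo > 0) mi / mo else Inf,
                 log_diff = mean(log1p(xi)) - mean(log1p(yo)),
                 raw_p = t$p.value,
                 direction = if (mi >= mo) "up" else "down")
    })
    tab <- do.call(rbind, res)
    tab$adjusted_p <- p.adjust(tab$raw_p, method = "BH")
    rows[[length(rows) + 1]] <- tab
  }
  out <- do.call(rbind, rows)
  out <- out[out$direction == "up" & out$fold_change > 1 + fc_min &
               out$adjusted_p < alpha, , drop = FALSE]
  out <- out[order(out$region, out$adjusted_p), ]
  rownames(out) <- NULL
  out <- out[, c("region", "gene", "fold_change", "log_diff", "raw_p",
                 "adjusted_p", "direction")]
  attr(out, "fc_min") <- fc_min
  attr(out, "alpha") <- alpha
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' Write marker tables to TSV, one file per region
#'
#' @param markers a `MarkerTable` from [regional_markers()].
#' @param dir output directory.
#' @export
write_markers <- function(markers, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in unique(markers$region)) {
    sub <- markers[markers$region == r, , drop = FALSE]
    utils::write.table(sub, file.path(dir, sprintf("region_%d_markers.tsv", r)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
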