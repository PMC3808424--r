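#' Filter a differential-expression table on significance and fold change
#'
#' Keeps genes with `p_value < p_max` and an absolute fold change beyond
#' `fc_min` on the ratio scale: `fold_change > fc_min` (direction `up`) or
#' `fold_change < 1/fc_min` (direction `down`). Both inequalities are
#' strict. The defaults (p < 0.05, |FC| > 1.5) mirror the usual
#' post-filtering of count-based DE results; no multiple-testing correction
#' is applied, matching that convention.
#'
#' @param de Tibble with at least `gene_id`, `fold_change`, `p_value`;
#'   extra columns pass through.
#' @param p_max Significance threshold (default 0.05, strict).
#' @param fc_min Fold-change threshold on the ratio scale (default 1.5,
#'   strict, applied symmetrically as `> fc_min` or `< 1/fc_min`).
#' @return The kept rows with an added `direction` column (`"up"`/`"down"`).
#' @export
filter_de <- function(de, p_max = 0.05, fc_min = 1.5) {
  req <- c("gene_id", "fold_change", "p_value")
  if (!all(req %in% names(de))) {
    stop("DE table must have columns: ", paste(req, collapse = ", "))
  }
  bad <- which(!is.finite(de$fold_change) | de$fold_change <= 0)
  if (length(bad) > 0) {
    stop("non-positive fold change at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (gene ", de$gene_id[bad[1]], ")")
  }
  if (any(de$p_value < 0 | de$p_value > 1)) stop("p-values must lie in [0, 1]")
  keep <- de$p_value < p_max &
    (de$fold_change > fc_min | de$fold_change < 1 / fc_min)
  out <- de[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change > fc_min, "up", "down")
  out
}

#' Tabulate filtered genes into fold-change bins
#'
#' Bins the kept genes by fold change into the half-open intervals
#' `[edge_i, edge_{i+1})` defined by `bin_edges`, tabulating up- and
#' down-regulated genes separately. Binning must be exhaustive: a gene whose
#' fold change falls outside the edges is an error.
#'
#' @param de_filtered Output of [filter_de()].
#' @param bin_edges Strictly increasing numeric vector of fold-change edges.
#' @return Tibble with columns `bin_start`, `bin_end`, `n_up`, `n_down`,
#'   `n_total`.
#' @export
fc_histogram <- function(de_filtered, bin_edges) {
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing with at least two values")
  }
  if (!all(c("fold_change", "direction") %in% names(de_filtered))) {
    stop("fc_histogram expects the output of filter_de (fold_change + direction)")
  }
  fc <- de_filtered$fold_change
  if (length(fc) > 0 && (any(fc < bin_edges[1]) || any(fc >= bin_edges[length(bin_edges)]))) {
    stop("fold changes fall outside the bin edges; binning must be exhaustive")
  }
  bin <- findInterval(fc, bin_edges, rightmost.closed = FALSE)
  k <- length(bin_edges) - 1
  up <- tabulate(bin[de_filtered$direction == "up"], nbins = k)
  down <- tabulate(bin[de_filtered$direction == "down"], nbins = k)
  tibble::tibble(bin_start = bin_edges[-length(bin_edges)],
                 bin_end = bin_edges[-1],
                 n_up = up, n_down = down, n_total = up + down)
}
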