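#' Per-promoter methylation-change profiles
#'
#' For each gene, counts the measured CCGG sites whose position falls inside
#' the gene's promoter window and splits them by direction of methylation
#' change. A site counts as hyper-methylated when `delta >= site_change_cutoff`
#' (for a zero cutoff, any `delta > 0`), hypo-methylated symmetrically, and
#' as `none` otherwise; zero-change sites stay in the denominator of
#' `pct_hyper = 100 * n_hyper / n_sites`. Genes with fewer than `min_sites`
#' measured promoter sites are dropped to limit sampling noise (default 2).
#'
#' @param deltas Output of [site_deltas()].
#' @param sites Site coordinate tibble (`site_id`, `chrom`, `pos`).
#' @param ann A `genome_annotation` (or gene tibble acceptable to
#'   [promoter_windows()]).
#' @param min_sites Minimum measured promoter sites (default 2).
#' @param site_change_cutoff Minimum `|delta|` for a directional site call
#'   (default 0: any nonzero change counts).
#' @param upstream,downstream Promoter extent in bp.
#' @return Tibble with columns `gene_id`, `chrom`, `n_sites`, `n_hyper`,
#'   `n_hypo`, `n_none`, `pct_hyper`.
#' @export
promoter_profiles <- function(deltas, sites, ann, min_sites = 2,
                              site_change_cutoff = 0,
                              upstream = 1500, downstream = 500) {
  pw <- promoter_windows(ann, upstream = upstream, downstream = downstream)
  d <- dplyr::inner_join(deltas[, c("site_id", "delta")],
                         sites[, c("site_id", "chrom", "pos")],
                         by = "site_id")
  if (nrow(d) == 0 || nrow(pw) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          n_sites = integer(), n_hyper = integer(),
                          n_hypo = integer(), n_none = integer(),
                          pct_hyper = numeric()))
  }
  hits <- GenomicRanges::findOverlaps(
    sites_as_granges(d),
    intervals_as_granges(pw[, c("chrom", "start", "end")])
  )
  per <- tibble::tibble(
    gene_id = pw$gene_id[S4Vectors::subjectHits(hits)],
    chrom = pw$chrom[S4Vectors::subjectHits(hits)],
    delta = d$delta[S4Vectors::queryHits(hits)]
  )
  cutoff <- site_change_cutoff
  per |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_hyper = if (cutoff > 0) sum(.data$delta >= cutoff) else sum(.data$delta > 0),
      n_hypo = if (cutoff > 0) sum(.data$delta <= -cutoff) else sum(.data$delta < 0),
      .groups = "drop") |>
    dplyr::mutate(n_none = .data$n_sites - .data$n_hyper - .data$n_hypo,
                  pct_hyper = 100 * .data$n_hyper / .data$n_sites) |>
    dplyr::filter(.data$n_sites >= min_sites) |>
    dplyr::arrange(.data$gene_id)
}

#' Classify methylation-expression concordance
#'
#' Assigns each gene a class from its expression direction and the
#' percentage of promoter sites that gained methylation, using a promoter
#' direction threshold (default 90): a promoter counts as hypomethylated
#' when `pct_hyper <= 100 - threshold` (at most 10% of sites moved the other
#' way) and hypermethylated when `pct_hyper >= threshold`. Classes:
#' `concordant_up` (up-regulated, hypomethylated promoter), `concordant_down`
#' (down-regulated, hypermethylated), `discordant_up` / `discordant_down`
#' for the reversed pairings, and `unclassified` for promoters between the
#' thresholds.
#'
#' @param direction Character vector, `"up"` or `"down"` per gene.
#' @param pct_hyper Percentage of promoter sites hyper-methylated, in
#'   `[0, 100]`.
#' @param threshold Promoter direction threshold as a percentage
#'   (default 90; bounds inclusive).
#' @return Character vector of classes.
#' @export
classify_concordance <- function(direction, pct_hyper, threshold = 90) {
  stopifnot(length(direction) == length(pct_hyper),
            all(direction %in% c("up", "down")),
            threshold > 50, threshold <= 100)
  lo <- 100 - threshold
  dplyr::case_when(
    direction == "up" & pct_hyper <= lo ~ "concordant_up",
    direction == "down" & pct_hyper >= threshold ~ "concordant_down",
    direction == "up" & pct_hyper >= threshold ~ "discordant_up",
    direction == "down" & pct_hyper <= lo ~ "discordant_down",
    TRUE ~ "unclassified"
  )
}

concordance_classes <- c("concordant_up", "concordant_down",
                         "discordant_up", "discordant_down", "unclassified")

#' Merge filtered DE genes with promoter methylation profiles
#'
#' Inner-joins the DE genes that passed [filter_de()] with the promoter
#' profiles that passed the minimum-site filter and classifies each with
#' [classify_concordance()].
#'
#' @param de_filtered Output of [filter_de()].
#' @param profiles Output of [promoter_profiles()].
#' @param threshold Concordance threshold percentage (default 90).
#' @return Tibble with columns `gene_id`, `chrom`, `fold_change`,
#'   `direction`, `n_sites`, `pct_hyper`, `class`.
#' @export
integrate_expression_methylation <- function(de_filtered, profiles,
                                             threshold = 90) {
  merged <- dplyr::inner_join(
    de_filtered[, c("gene_id", "fold_change", "direction")],
    profiles[, c("gene_id", "chrom", "n_sites", "pct_hyper")],
    by = "gene_id")
  merged$class <- classify_concordance(merged$direction, merged$pct_hyper,
                                       threshold = threshold)
  merged[, c("gene_id", "chrom", "fold_change", "direction", "n_sites",
             "pct_hyper", "class")]
}

#' Concordance class counts and report table
#'
#' Summarises classified records into per-class counts (all five classes,
#' zeros included) and a report table sorted by fold change ascending — from
#' the strongest down-regulation to the strongest up-regulation — with the
#' hyper-methylated-site percentage rounded to 4 decimal places.
#'
#' @param records Output of [integrate_expression_methylation()].
#' @return List with elements `counts` (tibble `class`, `n`) and `table`
#'   (tibble `chrom`, `gene_id`, `fold_change`, `n_sites`, `pct_hyper`,
#'   `class`).
#' @export
concordance_report <- function(records) {
  counts <- tibble::tibble(
    class = concordance_classes,
    n = unname(vapply(concordance_classes,
                      function(cl) sum(records$class == cl), integer(1)))
  )
  tab <- records[order(records$fold_change, records$gene_id),
                 c("chrom", "gene_id", "fold_change", "n_sites", "pct_hyper",
                   "class")]
  tab$pct_hyper <- round(tab$pct_hyper, 4)
  list(counts = counts, table = tibble::as_tibble(tab))
}
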