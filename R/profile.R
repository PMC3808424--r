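#' Per-site methylation change between conditions
#'
#' Computes `delta = m_treated - m_control` for every coverage-filtered site
#' together with a direction call (`hyper` for delta > 0, `hypo` for
#' delta < 0, `none` for exactly 0), a substantial-change flag at
#' `change_cutoff` (default 20 percentage points on the absolute fraction
#' scale) and the annotation context from [annotate_sites()]. Sites on the
#' reserved `spikein` contig or on chromosomes missing from the annotation
#' are kept with `NA` context so they still count in genome-wide totals.
#'
#' @param wide Output of [methylation_wide()] (optionally coverage-filtered).
#' @param ann A `genome_annotation`, or `NULL` to skip annotation context.
#' @param sites Site coordinate tibble (`site_id`, `chrom`, `pos`); required
#'   when `ann` is supplied.
#' @param change_cutoff Absolute methylation-fraction change regarded as
#'   substantial (default 0.2).
#' @param upstream,downstream Promoter extent in bp.
#' @return Tibble with columns `site_id`, `delta`, `direction`,
#'   `substantial`, `in_island`, `promoter_gene`, `in_promoter`,
#'   `nearest_gene`, `tss_distance`, `reads_control`, `reads_treated`,
#'   `m_control`, `m_treated`.
#' @export
site_deltas <- function(wide, ann = NULL, sites = NULL, change_cutoff = 0.2,
                        upstream = 1500, downstream = 500) {
  delta <- wide$m_treated - wide$m_control
  out <- tibble::tibble(
    site_id = wide$site_id,
    m_control = wide$m_control,
    m_treated = wide$m_treated,
    reads_control = wide$reads_control,
    reads_treated = wide$reads_treated,
    delta = delta,
    direction = dplyr::case_when(delta > 0 ~ "hyper",
                                 delta < 0 ~ "hypo",
                                 TRUE ~ "none"),
    substantial = abs(delta) >= change_cutoff
  )
  if (!is.null(ann)) {
    if (is.null(sites)) stop("site coordinates are required when an annotation is supplied")
    split <- split_placeable_sites(wide$site_id, sites, ann)
    ctx <- annotate_sites(split$known, ann,
                          upstream = upstream, downstream = downstream)
    ctx <- dplyr::bind_rows(ctx[, c("site_id", "in_island", "nearest_gene",
                                    "tss_distance", "in_promoter",
                                    "promoter_gene")],
                            split$missing)
    out <- dplyr::left_join(out, ctx[, c("site_id", "in_island", "nearest_gene",
                                         "tss_distance", "in_promoter",
                                         "promoter_gene")],
                            by = "site_id")
  } else {
    out$in_island <- NA
    out$nearest_gene <- NA_character_
    out$tss_distance <- NA_integer_
    out$in_promoter <- NA
    out$promoter_gene <- NA_character_
  }
  out
}

# Split site ids into those the annotation can place and a flagged-missing
# remainder (spike-in contig, unknown chromosome, or no coordinates at all).
# Missing sites keep NA context so they still count in genome-wide totals.
split_placeable_sites <- function(site_ids, sites, ann) {
  known <- sites[sites$site_id %in% site_ids &
                   sites$chrom %in% ann$chromosomes$chrom, , drop = FALSE]
  missing_ids <- setdiff(site_ids, known$site_id)
  missing <- tibble::tibble(site_id = missing_ids, in_island = NA,
                            nearest_gene = NA_character_,
                            tss_distance = NA_integer_, in_promoter = NA,
                            promoter_gene = NA_character_)
  list(known = known, missing = missing)
}

#' Region-stratified hyper/hypo methylation counts
#'
#' Counts hyper- and hypo-methylated sites within a genomic stratum at a
#' coverage threshold and a substantial-change cutoff. Strata:
#' `genome` (all sites), `promoter` (sites assigned to a promoter window),
#' `island` (sites inside a CpG island), `island_near_tss` (island sites
#' within 1500 bp of the nearest TSS). At `change_cutoff = 0` every nonzero
#' delta is counted and `n_hyper + n_hypo + n_none = n_total`; at a positive
#' cutoff only `|delta| >= change_cutoff` contributes to the directional
#' counts while `n_total` still counts every covered site in the stratum.
#'
#' @param deltas Output of [site_deltas()].
#' @param stratum One of `"genome"`, `"promoter"`, `"island"`,
#'   `"island_near_tss"`.
#' @param coverage_threshold Minimum combined reads per condition
#'   (default 30).
#' @param change_cutoff Minimum `|delta|` for a directional call (default 0).
#' @param tss_window Half-width in bp of the near-TSS restriction
#'   (default 1500).
#' @return One-row tibble: `stratum`, `coverage_threshold`, `change_cutoff`,
#'   `n_total`, `n_hyper`, `n_hypo`, `n_none`.
#' @export
summarize_region <- function(deltas, stratum = c("genome", "promoter", "island",
                                                 "island_near_tss"),
                             coverage_threshold = 30, change_cutoff = 0,
                             tss_window = 1500) {
  stratum <- match.arg(stratum)
  d <- deltas[deltas$reads_control >= coverage_threshold &
                deltas$reads_treated >= coverage_threshold, , drop = FALSE]
  keep <- switch(stratum,
    genome = rep(TRUE, nrow(d)),
    promoter = !is.na(d$in_promoter) & d$in_promoter,
    island = !is.na(d$in_island) & d$in_island,
    island_near_tss = !is.na(d$in_island) & d$in_island &
      !is.na(d$tss_distance) & abs(d$tss_distance) <= tss_window
  )
  d <- d[keep, , drop = FALSE]
  called <- abs(d$delta) >= change_cutoff
  tibble::tibble(
    stratum = stratum,
    coverage_threshold = coverage_threshold,
    change_cutoff = change_cutoff,
    n_total = nrow(d),
    n_hyper = sum(called & d$delta > 0),
    n_hypo = sum(called & d$delta < 0),
    n_none = nrow(d) - sum(called & d$delta != 0)
  )
}

#' Grid of region summaries across strata and thresholds
#'
#' @param deltas Output of [site_deltas()].
#' @param strata Character vector of strata (default all four).
#' @param coverage_thresholds Integer vector (default `c(30, 60, 100)`).
#' @param change_cutoffs Numeric vector (default `c(0, 0.2)`).
#' @return Tibble with one row per combination.
#' @export
summarize_regions <- function(deltas,
                              strata = c("genome", "promoter", "island",
                                         "island_near_tss"),
                              coverage_thresholds = c(30, 60, 100),
                              change_cutoffs = c(0, 0.2)) {
  grid <- expand.grid(stratum = strata, coverage_threshold = coverage_thresholds,
                      change_cutoff = change_cutoffs,
                      stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    summarize_region(deltas, grid$stratum[i], grid$coverage_threshold[i],
                     grid$change_cutoff[i])
  }))
}

#' Methylation change as a function of distance to the nearest TSS
#'
#' One row per site with a resolvable nearest gene; sites flagged missing
#' (no gene on the chromosome, or unplaceable site id) are excluded.
#'
#' @param deltas Output of [site_deltas()].
#' @return Tibble with columns `site_id`, `tss_distance`, `delta`,
#'   `in_island`, `in_promoter`.
#' @export
tss_profile <- function(deltas) {
  d <- deltas[!is.na(deltas$tss_distance), , drop = FALSE]
  tibble::tibble(site_id = d$site_id, tss_distance = d$tss_distance,
                 delta = d$delta, in_island = d$in_island,
                 in_promoter = d$in_promoter)
}
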