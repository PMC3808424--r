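#' Load the packaged hypoxia concordant-gene example table
#'
#' A 59-row reference table from a published MSCC study of post-hypoxic
#' mouse hippocampal cells: for each gene with a significant expression
#' change and at least two measured promoter CCGG sites, the expression fold
#' change (hypoxic/control), the number of measured promoter sites, and the
#' percentage of those sites that were hyper-methylated. It serves as a
#' worked example for [classify_concordance()]: replaying it yields 53
#' up-regulated genes with hypomethylated promoters and 6 down-regulated
#' genes with hypermethylated promoters.
#'
#' @return Tibble with columns `chrom`, `gene_id`, `fold_change`, `n_sites`,
#'   `pct_hyper`.
#' @export
load_concordant_gene_example <- function() {
  path <- system.file("extdata", "hypoxia_concordant_genes.tsv",
                      package = "msccpipe", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           gene_id = readr::col_character(),
                           fold_change = readr::col_double(),
                           n_sites = readr::col_integer(),
                           pct_hyper = readr::col_double()
                         ))
  if (nrow(tab) != 59 || anyNA(tab) ||
      any(tab$fold_change <= 0) || any(tab$n_sites < 2) ||
      any(tab$pct_hyper < 0 | tab$pct_hyper > 100)) {
    stop("packaged concordant-gene table failed its integrity check")
  }
  tab
}

#' Classify a ready-made gene table of fold changes and promoter percentages
#'
#' Entry point for tables that already carry per-gene fold change, measured
#' promoter site count and hyper-methylated-site percentage (such as the
#' packaged example). Applies the expression filter of [filter_de()]
#' (p-values taken as passing when absent), the minimum-site filter and
#' [classify_concordance()].
#'
#' @param tab Tibble with `gene_id`, `fold_change`, `n_sites`, `pct_hyper`
#'   and optionally `chrom`, `p_value`.
#' @param threshold Concordance threshold percentage (default 90).
#' @param min_sites Minimum measured promoter sites (default 2).
#' @param fc_min Fold-change threshold (default 1.5).
#' @param p_max Significance threshold applied when a `p_value` column is
#'   present (default 0.05).
#' @return Tibble as from [integrate_expression_methylation()].
#' @export
classify_gene_table <- function(tab, threshold = 90, min_sites = 2,
                                fc_min = 1.5, p_max = 0.05) {
  if (!"p_value" %in% names(tab)) tab$p_value <- 0
  if (!"chrom" %in% names(tab)) tab$chrom <- NA_character_
  de <- filter_de(tab[, c("gene_id", "fold_change", "p_value")],
                  p_max = p_max, fc_min = fc_min)
  prof <- tab[tab$n_sites >= min_sites,
              c("gene_id", "chrom", "n_sites", "pct_hyper")]
  integrate_expression_methylation(de, prof, threshold = threshold)
}

#' Pipeline configuration
#'
#' Collects the input paths and every analysis threshold for
#' [run_pipeline()].
#'
#' @param counts Path to the two-library counts TSV.
#' @param genes Path to the gene table (TSV or GTF).
#' @param islands Path to the island BED file.
#' @param sites Path to the CCGG site BED/TSV.
#' @param chromosomes Path to a chromosome-length TSV (`chrom`, `length`).
#' @param de_table Path to the DE results TSV.
#' @param library_info Optional path to per-library totals; column sums of
#'   the counts table are used when `NULL`.
#' @param out_dir Output directory.
#' @param min_reads Coverage filter (default 30).
#' @param change_cutoff Substantial-change cutoff (default 0.2).
#' @param p_max,fc_min Expression filter thresholds (defaults 0.05, 1.5).
#' @param min_promoter_sites Minimum measured promoter sites (default 2).
#' @param concordance_threshold Concordance threshold percentage
#'   (default 90).
#' @param site_change_cutoff Minimum `|delta|` for promoter site direction
#'   calls (default 0).
#' @param calibrate Apply the spike-in calibration to methylation estimates
#'   (default `FALSE`).
#' @param conditions Names of the control and treated condition.
#' @return A list of class `mscc_pipeline_config`.
#' @export
mscc_pipeline_config <- function(counts, genes, islands, sites, chromosomes,
                                 de_table, library_info = NULL,
                                 out_dir = "mscc_out",
                                 min_reads = 30, change_cutoff = 0.2,
                                 p_max = 0.05, fc_min = 1.5,
                                 min_promoter_sites = 2,
                                 concordance_threshold = 90,
                                 site_change_cutoff = 0,
                                 calibrate = FALSE,
                                 conditions = c("control", "hypoxic")) {
  cfg <- as.list(environment())
  stopifnot(min_reads >= 0, change_cutoff >= 0, change_cutoff <= 1,
            p_max > 0, p_max <= 1, fc_min >= 1,
            min_promoter_sites >= 0,
            concordance_threshold > 50, concordance_threshold <= 100)
  for (f in c("counts", "genes", "islands", "sites", "chromosomes",
              "de_table")) {
    if (!file.exists(cfg[[f]])) {
      stop("input file for '", f, "' not found: ", cfg[[f]])
    }
  }
  if (!is.null(library_info) && !file.exists(library_info)) {
    stop("input file for 'library_info' not found: ", library_info)
  }
  structure(cfg, class = "mscc_pipeline_config")
}

#' Run the full MSCC analysis chain
#'
#' Executes quantify (methylation estimation + coverage filter), profile
#' (per-site deltas, region summaries, TSS profile), expression filter and
#' integration in order, writing each stage's TSV output plus a run manifest
#' with input checksums and the thresholds used. Reruns on identical inputs
#' are byte-identical; the analysis stages use no randomness.
#'
#' @param cfg An `mscc_pipeline_config`.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the in-memory stage results:
#'   `methylation`, `deltas`, `summaries`, `tss_profile`, `de_filtered`,
#'   `promoter_profiles`, `concordance`, `report`, `calibration`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "mscc_pipeline_config"))
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("load", "reading inputs")
  counts <- read_counts(cfg$counts)
  genes <- read_genes(cfg$genes)
  islands <- read_islands(cfg$islands)
  sites <- read_sites(cfg$sites)
  chromosomes <- readr::read_tsv(cfg$chromosomes, comment = "#",
                                 show_col_types = FALSE)
  de <- read_de_table(cfg$de_table)
  lib_info <- if (is.null(cfg$library_info)) NULL else
    read_library_info(cfg$library_info)
  ann <- genome_annotation(chromosomes, genes, islands)

  say("quantify", "estimating per-site methylation")
  est <- estimate_methylation(counts, lib_info)
  calibration <- NULL
  if (cfg$calibrate) {
    sp <- spikein_estimates(est)
    if (nrow(sp) < 4) {
      warning("fewer than 4 spike-in standards found; raw estimates used")
    } else {
      calibration <- fit_calibration(sp$m_hat, sp$true_fraction)
      est$m_hat <- apply_calibration(est$m_hat, calibration)
    }
  }
  wide <- methylation_wide(est, conditions = cfg$conditions)
  wide <- wide[!grepl("^spikein_", wide$site_id), , drop = FALSE]
  covered <- filter_coverage(wide, min_reads = cfg$min_reads)
  write_stage_tsv(covered, file.path(cfg$out_dir, "methylation.tsv"))

  say("profile", "computing methylation changes and region summaries")
  deltas <- site_deltas(covered, ann, sites, change_cutoff = cfg$change_cutoff)
  summaries <- summarize_regions(deltas)
  prof <- tss_profile(deltas)
  write_stage_tsv(deltas, file.path(cfg$out_dir, "site_deltas.tsv"))
  write_stage_tsv(summaries, file.path(cfg$out_dir, "region_summaries.tsv"))
  write_stage_tsv(prof, file.path(cfg$out_dir, "tss_profile.tsv"))

  say("de-filter", "filtering the expression table")
  de_kept <- filter_de(de, p_max = cfg$p_max, fc_min = cfg$fc_min)
  write_stage_tsv(de_kept, file.path(cfg$out_dir, "de_filtered.tsv"))

  say("integrate", "classifying methylation-expression concordance")
  profs <- promoter_profiles(deltas, sites, ann,
                             min_sites = cfg$min_promoter_sites,
                             site_change_cutoff = cfg$site_change_cutoff)
  records <- integrate_expression_methylation(
    de_kept, profs, threshold = cfg$concordance_threshold)
  report <- concordance_report(records)
  write_stage_tsv(profs, file.path(cfg$out_dir, "promoter_profiles.tsv"))
  write_stage_tsv(report$table, file.path(cfg$out_dir, "concordance.tsv"))
  write_stage_tsv(report$counts, file.path(cfg$out_dir, "class_counts.tsv"))

  inputs <- c(counts = cfg$counts, genes = cfg$genes, islands = cfg$islands,
              sites = cfg$sites, chromosomes = cfg$chromosomes,
              de_table = cfg$de_table)
  manifest <- tibble::tibble(
    key = c("package_version", "min_reads", "change_cutoff", "p_max",
            "fc_min", "min_promoter_sites", "concordance_threshold",
            "site_change_cutoff", "calibrate",
            paste0("md5_", names(inputs))),
    value = c(as.character(utils::packageVersion("msccpipe")),
              cfg$min_reads, cfg$change_cutoff, cfg$p_max, cfg$fc_min,
              cfg$min_promoter_sites, cfg$concordance_threshold,
              cfg$site_change_cutoff, cfg$calibrate,
              unname(tools::md5sum(inputs)))
  )
  write_stage_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  say("done", "outputs in ", cfg$out_dir)

  invisible(list(methylation = covered, deltas = deltas,
                 summaries = summaries, tss_profile = prof,
                 de_filtered = de_kept, promoter_profiles = profs,
                 concordance = records, report = report,
                 calibration = calibration, manifest = manifest))
}
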