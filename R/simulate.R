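clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Configuration for the MSCC data simulator
#'
#' Defines the generative conditions for a synthetic two-library MSCC
#' experiment: a small genome with genes and CpG islands, a bimodal baseline
#' methylome (island sites hypomethylated, open-genome sites methylated),
#' condition-dependent hypomethylation targeted at a fraction of promoters,
#' Poisson tag counts from a sensitive and an insensitive library with
#' optional depth asymmetry, four internal calibration standards, and a
#' differential-expression table with known truth labels.
#'
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp, recycled over chromosomes
#'   (default 1e6).
#' @param n_genes,n_islands,n_sites Numbers of genes, CpG islands and CCGG
#'   sites (defaults 100, 60, 5000).
#' @param island_width Range (min, max) of island widths in bp
#'   (default 500-2000).
#' @param island_promoter_overlap Probability that an island is anchored on
#'   a randomly chosen promoter rather than placed uniformly (default 0.7).
#' @param island_density_ratio Relative CCGG site density per bp inside
#'   islands versus outside (default 8; CpG-dense islands carry more CCGG
#'   motifs).
#' @param promoter_site_floor Guaranteed number of sites placed inside every
#'   promoter window before density-based placement (default 0).
#' @param baseline_meth List with Beta shape pairs `island` and `open` for
#'   the two baseline components (defaults `c(1.5, 15)`, mean ~0.09, and
#'   `c(8, 2)`, mean 0.8).
#' @param prop_promoters_shifted Fraction of genes whose promoter sites are
#'   shifted in the treated condition (default 0.2).
#' @param shift_size Signed methylation-fraction shift applied to those
#'   sites, clamped to `[0, 1]` (default -0.4, i.e. hypomethylation).
#' @param noise_sd Standard deviation of the symmetric noise added to
#'   non-shifted sites in the treated condition, clamped to `[0, 1]`
#'   (default 0.02).
#' @param mean_site_depth Expected tags per site in the sensitive library
#'   (default 50).
#' @param depth_asymmetry Ratio of insensitive- to sensitive-library depth
#'   (default 1; values other than 1 exercise the library-size
#'   normalization).
#' @param spikein_depth Expected tags per library for the calibration
#'   standards (default 1000).
#' @param de_fraction Fraction of genes that are differentially expressed
#'   (default 0.1, split evenly between up and down).
#' @param lfc_scale Spread of log fold changes beyond the 1.5x threshold
#'   (default 0.5).
#' @return An object of class `mscc_sim_config`.
#' @export
mscc_sim_config <- function(seed = 1, n_chrom = 2, chrom_length = 1e6,
                            n_genes = 100, n_islands = 60, n_sites = 5000,
                            island_width = c(500, 2000),
                            island_promoter_overlap = 0.7,
                            island_density_ratio = 8,
                            promoter_site_floor = 0,
                            baseline_meth = list(island = c(1.5, 15),
                                                 open = c(8, 2)),
                            prop_promoters_shifted = 0.2,
                            shift_size = -0.4, noise_sd = 0.02,
                            mean_site_depth = 50, depth_asymmetry = 1,
                            spikein_depth = 1000,
                            de_fraction = 0.1, lfc_scale = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chrom >= 1, cfg$n_genes >= 1, cfg$n_sites >= 1,
            cfg$mean_site_depth > 0, cfg$depth_asymmetry > 0,
            cfg$spikein_depth > 0,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$prop_promoters_shifted >= 0, cfg$prop_promoters_shifted <= 1,
            cfg$island_promoter_overlap >= 0, cfg$island_promoter_overlap <= 1,
            cfg$noise_sd >= 0, cfg$island_density_ratio > 0,
            cfg$lfc_scale > 0, cfg$promoter_site_floor >= 0)
  structure(cfg, class = "mscc_sim_config")
}

#' @export
print.mscc_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<mscc_sim_config> seed %d: %d chrom x %g bp, %d genes, ",
                     "%d islands, %d sites, depth %g\n"),
              x$seed, x$n_chrom, x$chrom_length[1], x$n_genes, x$n_islands,
              x$n_sites, x$mean_site_depth))
  invisible(x)
}

#' Simulate a genome annotation and CCGG site set
#'
#' Places genes without TSS collisions, islands preferentially anchored over
#' promoter windows, and CCGG sites with elevated density inside islands
#' (controlled by `island_density_ratio`). Seeds the RNG from `cfg$seed`, so
#' two calls with the same config are identical.
#'
#' @param cfg An `mscc_sim_config`.
#' @return List with elements `ann` (a `genome_annotation`) and `sites`
#'   (tibble `site_id`, `chrom`, `pos`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "mscc_sim_config"))
  set.seed(cfg$seed)
  lens <- rep_len(cfg$chrom_length, cfg$n_chrom)
  chromosomes <- tibble::tibble(chrom = paste0("chr", seq_len(cfg$n_chrom)),
                                length = as.integer(lens))
  if (cfg$n_sites + cfg$n_genes * cfg$promoter_site_floor > sum(lens)) {
    stop("infeasible site density: more sites requested than base pairs")
  }
  # genes: margin 2000 bp from the ends so promoter windows rarely clip
  genes <- tibble::tibble(
    gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
    chrom = sample(chromosomes$chrom, cfg$n_genes, replace = TRUE,
                   prob = chromosomes$length),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    tss = NA_integer_
  )
  len_of <- stats::setNames(chromosomes$length, chromosomes$chrom)
  repeat {
    miss <- is.na(genes$tss)
    if (!any(miss)) break
    genes$tss[miss] <- as.integer(floor(stats::runif(
      sum(miss), 2000, unname(len_of[genes$chrom[miss]]) - 2000)))
    dup <- duplicated(genes[, c("chrom", "tss")])
    genes$tss[dup] <- NA_integer_
  }
  pw <- promoter_windows(genes, chrom_lengths = len_of)

  islands <- NULL
  if (cfg$n_islands > 0) {
    widths <- as.integer(round(stats::runif(cfg$n_islands, cfg$island_width[1],
                                            cfg$island_width[2])))
    anchored <- stats::runif(cfg$n_islands) < cfg$island_promoter_overlap
    chrom <- character(cfg$n_islands)
    start <- integer(cfg$n_islands)
    host <- sample.int(cfg$n_genes, cfg$n_islands, replace = TRUE)
    for (i in seq_len(cfg$n_islands)) {
      if (anchored[i]) {
        chrom[i] <- genes$chrom[host[i]]
        center <- genes$tss[host[i]] + as.integer(round(stats::runif(1, -400, 400)))
        start[i] <- center - widths[i] %/% 2
      } else {
        chrom[i] <- sample(chromosomes$chrom, 1, prob = chromosomes$length)
        start[i] <- as.integer(floor(stats::runif(1, 0, len_of[chrom[i]] - widths[i])))
      }
    }
    islands <- tibble::tibble(chrom = chrom,
                              start = pmax(start, 0L)) |>
      dplyr::mutate(end = pmin(.data$start + widths, len_of[.data$chrom]),
                    end = as.integer(.data$end),
                    start = as.integer(.data$start))
  } else {
    islands <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer())
  }
  ann <- genome_annotation(chromosomes, genes, islands)

  # guaranteed promoter sites, then density-based placement
  floor_pos <- NULL
  if (cfg$promoter_site_floor > 0) {
    floor_pos <- dplyr::bind_rows(lapply(seq_len(nrow(pw)), function(i) {
      tibble::tibble(chrom = pw$chrom[i],
                     pos = sample(seq.int(pw$start[i], pw$end[i] - 1L),
                                  cfg$promoter_site_floor))
    }))
  }
  n_free <- cfg$n_sites - cfg$n_genes * cfg$promoter_site_floor
  placed <- if (is.null(floor_pos)) {
    tibble::tibble(chrom = character(), pos = integer())
  } else floor_pos
  placed <- dplyr::distinct(placed, .data$chrom, .data$pos)
  isl_red <- if (nrow(islands) > 0) {
    GenomicRanges::reduce(intervals_as_granges(islands))
  } else NULL
  li <- if (is.null(isl_red)) 0 else sum(BiocGenerics::width(isl_red))
  lo <- sum(lens) - li
  p_island <- cfg$island_density_ratio * li /
    (cfg$island_density_ratio * li + lo)
  iw <- if (is.null(isl_red)) integer() else BiocGenerics::width(isl_red)
  n_target <- nrow(placed) + max(n_free, 0)
  tries <- 0
  while (nrow(placed) < n_target && tries < 200) {
    tries <- tries + 1
    need <- n_target - nrow(placed)
    in_isl <- stats::runif(need) < p_island
    new <- tibble::tibble(chrom = character(need), pos = integer(need))
    if (any(in_isl)) {
      pick <- sample.int(length(iw), sum(in_isl), replace = TRUE, prob = iw)
      new$chrom[in_isl] <- as.character(GenomicRanges::seqnames(isl_red))[pick]
      new$pos[in_isl] <- as.integer(floor(
        BiocGenerics::start(isl_red)[pick] - 1L +
          stats::runif(sum(in_isl), 0, iw[pick])))
    }
    if (any(!in_isl)) {
      n_out <- sum(!in_isl)
      ch <- sample(chromosomes$chrom, n_out, replace = TRUE,
                   prob = chromosomes$length)
      po <- as.integer(floor(stats::runif(n_out, 0, len_of[ch])))
      cand <- tibble::tibble(chrom = ch, pos = po)
      hit <- if (is.null(isl_red)) rep(FALSE, n_out) else
        IRanges::overlapsAny(
          GenomicRanges::GRanges(cand$chrom,
                                 IRanges::IRanges(cand$pos + 1L, width = 1L)),
          isl_red)
      cand$pos[hit] <- NA_integer_  # rejected, refilled next round
      new[!in_isl, ] <- cand
    }
    new <- new[!is.na(new$pos), , drop = FALSE]
    placed <- dplyr::distinct(dplyr::bind_rows(placed, new),
                              .data$chrom, .data$pos)
  }
  if (nrow(placed) < n_target) stop("could not place the requested site count")
  placed <- dplyr::arrange(placed, .data$chrom, .data$pos)
  sites <- tibble::tibble(site_id = sprintf("site_%06d", seq_len(nrow(placed))),
                          chrom = placed$chrom, pos = placed$pos)
  list(ann = ann, sites = sites)
}

#' Simulate true per-site methylation fractions and gene truth labels
#'
#' Control fractions are drawn from the two-component baseline (island sites
#' from the low component, open-genome sites from the high one). A seeded
#' fraction of genes is flagged `promoter_shifted`: every site in such a
#' gene's promoter window gets `m_treated = clamp(m_control + shift_size)`;
#' all other sites get `m_control` plus truncated symmetric noise. Gene DE
#' status (`up` / `down` / `null`) is drawn independently.
#'
#' Randomness continues the ambient RNG stream; [simulate_mscc()] seeds it
#' once via [simulate_genome()].
#'
#' @param genome Output of [simulate_genome()].
#' @param cfg The `mscc_sim_config`.
#' @return List with `site_meth` (tibble `site_id`, `in_island`, `shifted`,
#'   `m_control`, `m_treated`) and `gene_truth` (tibble `gene_id`,
#'   `de_status`, `promoter_shifted`).
#' @export
simulate_methylome <- function(genome, cfg) {
  sites <- genome$sites
  ann <- genome$ann
  n <- nrow(sites)
  in_isl <- site_in_island(sites, ann)
  m_control <- numeric(n)
  m_control[in_isl] <- stats::rbeta(sum(in_isl), cfg$baseline_meth$island[1],
                                    cfg$baseline_meth$island[2])
  m_control[!in_isl] <- stats::rbeta(sum(!in_isl), cfg$baseline_meth$open[1],
                                     cfg$baseline_meth$open[2])
  genes <- ann$genes
  gene_truth <- tibble::tibble(
    gene_id = genes$gene_id,
    de_status = ifelse(stats::runif(nrow(genes)) < cfg$de_fraction,
                       sample(c("up", "down"), nrow(genes), replace = TRUE),
                       "null"),
    promoter_shifted = stats::runif(nrow(genes)) < cfg$prop_promoters_shifted
  )
  pw <- promoter_windows(ann)
  pw <- pw[pw$gene_id %in% gene_truth$gene_id[gene_truth$promoter_shifted], ,
           drop = FALSE]
  shifted <- if (nrow(pw) > 0) {
    IRanges::overlapsAny(sites_as_granges(sites),
                         intervals_as_granges(pw[, c("chrom", "start", "end")]))
  } else rep(FALSE, n)
  m_treated <- numeric(n)
  m_treated[shifted] <- clamp01(m_control[shifted] + cfg$shift_size)
  m_treated[!shifted] <- clamp01(m_control[!shifted] +
                                   stats::rnorm(sum(!shifted), 0, cfg$noise_sd))
  list(site_meth = tibble::tibble(site_id = sites$site_id,
                                  in_island = in_isl, shifted = shifted,
                                  m_control = m_control,
                                  m_treated = m_treated),
       gene_truth = gene_truth)
}

#' Simulate two-library tag counts and spike-in standards
#'
#' For each site and condition, the sensitive-library count is
#' `U ~ Poisson(d_U (1 - m))` and the insensitive-library count
#' `M ~ Poisson(d_M m)`, with `d_U = mean_site_depth` and
#' `d_M = mean_site_depth * depth_asymmetry`. The four calibration
#' standards (0, 1/3, 2/3, 1) are generated the same way at `spikein_depth`
#' with equal library depths and appended as ordinary count rows on the
#' reserved contig `spikein`.
#'
#' @param methylome Output of [simulate_methylome()] (its `site_meth`
#'   element, or the list itself).
#' @param cfg The `mscc_sim_config`.
#' @param conditions Names of the two conditions.
#' @return List with `counts` (tibble `site_id`, `condition`,
#'   `sensitive_count`, `insensitive_count`), `lib_info` (per-condition
#'   totals), and `spikeins` (tibble `site_id`, `chrom`, `pos`,
#'   `true_fraction`).
#' @export
simulate_site_counts <- function(methylome, cfg,
                                 conditions = c("control", "hypoxic")) {
  sm <- if (is.list(methylome) && !is.data.frame(methylome)) {
    methylome$site_meth
  } else methylome
  d_u <- cfg$mean_site_depth
  d_m <- cfg$mean_site_depth * cfg$depth_asymmetry
  spike <- tibble::tibble(
    site_id = c("spikein_0", "spikein_33", "spikein_67", "spikein_100"),
    chrom = "spikein", pos = 0:3,
    true_fraction = c(0, 1/3, 2/3, 1)
  )
  one_condition <- function(cond, m_col) {
    m <- sm[[m_col]]
    site_rows <- tibble::tibble(
      site_id = sm$site_id, condition = cond,
      sensitive_count = stats::rpois(length(m), d_u * (1 - m)),
      insensitive_count = stats::rpois(length(m), d_m * m)
    )
    sp_rows <- tibble::tibble(
      site_id = spike$site_id, condition = cond,
      sensitive_count = stats::rpois(4, cfg$spikein_depth * (1 - spike$true_fraction)),
      insensitive_count = stats::rpois(4, cfg$spikein_depth * spike$true_fraction)
    )
    dplyr::bind_rows(site_rows, sp_rows)
  }
  counts <- dplyr::bind_rows(one_condition(conditions[1], "m_control"),
                             one_condition(conditions[2], "m_treated"))
  counts$sensitive_count <- as.integer(counts$sensitive_count)
  counts$insensitive_count <- as.integer(counts$insensitive_count)
  lib_info <- counts |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(sensitive_total = sum(.data$sensitive_count),
                     insensitive_total = sum(.data$insensitive_count),
                     .groups = "drop")
  list(counts = counts, lib_info = lib_info, spikeins = spike)
}

#' Simulate a differential-expression results table with known truth
#'
#' Truth-up genes receive `fold_change = exp(log 1.5 + |N(0, lfc_scale)| *
#' log 1.5)` (always above the 1.5x threshold) and `p ~ Uniform(0, 0.05)`;
#' truth-down genes the reciprocal fold change with the same p-value law;
#' null genes a fold change near 1 (`exp(N(0, 0.1))`) and `p ~ Uniform(0, 1)`.
#'
#' @param gene_truth Tibble from [simulate_methylome()] with `gene_id`,
#'   `de_status`.
#' @param cfg The `mscc_sim_config`.
#' @return Tibble with columns `gene_id`, `fold_change`, `p_value`.
#' @export
simulate_de_table <- function(gene_truth, cfg) {
  n <- nrow(gene_truth)
  lfc_mag <- log(1.5) + abs(stats::rnorm(n, 0, cfg$lfc_scale)) * log(1.5)
  fc <- dplyr::case_when(
    gene_truth$de_status == "up" ~ exp(lfc_mag),
    gene_truth$de_status == "down" ~ exp(-lfc_mag),
    TRUE ~ exp(stats::rnorm(n, 0, 0.1))
  )
  p <- ifelse(gene_truth$de_status == "null",
              stats::runif(n), stats::runif(n, 0, 0.05))
  tibble::tibble(gene_id = gene_truth$gene_id, fold_change = fc, p_value = p)
}

#' Run the full MSCC simulation
#'
#' Seeds the RNG once from `cfg$seed` (inside [simulate_genome()]) and
#' chains genome, methylome, tag-count and DE-table simulation, so the whole
#' bundle is reproducible from `(seed, cfg)`.
#'
#' @param cfg An `mscc_sim_config`.
#' @return List with elements `config`, `ann`, `sites`, `site_meth`,
#'   `gene_truth`, `counts`, `lib_info`, `spikeins`, `de_table`.
#' @export
simulate_mscc <- function(cfg = mscc_sim_config()) {
  genome <- simulate_genome(cfg)
  meth <- simulate_methylome(genome, cfg)
  cnt <- simulate_site_counts(meth, cfg)
  de <- simulate_de_table(meth$gene_truth, cfg)
  list(config = cfg, ann = genome$ann, sites = genome$sites,
       site_meth = meth$site_meth, gene_truth = meth$gene_truth,
       counts = cnt$counts, lib_info = cnt$lib_info,
       spikeins = cnt$spikeins, de_table = de)
}

#' Write a simulation bundle to disk
#'
#' Emits the deterministic TSV/BED files the analysis stages read:
#' `chromosomes.tsv`, `genes.tsv`, `islands.bed`, `sites.bed`,
#' `counts.tsv`, `library_info.tsv`, `de_table.tsv`, plus the truth tables
#' `truth_sites.tsv` and `truth_genes.tsv`.
#'
#' @param sim Output of [simulate_mscc()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(sim$ann$chromosomes, p("chromosomes.tsv"))
  readr::write_tsv(sim$ann$genes, p("genes.tsv"))
  isl <- sim$ann$islands
  readr::write_tsv(isl, p("islands.bed"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(chrom = sim$sites$chrom,
                                  start = sim$sites$pos,
                                  end = sim$sites$pos + 1L,
                                  name = sim$sites$site_id),
                   p("sites.bed"), col_names = FALSE)
  readr::write_tsv(sim$counts, p("counts.tsv"))
  readr::write_tsv(sim$lib_info, p("library_info.tsv"))
  readr::write_tsv(sim$de_table, p("de_table.tsv"))
  readr::write_tsv(sim$site_meth, p("truth_sites.tsv"))
  readr::write_tsv(sim$gene_truth, p("truth_genes.tsv"))
  invisible(dir)
}
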