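wide_row <- function(id, m_ctl, m_trt, reads = 100L) {
  tibble::tibble(site_id = id, m_control = m_ctl, m_treated = m_trt,
                 reads_control = reads, reads_treated = reads)
}

test_that("per-site deltas carry direction and the substantial-change flag", {
  wide <- dplyr::bind_rows(wide_row("drop", 0.8, 0.3),
                           wide_row("flat", 0.4, 0.4),
                           wide_row("small", 0.5, 0.6))
  d <- site_deltas(wide, change_cutoff = 0.2)
  expect_equal(d$delta, c(-0.5, 0, 0.1))
  expect_equal(d$direction, c("hypo", "none", "hyper"))
  expect_equal(d$substantial, c(TRUE, FALSE, FALSE))
})

test_that("direction counts equal a brute-force recount on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 300
    wide <- tibble::tibble(site_id = sprintf("s%03d", 1:n),
                           m_control = round(runif(n), 2),
                           m_treated = round(runif(n), 2),
                           reads_control = 100L, reads_treated = 100L)
    d <- site_deltas(wide)
    delta <- wide$m_treated - wide$m_control
    expect_equal(sum(d$direction == "hyper"), sum(delta > 0))
    expect_equal(sum(d$direction == "hypo"), sum(delta < 0))
    expect_equal(sum(d$direction == "none"), sum(delta == 0))
  }
})

test_that("region summaries respect their counting identities", {
  set.seed(22)
  ann <- random_annotation(n_genes = 25, n_islands = 12)
  sites <- random_sites(800, ann)
  wide <- tibble::tibble(site_id = sites$site_id,
                         m_control = runif(nrow(sites)),
                         m_treated = runif(nrow(sites)),
                         reads_control = rpois(nrow(sites), 60),
                         reads_treated = rpois(nrow(sites), 60))
  d <- site_deltas(wide, ann, sites)
  all_sum <- summarize_regions(d)
  # cutoff 0: hyper + hypo + none = total in every stratum
  at0 <- all_sum[all_sum$change_cutoff == 0, ]
  expect_true(all(at0$n_hyper + at0$n_hypo + at0$n_none == at0$n_total))
  # positive cutoff: directional counts only include |delta| >= cutoff
  at2 <- all_sum[all_sum$change_cutoff == 0.2, ]
  for (i in seq_len(nrow(at2))) {
    strat <- at2$stratum[i]
    thr <- at2$coverage_threshold[i]
    ref <- summarize_region(d, strat, thr, 0)
    expect_lte(at2$n_hyper[i] + at2$n_hypo[i], ref$n_hyper + ref$n_hypo)
  }
  # raising the coverage threshold never increases totals
  for (strat in unique(all_sum$stratum)) {
    tot <- at0$n_total[at0$stratum == strat][order(c(30, 60, 100))]
    expect_true(all(diff(tot) <= 0))
  }
  # each sub-stratum is bounded by the genome stratum
  genome_tot <- at0$n_total[at0$stratum == "genome" & at0$coverage_threshold == 30]
  expect_true(all(at0$n_total[at0$coverage_threshold == 30] <= genome_tot))
  # hand recount of the cutoff behaviour on the genome stratum
  covered <- d[d$reads_control >= 30 & d$reads_treated >= 30, ]
  s <- summarize_region(d, "genome", 30, 0.2)
  expect_equal(s$n_hyper, sum(covered$delta >= 0.2))
  expect_equal(s$n_hypo, sum(covered$delta <= -0.2))
})

test_that("an empty stratum reports zero counts", {
  wide <- wide_row("s1", 0.2, 0.9)
  ann <- genome_annotation(
    tibble::tibble(chrom = "chr1", length = 50000L),
    tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+", tss = 40000L),
    tibble::tibble(chrom = character(), start = integer(), end = integer()))
  d <- site_deltas(wide, ann, tibble::tibble(site_id = "s1", chrom = "chr1",
                                             pos = 100L))
  s <- summarize_region(d, "island")
  expect_equal(c(s$n_total, s$n_hyper, s$n_hypo), c(0L, 0L, 0L))
})

test_that("a promoter-targeted hypomethylation shift dominates the island stratum", {
  # ten genes, each with an island fully inside its promoter window; all
  # promoters shifted by -0.4 from a methylated baseline
  n_genes <- 10
  tss <- seq(10000L, by = 20000L, length.out = n_genes)
  ann <- genome_annotation(
    tibble::tibble(chrom = "chr1", length = 300000L),
    tibble::tibble(gene_id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                   strand = "+", tss = tss),
    tibble::tibble(chrom = "chr1", start = tss - 600L, end = tss)
  )
  set.seed(23)
  in_isl <- unlist(lapply(tss, function(t) t - sample.int(600, 8)))
  out_isl <- seq(5000L, 295000L, by = 3500L)
  out_isl <- setdiff(out_isl, in_isl)
  sites <- tibble::tibble(chrom = "chr1", pos = sort(c(in_isl, out_isl)))
  sites$site_id <- sprintf("s%04d", seq_len(nrow(sites)))
  genome <- list(ann = ann, sites = sites)
  cfg <- mscc_sim_config(prop_promoters_shifted = 1, shift_size = -0.4,
                         baseline_meth = list(island = c(8, 2), open = c(8, 2)),
                         mean_site_depth = 200)
  meth <- simulate_methylome(genome, cfg)
  cnt <- simulate_site_counts(meth, cfg)
  # equal library depths: pass depth-matched totals so the normalization
  # is neutral and the test isolates the stratum counting
  lib <- tibble::tibble(condition = c("control", "hypoxic"),
                        sensitive_total = 1e6, insensitive_total = 1e6)
  est <- estimate_methylation(cnt$counts, lib)
  wide <- filter_coverage(methylation_wide(est), 30)
  wide <- wide[!grepl("^spikein", wide$site_id), ]
  d <- site_deltas(wide, ann, sites)
  s <- summarize_region(d, "island", 30, 0.2)
  expect_gt(s$n_total, 0)
  expect_gte(s$n_hypo / s$n_total, 0.85)
})

test_that("the TSS profile covers exactly the sites with a resolvable gene", {
  ann <- genome_annotation(
    tibble::tibble(chrom = c("chr1", "chr2"), length = 50000L),
    tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000L),
    tibble::tibble(chrom = "chr1", start = 9000L, end = 10050L))
  sites <- tibble::tibble(site_id = c("at_tss", "near", "orphan"),
                          chrom = c("chr1", "chr1", "chr2"),
                          pos = c(10000L, 9100L, 100L))
  wide <- dplyr::bind_rows(wide_row("at_tss", 0.5, 0.1),
                           wide_row("near", 0.5, 0.9),
                           wide_row("orphan", 0.5, 0.5))
  d <- site_deltas(wide, ann, sites)
  prof <- tss_profile(d)
  # orphan site (gene-less chromosome) is excluded; bookkeeping holds
  expect_equal(nrow(prof), nrow(d) - sum(is.na(d$tss_distance)))
  expect_true(any(prof$tss_distance == 0))
  expect_false("orphan" %in% prof$site_id)
  # island rows within 1500 bp of the TSS match the island_near_tss stratum
  near <- prof[prof$in_island & abs(prof$tss_distance) <= 1500, ]
  s <- summarize_region(d, "island_near_tss", 30, 0)
  expect_equal(nrow(near), s$n_total)
})
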