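test_that("the simulation is fully reproducible from its seed", {
  cfg <- mscc_sim_config(seed = 1, n_sites = 1000, n_genes = 20, n_islands = 15)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  s1 <- simulate_mscc(cfg)
  s2 <- simulate_mscc(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$de_table, s2$de_table)
  # a different seed changes the outputs
  s3 <- simulate_mscc(mscc_sim_config(seed = 2, n_sites = 1000, n_genes = 20,
                                      n_islands = 15))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("genome simulation respects island structure and feasibility", {
  no_isl <- simulate_genome(mscc_sim_config(seed = 3, n_islands = 0,
                                            n_sites = 500, n_genes = 10))
  expect_false(any(site_in_island(no_isl$sites, no_isl$ann)))
  expect_error(simulate_genome(mscc_sim_config(seed = 1, n_chrom = 1,
                                               chrom_length = 5000,
                                               n_sites = 6000)),
               "infeasible")
  cfg <- mscc_sim_config(seed = 4, n_genes = 10, promoter_site_floor = 5,
                         n_sites = 500)
  g <- simulate_genome(cfg)
  pw <- promoter_windows(g$ann)
  per_gene <- vapply(seq_len(nrow(pw)), function(i) {
    sum(g$sites$chrom == pw$chrom[i] &
          g$sites$pos >= pw$start[i] & g$sites$pos < pw$end[i])
  }, numeric(1))
  expect_true(all(per_gene >= 5))
})

test_that("site density inside islands matches the configured ratio", {
  cfg <- mscc_sim_config(seed = 5, n_sites = 10000, n_chrom = 2,
                         chrom_length = 2e6, n_islands = 40,
                         island_density_ratio = 8)
  g <- simulate_genome(cfg)
  in_isl <- site_in_island(g$sites, g$ann)
  isl <- g$ann$islands
  red <- IRanges::reduce(IRanges::IRanges(isl$start + 1L, isl$end))
  li <- sum(IRanges::width(red))
  lo <- sum(g$ann$chromosomes$length) - li
  p <- 8 * li / (8 * li + lo)
  n <- nrow(g$sites)
  # observed in-island share within 3 binomial standard deviations
  expect_lt(abs(sum(in_isl) - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
})

test_that("treated methylation applies the promoter shift with clamping", {
  ann <- tiny_annotation()
  sites <- tibble::tibble(site_id = c("in_prom", "outside"),
                          chrom = "chr1", pos = c(9500L, 30000L))
  genome <- list(ann = ann, sites = sites)
  base <- list(island = c(5, 5), open = c(5, 5))

  # zero shift and zero noise: treated identical to control
  set.seed(6)
  m0 <- simulate_methylome(genome, mscc_sim_config(
    prop_promoters_shifted = 1, shift_size = 0, noise_sd = 0,
    baseline_meth = base))
  expect_identical(m0$site_meth$m_treated, m0$site_meth$m_control)

  # shift applies only to promoter sites of shifted genes, with clamping
  set.seed(7)
  m1 <- simulate_methylome(genome, mscc_sim_config(
    prop_promoters_shifted = 1, shift_size = -0.4, noise_sd = 0,
    baseline_meth = base))
  sm <- m1$site_meth
  expect_true(sm$shifted[sm$site_id == "in_prom"])
  expect_false(sm$shifted[sm$site_id == "outside"])
  expect_equal(sm$m_treated[1], max(sm$m_control[1] - 0.4, 0))
  expect_equal(sm$m_treated[2], sm$m_control[2])

  # a shift larger than the control fraction clamps at zero
  set.seed(8)
  m2 <- simulate_methylome(genome, mscc_sim_config(
    prop_promoters_shifted = 1, shift_size = -1, noise_sd = 0,
    baseline_meth = base))
  expect_equal(m2$site_meth$m_treated[1], 0)
})

test_that("tag counts follow the two-library Poisson structure", {
  cfg <- mscc_sim_config(mean_site_depth = 200)
  set.seed(9)
  pure <- tibble::tibble(site_id = c("meth0", "meth1"),
                         m_control = c(0, 1), m_treated = c(0, 1))
  cnt <- simulate_site_counts(pure, cfg)
  ctl <- cnt$counts[cnt$counts$condition == "control", ]
  expect_equal(ctl$insensitive_count[ctl$site_id == "meth0"], 0L)
  expect_equal(ctl$sensitive_count[ctl$site_id == "meth1"], 0L)
  expect_true(all(cnt$counts$sensitive_count >= 0))

  # Monte Carlo: estimate at m = 0.5, equal depths 200, centred within 0.01
  set.seed(10)
  sm <- tibble::tibble(site_id = sprintf("s%05d", 1:10000),
                       m_control = 0.5, m_treated = 0.5)
  cnt <- simulate_site_counts(sm, cfg)
  est <- estimate_methylation(
    cnt$counts[cnt$counts$condition == "control" &
                 !grepl("^spikein", cnt$counts$site_id), ],
    tibble::tibble(condition = "control",
                   sensitive_total = 1e6, insensitive_total = 1e6))
  expect_lt(abs(mean(est$m_hat) - 0.5), 0.01)
})

test_that("library totals account for every site and spike-in tag", {
  set.seed(11)
  sm <- tibble::tibble(site_id = sprintf("s%03d", 1:50),
                       m_control = runif(50), m_treated = runif(50))
  cnt <- simulate_site_counts(sm, mscc_sim_config())
  sums <- cnt$counts |>
    dplyr::group_by(condition) |>
    dplyr::summarise(u = sum(sensitive_count), m = sum(insensitive_count))
  expect_equal(cnt$lib_info$sensitive_total, sums$u)
  expect_equal(cnt$lib_info$insensitive_total, sums$m)
  # exactly four spike-in standards per condition
  expect_equal(sum(grepl("^spikein_", cnt$counts$site_id)), 8L)
  expect_equal(nrow(cnt$spikeins), 4L)
  expect_equal(sort(cnt$spikeins$true_fraction), c(0, 1/3, 2/3, 1))
})

test_that("the simulated DE table encodes its truth labels", {
  truth <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                          de_status = rep(c("up", "down", "null"), each = 100),
                          promoter_shifted = FALSE)
  set.seed(12)
  de <- simulate_de_table(truth, mscc_sim_config())
  expect_true(all(de$fold_change[truth$de_status == "up"] > 1.5))
  expect_true(all(de$fold_change[truth$de_status == "down"] < 1 / 1.5))
  expect_true(all(de$p_value[truth$de_status != "null"] < 0.05))
  kept <- filter_de(de)
  # every truth-DE gene passes the filters with the matching direction
  expect_setequal(kept$gene_id[kept$direction == "up"],
                  truth$gene_id[truth$de_status == "up"])
  # null genes only slip through at the expected false-positive rate
  null_kept <- sum(kept$gene_id %in% truth$gene_id[truth$de_status == "null"])
  expect_lt(null_kept / 100, 0.1)

  # no DE at all when de_fraction is zero
  set.seed(13)
  g <- simulate_genome(mscc_sim_config(seed = 13, n_genes = 50, n_sites = 200))
  m <- simulate_methylome(g, mscc_sim_config(de_fraction = 0))
  expect_true(all(m$gene_truth$de_status == "null"))

  # truth-up count is a seeded draw: regenerating reproduces it
  cfg <- mscc_sim_config(seed = 14, n_genes = 1000, n_sites = 2000,
                         de_fraction = 0.1)
  t1 <- simulate_mscc(cfg)$gene_truth
  t2 <- simulate_mscc(cfg)$gene_truth
  expect_identical(t1, t2)
  expect_gt(sum(t1$de_status == "up"), 0)
})

test_that("generated counts are non-negative integers", {
  set.seed(15)
  sim <- simulate_mscc(mscc_sim_config(seed = 15, n_genes = 20, n_sites = 500))
  expect_true(is.integer(sim$counts$sensitive_count))
  expect_true(is.integer(sim$counts$insensitive_count))
  expect_true(all(sim$counts$sensitive_count >= 0))
  expect_true(all(sim$counts$insensitive_count >= 0))
})

test_that("written simulation files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_mscc(mscc_sim_config(seed = 16, n_genes = 15, n_sites = 300,
                                       n_islands = 10))
  write_simulation(sim, dir)
  genes <- read_genes(file.path(dir, "genes.tsv"))
  expect_equal(genes, sim$ann$genes)
  islands <- read_islands(file.path(dir, "islands.bed"))
  expect_equal(islands$start, sim$ann$islands$start)
  expect_equal(islands$end, sim$ann$islands$end)
  sites <- read_sites(file.path(dir, "sites.bed"))
  expect_equal(sites$pos, sim$sites$pos)
  expect_equal(sites$site_id, sim$sites$site_id)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(counts, sim$counts)
})
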