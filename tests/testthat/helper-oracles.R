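# Brute-force oracles, independent of the package implementation, plus
# small fixture builders used across test files.

# island membership by scanning every island interval
bf_in_island <- function(chrom, pos, islands) {
  vapply(seq_along(pos), function(i) {
    any(islands$chrom == chrom[i] &
          islands$start <= pos[i] & pos[i] < islands$end)
  }, logical(1))
}

# nearest TSS by exhaustive scan over all genes on the chromosome,
# ties resolved toward the gene the site is downstream of, then by id
bf_nearest_tss <- function(chrom, pos, genes) {
  res_gene <- character(length(pos))
  res_dist <- integer(length(pos))
  for (i in seq_along(pos)) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      res_gene[i] <- NA_character_
      res_dist[i] <- NA_integer_
      next
    }
    d_abs <- abs(pos[i] - g$tss)
    g <- g[d_abs == min(d_abs), , drop = FALSE]
    d_signed <- ifelse(g$strand == "+", pos[i] - g$tss, g$tss - pos[i])
    ord <- order(d_signed < 0, g$gene_id)
    res_gene[i] <- g$gene_id[ord[1]]
    res_dist[i] <- d_signed[ord[1]]
  }
  list(gene = res_gene, dist = res_dist)
}

# coverage filter by row-wise scan
bf_filter_coverage <- function(wide, min_reads) {
  keep <- vapply(seq_len(nrow(wide)), function(i) {
    wide$reads_control[i] >= min_reads && wide$reads_treated[i] >= min_reads
  }, logical(1))
  wide[keep, , drop = FALSE]
}

# concordance class by explicit case analysis
bf_classify <- function(direction, pct_hyper, threshold = 90) {
  vapply(seq_along(direction), function(i) {
    lo <- 100 - threshold
    if (direction[i] == "up") {
      if (pct_hyper[i] <= lo) "concordant_up"
      else if (pct_hyper[i] >= threshold) "discordant_up"
      else "unclassified"
    } else {
      if (pct_hyper[i] >= threshold) "concordant_down"
      else if (pct_hyper[i] <= lo) "discordant_down"
      else "unclassified"
    }
  }, character(1))
}

# a random small annotation for property tests
random_annotation <- function(n_genes = 20, n_islands = 10, n_chrom = 2,
                              len = 100000) {
  chromosomes <- tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)),
                                length = len)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(chromosomes$chrom, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = sample.int(len - 4000, n_genes) + 2000L
  )
  while (anyDuplicated(genes[, c("chrom", "tss")])) {
    dup <- duplicated(genes[, c("chrom", "tss")])
    genes$tss[dup] <- sample.int(len - 4000, sum(dup)) + 2000L
  }
  start <- sample.int(len - 3000, n_islands)
  islands <- tibble::tibble(
    chrom = sample(chromosomes$chrom, n_islands, replace = TRUE),
    start = start,
    end = start + sample(200:2000, n_islands, replace = TRUE)
  )
  genome_annotation(chromosomes, genes, islands)
}

random_sites <- function(n, ann) {
  chrom <- sample(ann$chromosomes$chrom, n, replace = TRUE)
  pos <- sample.int(ann$chromosomes$length[1], n) - 1L
  keep <- !duplicated(paste(chrom, pos))
  tibble::tibble(site_id = sprintf("s%05d", seq_len(sum(keep))),
                 chrom = chrom[keep], pos = pos[keep])
}

# a deterministic one-gene genome used by several arithmetic tests
tiny_annotation <- function() {
  genome_annotation(
    chromosomes = tibble::tibble(chrom = "chr1", length = 50000L),
    genes = tibble::tibble(gene_id = "geneA", chrom = "chr1",
                           strand = "+", tss = 10000L),
    islands = tibble::tibble(chrom = "chr1", start = 9000L, end = 9600L)
  )
}
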