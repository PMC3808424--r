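#' Assemble a genome annotation
#'
#' Bundles chromosome sizes, gene TSS records and CpG-island intervals into a
#' single validated object. All coordinates are 0-based; intervals are
#' half-open `[start, end)`.
#'
#' @param chromosomes Tibble with columns `chrom`, `length` (bp).
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `tss` (0-based bp).
#' @param islands Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open). Overlapping islands are allowed; membership tests take the
#'   union.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes, islands) {
  chromosomes <- tibble::as_tibble(chromosomes)
  genes <- tibble::as_tibble(genes)
  islands <- tibble::as_tibble(islands)
  if (anyDuplicated(chromosomes$chrom)) stop("chromosome names must be unique")
  validate_genes(genes)
  if (nrow(islands) > 0 && any(islands$start >= islands$end)) {
    stop("island intervals must satisfy start < end")
  }
  len <- stats::setNames(chromosomes$length, chromosomes$chrom)
  bad_gene <- !(genes$chrom %in% names(len)) | genes$tss >= len[genes$chrom]
  if (any(bad_gene)) {
    stop("genes outside their chromosome bounds: ",
         paste(utils::head(genes$gene_id[bad_gene], 5), collapse = ", "))
  }
  if (nrow(islands) > 0) {
    bad_isl <- !(islands$chrom %in% names(len)) | islands$end > len[islands$chrom] |
      islands$start < 0
    if (any(bad_isl)) stop("islands outside their chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, genes = genes, islands = islands),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d chromosome(s), %d gene(s), %d island(s)\n",
              nrow(x$chromosomes), nrow(x$genes), nrow(x$islands)))
  invisible(x)
}

#' Promoter windows around transcription start sites
#'
#' The promoter is defined as the interval from `upstream` bp upstream to
#' `downstream` bp downstream of the TSS, read in the gene's own orientation:
#' on the `+` strand the window is `[tss - upstream, tss + downstream)`, on
#' the `-` strand the coordinate mirror `[tss - downstream, tss + upstream)`.
#' Windows are
#' clipped to `[0, chromosome length)` when the annotation carries lengths,
#' so a TSS near a chromosome edge yields a narrower window.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`) or a
#'   `genome_annotation`.
#' @param upstream,downstream Window extent in bp (defaults 1500 and 500).
#' @param chrom_lengths Optional named vector of chromosome lengths used for
#'   clipping; taken from the annotation when one is supplied.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `tss`, `start`,
#'   `end` (0-based half-open).
#' @export
promoter_windows <- function(genes, upstream = 1500, downstream = 500,
                             chrom_lengths = NULL) {
  if (inherits(genes, "genome_annotation")) {
    chrom_lengths <- stats::setNames(genes$chromosomes$length, genes$chromosomes$chrom)
    genes <- genes$genes
  }
  validate_genes(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    if (!all(genes$chrom %in% names(chrom_lengths))) {
      stop("unknown chromosome in gene table: ",
           paste(setdiff(genes$chrom, names(chrom_lengths)), collapse = ", "))
    }
    end <- pmin(end, unname(chrom_lengths[genes$chrom]))
  }
  tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                 strand = genes$strand, tss = genes$tss,
                 start = as.integer(start), end = as.integer(end))
}

sites_as_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(start = sites$pos + 1L, width = 1L))
}

intervals_as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' CpG-island membership of CCGG sites
#'
#' A site is inside an island when `start <= pos < end` for at least one
#' island interval on the same chromosome (union semantics over overlapping
#' islands).
#'
#' @param sites Tibble with columns `site_id`, `chrom`, `pos`.
#' @param islands Island tibble (`chrom`, `start`, `end`) or a
#'   `genome_annotation`.
#' @return Logical vector parallel to `sites`.
#' @export
site_in_island <- function(sites, islands) {
  if (inherits(islands, "genome_annotation")) islands <- islands$islands
  if (nrow(islands) == 0 || nrow(sites) == 0) return(rep(FALSE, nrow(sites)))
  IRanges::overlapsAny(sites_as_granges(sites), intervals_as_granges(islands))
}

#' Signed distance to the nearest transcription start site
#'
#' For each site, finds the gene on the same chromosome whose TSS minimizes
#' `|pos - tss|` and reports the strand-aware signed distance: negative when
#' the site lies upstream of the TSS in the gene's reading direction (so for
#' a `-` strand gene, `pos > tss` gives a negative distance). Equidistant
#' ties resolve toward the gene the site is downstream of (positive signed
#' distance), then by lexicographic gene id. Sites on chromosomes with no
#' genes get `NA` for both fields and are excluded from TSS profiles.
#'
#' @param sites Tibble with columns `site_id`, `chrom`, `pos`.
#' @param genes Gene tibble or a `genome_annotation`.
#' @return Tibble with columns `site_id`, `nearest_gene`, `tss_distance`.
#' @export
nearest_tss <- function(sites, genes) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes
  validate_genes(genes)
  n <- nrow(sites)
  out_gene <- rep(NA_character_, n)
  out_dist <- rep(NA_integer_, n)
  for (chr in unique(sites$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    si <- which(sites$chrom == chr)
    if (nrow(g) == 0) next
    ord <- order(g$tss, g$gene_id)
    g <- g[ord, , drop = FALSE]
    tss <- g$tss
    pos <- sites$pos[si]
    idx <- findInterval(pos, tss)        # last tss <= pos
    left <- ifelse(idx >= 1, tss[pmax(idx, 1)], NA_integer_)
    right <- ifelse(idx < length(tss), tss[pmin(idx + 1, length(tss))], NA_integer_)
    dl <- abs(pos - left)
    dr <- abs(right - pos)
    for (k in seq_along(si)) {
      dmin <- min(dl[k], dr[k], na.rm = TRUE)
      cand_tss <- unique(stats::na.omit(c(left[k], right[k])))
      cand_tss <- cand_tss[abs(pos[k] - cand_tss) == dmin]
      cand <- g[g$tss %in% cand_tss, , drop = FALSE]
      d_signed <- ifelse(cand$strand == "+", pos[k] - cand$tss, cand$tss - pos[k])
      # ties: prefer the gene whose TSS the site is downstream of, then id
      pick <- order(d_signed < 0, cand$gene_id)[1]
      out_gene[si[k]] <- cand$gene_id[pick]
      out_dist[si[k]] <- d_signed[pick]
    }
  }
  tibble::tibble(site_id = sites$site_id, nearest_gene = out_gene,
                 tss_distance = out_dist)
}

#' Annotate CCGG sites with island, promoter and TSS context
#'
#' Combines [site_in_island()] and [nearest_tss()] and assigns each site to
#' at most one promoter: that of its nearest-TSS gene, and only when the site
#' actually falls inside that gene's promoter window. Single assignment keeps
#' downstream region strata disjoint even where promoter windows overlap.
#'
#' @param sites Tibble with columns `site_id`, `chrom`, `pos`.
#' @param ann A `genome_annotation`.
#' @param upstream,downstream Promoter extent passed to [promoter_windows()].
#' @return Tibble with columns `site_id`, `chrom`, `pos`, `in_island`,
#'   `nearest_gene`, `tss_distance`, `in_promoter`, `promoter_gene`.
#' @export
annotate_sites <- function(sites, ann, upstream = 1500, downstream = 500) {
  stopifnot(inherits(ann, "genome_annotation"))
  validate_sites(sites)
  unknown <- setdiff(unique(sites$chrom), ann$chromosomes$chrom)
  unknown <- setdiff(unknown, "spikein")
  if (length(unknown) > 0) {
    stop("sites on chromosomes absent from the annotation: ",
         paste(unknown, collapse = ", "))
  }
  nt <- nearest_tss(sites, ann)
  pw <- promoter_windows(ann, upstream = upstream, downstream = downstream)
  win <- pw[match(nt$nearest_gene, pw$gene_id), , drop = FALSE]
  in_prom <- !is.na(nt$nearest_gene) &
    sites$pos >= win$start & sites$pos < win$end
  tibble::tibble(
    site_id = sites$site_id, chrom = sites$chrom, pos = sites$pos,
    in_island = site_in_island(sites, ann),
    nearest_gene = nt$nearest_gene,
    tss_distance = nt$tss_distance,
    in_promoter = in_prom,
    promoter_gene = ifelse(in_prom, nt$nearest_gene, NA_character_)
  )
}
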