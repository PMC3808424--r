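#' Read a gene table
#'
#' Reads gene records from either a four-column TSV (`gene_id`, `chrom`,
#' `strand`, `tss`; 0-based TSS coordinates) or a GTF/GFF file. GTF input is
#' reduced to one record per gene: the 5' end of the annotated interval on the
#' feature's strand becomes the transcription start site, converted from the
#' 1-based closed GTF convention to the package's 0-based convention.
#'
#' @param path Path to a TSV or GTF/GFF file.
#' @param format `"tsv"` (default), `"gtf"`, or `"auto"` to decide from the
#'   file extension.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_genes <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path)
    keep <- if ("type" %in% names(S4Vectors::mcols(gr))) gr$type == "gene" else rep(TRUE, length(gr))
    gr <- gr[keep]
    id_col <- intersect(c("gene_id", "gene_name", "ID"), names(S4Vectors::mcols(gr)))[1]
    if (is.na(id_col)) stop("GTF input carries no gene_id/gene_name/ID attribute")
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*")) stop("GTF gene records must be stranded")
    genes <- tibble::tibble(
      gene_id = as.character(S4Vectors::mcols(gr)[[id_col]]),
      chrom   = as.character(GenomicRanges::seqnames(gr)),
      strand  = strand,
      # rtracklayer imports 1-based closed; the 5' base in 0-based coords is
      # start-1 on + and end-1 on -.
      tss = ifelse(strand == "+",
                   BiocGenerics::start(gr) - 1L,
                   BiocGenerics::end(gr) - 1L)
    )
  } else {
    genes <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                             col_types = readr::cols(
                               gene_id = readr::col_character(),
                               chrom = readr::col_character(),
                               strand = readr::col_character(),
                               tss = readr::col_integer()
                             ))
  }
  validate_genes(genes)
  genes
}

validate_genes <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "tss")
  if (!all(req %in% names(genes))) {
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(genes$tss < 0)) stop("gene TSS coordinates must be >= 0")
  invisible(genes)
}

#' Read CpG-island intervals from a BED3 file
#'
#' BED is 0-based half-open, which is also the package's internal convention,
#' so coordinates pass through unchanged.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_islands <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  islands <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # back to 0-based half-open
    end   = BiocGenerics::end(gr)
  )
  if (any(islands$start >= islands$end)) stop("island intervals must satisfy start < end")
  islands
}

#' Read CCGG site coordinates
#'
#' Accepts either a BED4 file (`chrom`, `start`, `end`, `name`; the interval
#' start is taken as the site position) or a TSV with columns `site_id`,
#' `chrom`, `pos`.
#'
#' @param path Input path.
#' @param format `"auto"` (default, from extension), `"bed"` or `"tsv"`.
#' @return A tibble with columns `site_id`, `chrom`, `pos` (0-based position
#'   of the first C of the CCGG motif on the forward strand).
#' @export
read_sites <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if ("name" %in% names(S4Vectors::mcols(gr))) as.character(gr$name) else
      sprintf("site_%06d", seq_along(gr))
    sites <- tibble::tibble(
      site_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      pos = BiocGenerics::start(gr) - 1L
    )
  } else {
    sites <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                             col_types = readr::cols(
                               site_id = readr::col_character(),
                               chrom = readr::col_character(),
                               pos = readr::col_integer()
                             ))
  }
  validate_sites(sites)
  sites
}

validate_sites <- function(sites) {
  req <- c("site_id", "chrom", "pos")
  if (!all(req %in% names(sites))) stop("site table must have columns: ", paste(req, collapse = ", "))
  if (any(sites$pos < 0)) stop("site positions must be >= 0")
  if (anyDuplicated(sites[, c("chrom", "pos")])) stop("site (chrom, pos) pairs must be unique")
  invisible(sites)
}

#' Read a two-library MSCC tag-count table
#'
#' @param path TSV with columns `site_id`, `condition`, `sensitive_count`
#'   (HpaII library, tags from unmethylated molecules) and `insensitive_count`
#'   (inverse MspI library, tags from methylated molecules).
#' @return A tibble with those four columns.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            col_types = readr::cols(
                              site_id = readr::col_character(),
                              condition = readr::col_character(),
                              sensitive_count = readr::col_integer(),
                              insensitive_count = readr::col_integer()
                            ))
  if (any(counts$sensitive_count < 0) || any(counts$insensitive_count < 0)) {
    stop("tag counts must be non-negative")
  }
  counts
}

#' Read per-library total tag counts
#'
#' @param path TSV with columns `condition`, `sensitive_total`,
#'   `insensitive_total`.
#' @return A tibble with those columns.
#' @export
read_library_info <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    condition = readr::col_character(),
                    sensitive_total = readr::col_double(),
                    insensitive_total = readr::col_double()
                  ))
}

#' Read a differential-expression results table
#'
#' Extra columns beyond `gene_id`, `fold_change`, `p_value` are preserved.
#'
#' @param path TSV path.
#' @return A tibble containing at least `gene_id`, `fold_change`, `p_value`.
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  req <- c("gene_id", "fold_change", "p_value")
  if (!all(req %in% names(de))) {
    stop("DE table must have columns: ", paste(req, collapse = ", "))
  }
  de$gene_id <- as.character(de$gene_id)
  de
}

#' Write a tibble as a TSV interchange file
#'
#' All stage outputs use plain TSV with a header line so that reruns are
#' byte-identical and diffable.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
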