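#' Estimate per-site methylation fractions from two-library tag counts
#'
#' MSCC produces, per site and condition, a tag count `U` from the
#' methylation-sensitive HpaII library (unmethylated molecules cut) and a tag
#' count `M` from the inverse methylation-insensitive MspI library
#' (methylated molecules). The methylation fraction is estimated as the
#' library-size-normalized share of methylated-library signal,
#'
#' \deqn{\hat m = \frac{M/N_M}{M/N_M + U/N_U},}
#'
#' where `N_U` and `N_M` are total mapped tags per library. With equal
#' library depths this reduces to `M / (M + U)`; the normalization corrects
#' depth asymmetry between the two libraries. Sites with `U = M = 0` in a
#' condition are flagged undefined (`m_hat = NA`) rather than evaluated.
#'
#' @param counts Tibble with columns `site_id`, `condition`,
#'   `sensitive_count`, `insensitive_count`.
#' @param lib_info Optional tibble (`condition`, `sensitive_total`,
#'   `insensitive_total`). When `NULL`, totals default to the column sums of
#'   `counts` within each condition.
#' @return Tibble with columns `site_id`, `condition`, `m_hat`,
#'   `total_reads`, `defined`.
#' @export
estimate_methylation <- function(counts, lib_info = NULL) {
  stopifnot(all(c("site_id", "condition", "sensitive_count", "insensitive_count")
                %in% names(counts)))
  if (any(counts$sensitive_count < 0) || any(counts$insensitive_count < 0)) {
    stop("tag counts must be non-negative")
  }
  if (is.null(lib_info)) {
    lib_info <- counts |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(sensitive_total = sum(.data$sensitive_count),
                       insensitive_total = sum(.data$insensitive_count),
                       .groups = "drop")
  }
  if (any(lib_info$sensitive_total <= 0) || any(lib_info$insensitive_total <= 0)) {
    stop("library totals must be positive")
  }
  est <- counts |>
    dplyr::left_join(lib_info, by = "condition")
  if (anyNA(est$sensitive_total)) {
    stop("library info missing for condition(s): ",
         paste(setdiff(counts$condition, lib_info$condition), collapse = ", "))
  }
  u_rate <- est$sensitive_count / est$sensitive_total
  m_rate <- est$insensitive_count / est$insensitive_total
  defined <- (est$sensitive_count + est$insensitive_count) > 0
  m_hat <- ifelse(defined, m_rate / (m_rate + u_rate), NA_real_)
  tibble::tibble(
    site_id = est$site_id,
    condition = est$condition,
    m_hat = m_hat,
    total_reads = est$sensitive_count + est$insensitive_count,
    defined = defined
  )
}

#' Reshape per-condition methylation estimates to one row per site
#'
#' @param est Output of [estimate_methylation()].
#' @param conditions Character vector of length 2 naming the control and
#'   treated condition, in that order.
#' @return Tibble with columns `site_id`, `m_control`, `m_treated`,
#'   `reads_control`, `reads_treated`. Sites lacking either condition, or
#'   undefined (zero-tag) in one, are dropped.
#' @export
methylation_wide <- function(est, conditions = c("control", "hypoxic")) {
  stopifnot(length(conditions) == 2)
  est <- est[est$condition %in% conditions & est$defined, , drop = FALSE]
  wide <- est |>
    dplyr::mutate(role = ifelse(.data$condition == conditions[1], "control", "treated")) |>
    dplyr::select("site_id", "role", "m_hat", "total_reads") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("m_hat", "total_reads"),
                       names_glue = "{.value}_{role}")
  for (col in c("m_hat_control", "m_hat_treated",
                "total_reads_control", "total_reads_treated")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- wide |>
    dplyr::filter(!is.na(.data$m_hat_control), !is.na(.data$m_hat_treated)) |>
    dplyr::rename(m_control = "m_hat_control", m_treated = "m_hat_treated",
                  reads_control = "total_reads_control",
                  reads_treated = "total_reads_treated")
  wide[, c("site_id", "m_control", "m_treated", "reads_control", "reads_treated")]
}

#' Coverage filter on combined two-library read counts
#'
#' Keeps a site only when, in each condition separately, the combined tag
#' count from the sensitive and insensitive libraries reaches `min_reads`
#' (inclusive). The default of 30 reads is the profiling filter; 60 and 100
#' support coverage-stratified summaries.
#'
#' @param wide Output of [methylation_wide()].
#' @param min_reads Minimum combined reads per condition (default 30).
#' @return The filtered tibble.
#' @export
filter_coverage <- function(wide, min_reads = 30) {
  wide[wide$reads_control >= min_reads & wide$reads_treated >= min_reads, ,
       drop = FALSE]
}

#' Fit a linear calibration against internal spike-in standards
#'
#' Each MSCC library set carries four internal standards mixed to known
#' methylation fractions (0, 1/3, 2/3 and 1). A least-squares line mapping
#' the raw estimate to the known fraction gives a slope/intercept correction;
#' it is applied identically to both conditions and is off by default in the
#' pipeline, since raw estimates are already consistent when library depths
#' are normalized.
#'
#' @param m_hat Numeric vector of raw estimates at the standards.
#' @param true_fraction Known fractions, same length (defaults to the four
#'   canonical standards when `m_hat` has length 4).
#' @return An object of class `mscc_calibration` with elements `slope`,
#'   `intercept`, `residuals`, `n`.
#' @export
fit_calibration <- function(m_hat, true_fraction = c(0, 1/3, 2/3, 1)) {
  if (length(m_hat) != length(true_fraction)) {
    stop("m_hat and true_fraction must have equal length")
  }
  if (length(m_hat) < 4) {
    warning("fewer than 4 calibration standards; calibration unavailable, raw values used")
    return(structure(list(slope = 1, intercept = 0,
                          residuals = rep(NA_real_, length(m_hat)),
                          n = length(m_hat), identity = TRUE),
                     class = "mscc_calibration"))
  }
  if (anyNA(m_hat)) stop("calibration standards must have defined estimates")
  fit <- stats::lm(true_fraction ~ m_hat)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit)),
                 n = length(m_hat), identity = FALSE),
            class = "mscc_calibration")
}

#' @export
print.mscc_calibration <- function(x, ...) {
  cat(sprintf("<mscc_calibration> calibrated = %.4f + %.4f * raw (n = %d)\n",
              x$intercept, x$slope, x$n))
  invisible(x)
}

#' Apply a spike-in calibration to raw methylation estimates
#'
#' @param m_hat Numeric vector of raw estimates.
#' @param calibration An `mscc_calibration` from [fit_calibration()].
#' @return Calibrated fractions, clamped to `[0, 1]`.
#' @export
apply_calibration <- function(m_hat, calibration) {
  stopifnot(inherits(calibration, "mscc_calibration"))
  pmin(pmax(calibration$intercept + calibration$slope * m_hat, 0), 1)
}

#' Extract spike-in standard estimates from a counts table
#'
#' Spike-in standards are carried as ordinary count rows on the reserved
#' contig name `"spikein"` with site ids encoding the nominal percentage
#' (`spikein_0`, `spikein_33`, `spikein_67`, `spikein_100`).
#'
#' @param est Output of [estimate_methylation()] including spike-in rows.
#' @param condition Condition to extract (default pools conditions by mean).
#' @return Tibble with columns `site_id`, `true_fraction`, `m_hat`.
#' @export
spikein_estimates <- function(est, condition = NULL) {
  sp <- est[grepl("^spikein_", est$site_id), , drop = FALSE]
  if (!is.null(condition)) sp <- sp[sp$condition == condition, , drop = FALSE]
  truth <- c(spikein_0 = 0, spikein_33 = 1/3, spikein_67 = 2/3, spikein_100 = 1)
  sp |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(m_hat = mean(.data$m_hat), .groups = "drop") |>
    dplyr::mutate(true_fraction = unname(truth[.data$site_id])) |>
    dplyr::arrange(.data$true_fraction) |>
    dplyr::select("site_id", "true_fraction", "m_hat")
}
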