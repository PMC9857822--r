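#' Quantitative accuracy of a measured sphere concentration
#'
#' Accuracy in percent of a reconstructed hot-sphere measurement against
#' the known true activity concentration:
#' \deqn{\mathrm{Accuracy}(\%) = \left(1 -
#'   \frac{|A_{true} - a_{meas}|}{A_{true}}\right) \times 100}
#' The statistic is symmetric in the sign of the error and strictly
#' decreasing in its magnitude; it can go negative when the absolute error
#' exceeds the true concentration, and such values are reported as-is.
#'
#' @param true_conc True activity concentration (Bq/mL, > 0). Vectorized.
#' @param measured_conc Measured concentration in the reconstructed volume
#'   (Bq/mL, >= 0). Vectorized.
#' @return Accuracy in percent.
#' @export
#' @examples
#' accuracy(100, 95)  # 95
accuracy <- function(true_conc, measured_conc) {
  if (any(!is.finite(true_conc)) || any(true_conc <= 0))
    stop("true concentration must be positive", call. = FALSE)
  if (any(!is.finite(measured_conc)) || any(measured_conc < 0))
    stop("measured concentration must be non-negative", call. = FALSE)
  (1 - abs(true_conc - measured_conc) / true_conc) * 100
}

#' Qualify a scanner for quantitative use
#'
#' A scanner qualifies for absolute quantification when (a) every
#' hot-sphere accuracy exceeds the vendor-recommended threshold (90% by
#' default) and (b) the relative deviation between the planar and
#' SPECT-derived sensitivity conversion factors lies within 0-5%. The
#' deviation is computed as `|planar - spect| / spect * 100`, with the
#' SPECT factor as reference since quantification runs on the SPECT data.
#'
#' @param sphere_accuracies Data frame with columns `sphere_id`,
#'   `true_concentration`, `measured_concentration` (Bq/mL), e.g. from
#'   [generate_phantom()]; per-sphere accuracy is computed internally. An
#'   `accuracy_pct` column, if present, is recomputed.
#' @param threshold_pct Minimum acceptable per-sphere accuracy (percent).
#' @param sensitivity_planar,sensitivity_spect Sensitivity conversion
#'   factors (counts/s per MBq) from the planar and tomographic
#'   calibration acquisitions.
#' @param max_deviation_pct Maximum acceptable sensitivity deviation.
#' @return A list of class `scanner_qualification`: `pass` (logical),
#'   `spheres` (per-sphere table with `accuracy_pct` and `pass`),
#'   `min_accuracy_pct`, `sensitivity_deviation_pct`, `failures`
#'   (character vector naming failing spheres and/or the deviation check).
#' @export
qualify_scanner <- function(sphere_accuracies, threshold_pct = 90,
                            sensitivity_planar, sensitivity_spect,
                            max_deviation_pct = 5) {
  if (!is.data.frame(sphere_accuracies) || nrow(sphere_accuracies) == 0L)
    stop("at least one sphere measurement is required", call. = FALSE)
  need <- c("sphere_id", "true_concentration", "measured_concentration")
  if (!all(need %in% names(sphere_accuracies)))
    stop("sphere table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!is.finite(sensitivity_planar) || sensitivity_planar <= 0 ||
      !is.finite(sensitivity_spect) || sensitivity_spect <= 0)
    stop("sensitivity factors must be positive", call. = FALSE)

  sph <- sphere_accuracies
  sph$accuracy_pct <- accuracy(sph$true_concentration,
                               sph$measured_concentration)
  sph$pass <- sph$accuracy_pct > threshold_pct
  dev_pct <- abs(sensitivity_planar - sensitivity_spect) /
    sensitivity_spect * 100
  dev_ok <- dev_pct <= max_deviation_pct

  failures <- character(0)
  if (any(!sph$pass))
    failures <- c(failures, sprintf(
      "sphere %s accuracy %.2f%% <= threshold %.1f%%",
      sph$sphere_id[!sph$pass], sph$accuracy_pct[!sph$pass], threshold_pct))
  if (!dev_ok)
    failures <- c(failures, sprintf(
      "sensitivity conversion-factor deviation %.2f%% exceeds %.1f%%",
      dev_pct, max_deviation_pct))

  structure(list(pass = all(sph$pass) && dev_ok,
                 spheres = sph,
                 min_accuracy_pct = min(sph$accuracy_pct),
                 sensitivity_deviation_pct = dev_pct,
                 threshold_pct = threshold_pct,
                 failures = failures),
            class = "scanner_qualification")
}

#' @export
print.scanner_qualification <- function(x, ...) {
  cat(sprintf("Scanner qualification: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  spheres: %d, min accuracy %.2f%% (threshold %.1f%%)\n",
              nrow(x$spheres), x$min_accuracy_pct, x$threshold_pct))
  cat(sprintf("  sensitivity deviation: %.2f%%\n",
              x$sensitivity_deviation_pct))
  if (length(x$failures))
    cat("  failures:\n", paste0("   - ", x$failures, "\n"), sep = "")
  invisible(x)
}
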