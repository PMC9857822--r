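#' Site-stratified uptake summary
#'
#' Sample mean and standard deviation (n-1 denominator) of SUVmax,
#' SUVpeak, reference-tissue SUV and TL/N ratio for all lesions at one
#' anatomical site. Lesions, not patients, are the summary unit: repeated
#' scans contribute their lesions individually, matching how pooled
#' per-lesion uptake tables are reported.
#'
#' @param table Data frame with one row per lesion per scan; must contain
#'   `site` and `suv_max`, and may contain `suv_peak`, `reference_suv`,
#'   `tln_ratio` (missing values are dropped per metric).
#' @param site Site to summarize (`"liver"`, `"lymph_node"`, `"bone"`,
#'   `"other"`, ...).
#' @return Data frame with one row per available metric: `metric`, `n`,
#'   `mean`, `sd`, and `formatted` (`"mean ± sd"` to two decimals).
#' @export
site_summary <- function(table, site) {
  stopifnot(is.data.frame(table), all(c("site", "suv_max") %in% names(table)))
  sub <- table[table$site == site, , drop = FALSE]
  if (nrow(sub) < 2L)
    stop(sprintf("fewer than two lesions at site '%s'", site),
         call. = FALSE)
  metrics <- intersect(c("suv_max", "suv_peak", "reference_suv",
                         "tln_ratio"), names(sub))
  rows <- lapply(metrics, function(m) {
    x <- sub[[m]][!is.na(sub[[m]])]
    if (length(x) < 2L) return(NULL)
    data.frame(metric = m, n = length(x), mean = mean(x),
               sd = stats::sd(x),
               formatted = sprintf("%.2f ± %.2f", mean(x),
                                   stats::sd(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test between lesion and reference uptake
#'
#' Two-sided paired-samples t-test, pairing by lesion. Degenerate inputs
#' whose pairwise differences have zero variance are rejected rather than
#' reported with an infinite statistic.
#'
#' @param lesion_values,reference_values Equal-length numeric vectors
#'   (n >= 3), paired elementwise.
#' @return List with `t`, `df`, `p`, `mean_difference` and `significant`
#'   (`p < 0.05`).
#' @export
paired_t_test <- function(lesion_values, reference_values) {
  if (length(lesion_values) != length(reference_values))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(lesion_values) < 3L)
    stop("at least three pairs are required", call. = FALSE)
  d <- lesion_values - reference_values
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      # identical pairs: no evidence of any difference
      return(list(t = 0, df = length(d) - 1L, p = 1,
                  mean_difference = 0, significant = FALSE))
    }
    stop("pairwise differences have zero variance; t statistic undefined",
         call. = FALSE)
  }
  res <- stats::t.test(lesion_values, reference_values, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value,
       mean_difference = unname(res$estimate),
       significant = res$p.value < 0.05)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation coefficient with its two-sided p-value from
#' the t transform, as used for SUVmax-SUVpeak and ki67-SUV association
#' tests.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return List with `r`, `n`, `p` and `significant` (`p < 0.05`).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("at least three observations are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), n = length(x), p = res$p.value,
       significant = res$p.value < 0.05)
}

#' Marker positivity rates across a cohort
#'
#' Percent of patients flagged positive for each marker, to one decimal.
#' Marker columns are logical (or 0/1) flags named `marker_<name>`;
#' patients appearing in several rows (one row per lesion) are counted
#' once.
#'
#' @param table Data frame with a `patient_id` column and one
#'   `marker_<name>` column per marker.
#' @param markers Character vector of marker names (e.g. `"cga"`,
#'   `"syn"`); each must have a matching `marker_` column.
#' @return Data frame with `marker`, `n_positive`, `n_patients`,
#'   `positivity_pct`.
#' @export
positivity_rates <- function(table, markers) {
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  cols <- paste0("marker_", markers)
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("unknown marker(s): ",
         paste(sub("^marker_", "", missing), collapse = ", "),
         call. = FALSE)
  first <- table[!duplicated(table$patient_id), , drop = FALSE]
  n_pat <- nrow(first)
  if (n_pat == 0L) stop("at least one patient is required", call. = FALSE)
  data.frame(marker = markers,
             n_positive = vapply(cols, function(cl)
               sum(as.logical(first[[cl]])), integer(1L)),
             n_patients = n_pat,
             positivity_pct = vapply(cols, function(cl)
               round(100 * sum(as.logical(first[[cl]])) / n_pat, 1),
               numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Format a p-value for report tables
#'
#' Three decimals; values below 0.0005 render as `"0.000"`, the display
#' convention of clinical statistics packages.
#'
#' @param p Numeric p-value(s) in `[0, 1]`.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  sprintf("%.3f", p)
}
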