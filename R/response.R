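RESPONSE_CATEGORIES <- c("CR", "PR", "SD", "PD")

#' Select target lesions for response assessment
#'
#' Picks the `max_targets` lesions with the highest SUVmax as the scan's
#' target set; ties in SUVmax are broken by lexicographic `lesion_id`
#' order, so selection is deterministic. The summed SUVmax of the selected
#' targets is the quantity tracked between scans.
#'
#' @param lesions Data frame with at least `lesion_id` and `suv_max`
#'   columns (e.g. from [measure_lesions()]); may be empty (a scan with no
#'   measurable uptake yields a summed SUVmax of 0).
#' @param max_targets Maximum number of target lesions (default 5).
#' @param scan_id,patient_id Identifiers carried into the result.
#' @param new_lesion_flag `TRUE` if this scan shows tumoral foci not
#'   present at baseline.
#' @return An object of class `target_lesion_set` with fields `scan_id`,
#'   `patient_id`, `targets` (the selected rows, ranked), `lesions` (all
#'   input rows), `summed_suv_max`, `new_lesion_flag`.
#' @export
select_targets <- function(lesions, max_targets = 5, scan_id = "scan",
                           patient_id = "patient",
                           new_lesion_flag = FALSE) {
  if (is.null(lesions) || nrow(lesions) == 0L) {
    lesions <- data.frame(lesion_id = character(0), suv_max = numeric(0),
                          stringsAsFactors = FALSE)
  }
  if (!all(c("lesion_id", "suv_max") %in% names(lesions)))
    stop("`lesions` needs columns lesion_id and suv_max", call. = FALSE)
  if (max_targets < 1) stop("max_targets must be >= 1", call. = FALSE)
  ord <- order(-lesions$suv_max, lesions$lesion_id)
  targets <- lesions[ord, , drop = FALSE]
  targets <- utils::head(targets, max_targets)
  structure(
    list(scan_id = scan_id, patient_id = patient_id,
         targets = targets, lesions = lesions,
         summed_suv_max = sum(targets$suv_max),
         new_lesion_flag = isTRUE(new_lesion_flag)),
    class = "target_lesion_set"
  )
}

#' Classify treatment response between two scans
#'
#' PERCIST 1.0 criteria adapted to SPECT, applied to the summed SUVmax of
#' the target lesions:
#' * **CR** — no uptake in any baseline target lesion at follow-up (each
#'   matched lesion's SUVmax at or below `background_suv`) and no new
#'   lesions;
#' * **PD** — new tumoral foci, or an increase in summed SUVmax > 30%;
#' * **PR** — a decrease in summed SUVmax > 30%;
#' * **SD** — any change < 30% in magnitude. A change of exactly 30%
#'   falls to SD, since PR/PD are defined by strict inequalities.
#' A baseline with zero summed SUVmax followed by measurable uptake is
#' classified PD (re-appearance counts as a new focus) and flagged in the
#' assessment note.
#'
#' @param baseline,followup [select_targets()] results for the two scans,
#'   chronologically ordered.
#' @param background_suv Reference uptake (g/mL) below which a lesion is
#'   considered to show "no uptake", e.g. healthy-liver SUVmax. `NA`
#'   (default) disables the CR check, so complete disappearance is graded
#'   PR on the summed-SUVmax change.
#' @return An object of class `response_assessment` with `patient_id`,
#'   `baseline_scan`, `followup_scan`, `delta_pct`
#'   (`100 * (sum_f - sum_b) / sum_b`), `category`, `new_lesion_flag`,
#'   `note`.
#' @export
classify_response <- function(baseline, followup,
                              background_suv = NA_real_) {
  stopifnot(inherits(baseline, "target_lesion_set"),
            inherits(followup, "target_lesion_set"))
  sum_b <- baseline$summed_suv_max
  sum_f <- followup$summed_suv_max
  new_lesion <- followup$new_lesion_flag
  note <- NA_character_

  if (sum_b <= 0) {
    if (new_lesion || sum_f > 0) {
      category <- "PD"
      note <- "uptake re-appeared after a zero-uptake baseline; treated as new focus"
    } else {
      category <- "CR"
      note <- "continued absence of uptake"
    }
    delta <- NA_real_
  } else {
    delta <- 100 * (sum_f - sum_b) / sum_b
    cr <- FALSE
    if (!new_lesion && !is.na(background_suv)) {
      # follow-up uptake of each baseline target; an unmatched lesion is
      # taken as resolved (no measurable uptake)
      fu <- followup$lesions$suv_max[
        match(baseline$targets$lesion_id, followup$lesions$lesion_id)]
      fu[is.na(fu)] <- 0
      cr <- all(fu <= background_suv)
    }
    category <- if (cr) "CR"
      else if (new_lesion || delta > 30) "PD"
      else if (delta < -30) "PR"
      else "SD"
  }
  structure(
    list(patient_id = baseline$patient_id,
         baseline_scan = baseline$scan_id,
         followup_scan = followup$scan_id,
         delta_pct = delta,
         category = category,
         new_lesion_flag = new_lesion,
         note = note),
    class = "response_assessment"
  )
}

#' @export
print.response_assessment <- function(x, ...) {
  cat(sprintf("%s: %s -> %s  %s (delta %s%%)\n",
              x$patient_id, x$baseline_scan, x$followup_scan, x$category,
              if (is.na(x$delta_pct)) "NA" else sprintf("%+.1f", x$delta_pct)))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Evaluate a patient's longitudinal scan series
#'
#' Classifies each follow-up scan against the baseline (default,
#' PERCIST-style) or against the immediately preceding scan. The final
#' response category is the category of the last follow-up, since only the
#' conclusion of the last performed scan counts for cohort-level response
#' distribution.
#'
#' @param scans Chronologically ordered list of [select_targets()] results;
#'   the first is the baseline. At least two scans are required.
#' @param comparison_mode `"vs_baseline"` (each follow-up against the first
#'   scan) or `"vs_previous"` (against the preceding scan).
#' @param background_suv Passed to [classify_response()].
#' @return A list of class `patient_evaluation`: `assessments` (one
#'   [classify_response()] result per follow-up) and `final_category`.
#' @export
evaluate_patient <- function(scans,
                             comparison_mode = c("vs_baseline",
                                                 "vs_previous"),
                             background_suv = NA_real_) {
  comparison_mode <- match.arg(comparison_mode)
  if (!is.list(scans) || length(scans) < 2L)
    stop("at least two consecutive scans are required for response ",
         "assessment", call. = FALSE)
  assessments <- vector("list", length(scans) - 1L)
  for (k in 2:length(scans)) {
    ref <- if (comparison_mode == "vs_baseline") scans[[1L]]
           else scans[[k - 1L]]
    assessments[[k - 1L]] <- classify_response(ref, scans[[k]],
                                               background_suv)
  }
  structure(
    list(assessments = assessments,
         final_category = assessments[[length(assessments)]]$category,
         comparison_mode = comparison_mode),
    class = "patient_evaluation"
  )
}

#' Cohort response-category distribution
#'
#' @param final_categories Character vector of final per-patient categories
#'   (`"CR"`, `"PR"`, `"SD"`, `"PD"`).
#' @return Data frame with `category`, `n` and `percent` (two decimals,
#'   summing to 100 up to rounding) for each of the four categories; order
#'   CR, PR, SD, PD.
#' @export
#' @examples
#' cohort_distribution(c(rep("SD", 9), rep("PD", 2), rep("PR", 3)))
cohort_distribution <- function(final_categories) {
  if (length(final_categories) == 0L)
    stop("at least one patient is required", call. = FALSE)
  bad <- setdiff(unique(final_categories), RESPONSE_CATEGORIES)
  if (length(bad))
    stop("unknown categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- table(factor(final_categories, levels = RESPONSE_CATEGORIES))
  data.frame(category = RESPONSE_CATEGORIES,
             n = as.integer(n),
             percent = round(100 * as.integer(n) / length(final_categories),
                             2),
             stringsAsFactors = FALSE)
}
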