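#' Read sphere VOI definitions from CSV or JSON
#'
#' The file must provide one record per VOI with fields `label`, `x_mm`,
#' `y_mm`, `z_mm`, `radius_mm` and optionally `site`. Format is chosen by
#' file extension (`.csv` vs `.json`).
#'
#' @param path Path to a `.csv` or `.json` sphere list.
#' @return List of [sphere_voi()] objects.
#' @export
read_sphere_vois <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    stop("unsupported VOI file type: .", ext, call. = FALSE))
  need <- c("label", "x_mm", "y_mm", "z_mm", "radius_mm")
  if (!all(need %in% names(df)))
    stop("VOI file must provide fields: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"site" %in% names(df)) df$site <- "other"
  lapply(seq_len(nrow(df)), function(i)
    sphere_voi(c(df$x_mm[i], df$y_mm[i], df$z_mm[i]), df$radius_mm[i],
               label = df$label[i], site = df$site[i]))
}

#' Write a lesion measurement table to CSV
#'
#' @param measurements Data frame from [measure_lesions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' Write a scanner qualification report to JSON
#'
#' @param qual A [qualify_scanner()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qualification_json <- function(qual, path) {
  stopifnot(inherits(qual, "scanner_qualification"))
  jsonlite::write_json(
    list(pass = qual$pass,
         min_accuracy_pct = qual$min_accuracy_pct,
         sensitivity_deviation_pct = qual$sensitivity_deviation_pct,
         threshold_pct = qual$threshold_pct,
         failures = qual$failures,
         spheres = qual$spheres),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
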