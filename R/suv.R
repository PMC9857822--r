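#' Patient physiology record
#'
#' Weight, height and sex, as needed by the lean-body-mass (LBM) formulas.
#' Inputs outside conventional adult sanity bounds (20-300 kg, 100-250 cm)
#' are rejected unless `override = TRUE`.
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_cm Standing height in centimetres (> 0).
#' @param sex `"male"` or `"female"`.
#' @param override Skip the sanity-bound check (formula still requires
#'   strictly positive inputs).
#' @return An object of class `patient_physiology`.
#' @export
patient_physiology <- function(weight_kg, height_cm,
                               sex = c("male", "female"),
                               override = FALSE) {
  sex <- match.arg(sex)
  if (!is.finite(weight_kg) || weight_kg <= 0 ||
      !is.finite(height_cm) || height_cm <= 0)
    stop("weight and height must be positive", call. = FALSE)
  if (!override &&
      (weight_kg < 20 || weight_kg > 300 || height_cm < 100 || height_cm > 250))
    stop(sprintf(
      "physiology outside sanity bounds (weight %.1f kg, height %.1f cm); ",
      weight_kg, height_cm),
      "use override = TRUE if intentional", call. = FALSE)
  structure(list(weight_kg = weight_kg, height_cm = height_cm, sex = sex),
            class = "patient_physiology")
}

#' Lean body mass by the James formulas
#'
#' LBM in kg is computed from weight `w` (kg) and height `h` (cm) as
#' `1.10 w - 120 (w/h)^2` for males and `1.07 w - 148 (w/h)^2` for females.
#' SUV normalized to LBM rather than body weight avoids the bias that body
#' fat (which takes up little tracer) introduces into uptake values.
#'
#' @param phys A [patient_physiology()].
#' @return Lean body mass in kg (> 0, or 0 in the degenerate zero-weight
#'   limit).
#' @export
#' @examples
#' compute_lbm(patient_physiology(80, 180, "male"))    # 64.296
#' compute_lbm(patient_physiology(60, 165, "female"))  # 44.630
compute_lbm <- function(phys) {
  stopifnot(inherits(phys, "patient_physiology"))
  w <- phys$weight_kg
  h <- phys$height_cm
  lbm <- switch(phys$sex,
    male   = 1.10 * w - 120 * (w / h)^2,
    female = 1.07 * w - 148 * (w / h)^2
  )
  if (lbm < 0)
    stop(sprintf(
      "LBM formula yields %.2f kg for %s, %.1f kg, %.1f cm; ",
      lbm, phys$sex, w, h),
      "inputs are outside the formula's validity range", call. = FALSE)
  lbm
}

# hours between two time points; accepts POSIXct or bare numerics
# (interpreted as hours on a common clock)
hours_between <- function(from, to) {
  if (inherits(from, "POSIXt") || inherits(to, "POSIXt"))
    as.numeric(difftime(to, from, units = "hours"))
  else
    as.numeric(to) - as.numeric(from)
}

#' Administered-activity record
#'
#' Holds the syringe activity measurements and the four timestamps of the
#' decay-correction cascade: the pre-injection measurement time, the
#' administration (injection) time, the residual-syringe measurement time
#' post injection, and the scan time. Timestamps may be `POSIXct` or plain
#' numerics in hours on a common clock.
#'
#' @param measured_activity_MBq Pre-injection syringe activity (MBq).
#' @param residual_activity_MBq Post-injection residual syringe activity
#'   (MBq); must not exceed the measured activity.
#' @param measured_time,administered_time,postinjection_time,scan_time
#'   Event timestamps; must satisfy `measured <= administered <= scan` and
#'   `measured <= postinjection`.
#' @param half_life_h Physical half-life of the radionuclide in hours
#'   (default 6.0067 h, technetium-99m).
#' @return An object of class `activity_record` with derived field
#'   `lambda_per_h = 0.693 / half_life_h`.
#' @export
activity_record <- function(measured_activity_MBq, residual_activity_MBq,
                            measured_time, administered_time,
                            postinjection_time, scan_time,
                            half_life_h = 6.0067) {
  if (!is.finite(measured_activity_MBq) || measured_activity_MBq < 0)
    stop("measured activity must be >= 0", call. = FALSE)
  if (!is.finite(residual_activity_MBq) || residual_activity_MBq < 0)
    stop("residual activity must be >= 0", call. = FALSE)
  if (residual_activity_MBq > measured_activity_MBq)
    stop("residual activity exceeds measured activity", call. = FALSE)
  if (half_life_h <= 0) stop("half-life must be positive", call. = FALSE)
  eps <- 1e-9
  if (hours_between(measured_time, administered_time) < -eps)
    stop("measured_time must not be after administered_time", call. = FALSE)
  if (hours_between(administered_time, scan_time) < -eps)
    stop("administered_time must not be after scan_time", call. = FALSE)
  if (hours_between(measured_time, postinjection_time) < -eps)
    stop("measured_time must not be after postinjection_time", call. = FALSE)
  structure(
    list(measured_activity_MBq = measured_activity_MBq,
         residual_activity_MBq = residual_activity_MBq,
         measured_time = measured_time,
         administered_time = administered_time,
         postinjection_time = postinjection_time,
         scan_time = scan_time,
         half_life_h = half_life_h,
         lambda_per_h = 0.693 / half_life_h),
    class = "activity_record"
  )
}

#' Radioactive decay factor
#'
#' Returns `exp(lambda * delta_t)`. The sign convention follows the cascade
#' in [actual_activity()]: a negative `delta_t` (earlier-to-later reference)
#' decays activity forward in time, a positive one back-corrects it.
#'
#' @param lambda_per_h Decay constant in 1/h (> 0), `0.693 / half_life`.
#' @param delta_t_h Signed time difference in hours.
#' @return The dimensionless decay factor.
#' @export
decay_factor <- function(lambda_per_h, delta_t_h) {
  if (!is.finite(lambda_per_h) || lambda_per_h <= 0)
    stop("lambda must be positive", call. = FALSE)
  exp(lambda_per_h * delta_t_h)
}

#' Net administered activity decayed to scan time
#'
#' Composes the three decay factors of the syringe cascade exactly as used
#' in clinical SUV quantification:
#' \deqn{A = d_{scan} \, d_1 \, (A_{meas} - d_2 A_{resid})}
#' with `d1 = exp(lambda (t_measured - t_administered))`,
#' `d2 = exp(lambda (t_postinjection - t_measured))` and
#' `d_scan = exp(lambda (t_administered - t_scan))`. The residual syringe
#' activity is back-corrected to the measurement time (`d2 >= 1`), the net
#' injected activity is decayed to the administration time (`d1 <= 1`) and
#' then to the scan time (`d_scan <= 1`).
#'
#' @param rec An [activity_record()].
#' @return Activity at scan time in MBq (>= 0).
#' @export
#' @examples
#' rec <- activity_record(800, 40, 0, 0, 0, 6.0067)
#' actual_activity(rec)  # 380.0: 760 MBq decayed one half-life
actual_activity <- function(rec) {
  stopifnot(inherits(rec, "activity_record"))
  lam <- rec$lambda_per_h
  d1 <- decay_factor(lam, hours_between(rec$administered_time,
                                        rec$measured_time))
  d2 <- decay_factor(lam, hours_between(rec$measured_time,
                                        rec$postinjection_time))
  dscan <- decay_factor(lam, hours_between(rec$scan_time,
                                           rec$administered_time))
  net <- rec$measured_activity_MBq - d2 * rec$residual_activity_MBq
  if (net < 0)
    stop(sprintf(
      "back-decayed residual (%.2f MBq) exceeds measured activity (%.2f MBq)",
      d2 * rec$residual_activity_MBq, rec$measured_activity_MBq),
      call. = FALSE)
  dscan * d1 * net
}

#' Convert an activity-concentration volume to SUV (lean body mass)
#'
#' Applies, voxelwise,
#' \deqn{SUV_{lbm} = \frac{C \,[\mathrm{Bq/mL}] \times LBM \,[\mathrm{kg}]
#'   \times 1000}{A_{actual} \,[\mathrm{Bq}]} \quad [\mathrm{g/mL}]}
#' where the actual activity is the administered dose decay-corrected to
#' scan time ([actual_activity()]). The conversion is linear in the
#' activity concentration, so every downstream SUV statistic scales with
#' the input volume.
#'
#' @param activity_vol A [voxel_volume()] of activity concentrations in
#'   Bq/mL.
#' @param phys A [patient_physiology()].
#' @param rec An [activity_record()].
#' @return A [suv_volume()] with the same geometry.
#' @export
to_suv_volume <- function(activity_vol, phys, rec) {
  stopifnot(inherits(activity_vol, "voxel_volume"))
  lbm_kg <- compute_lbm(phys)
  act_MBq <- actual_activity(rec)
  if (act_MBq <= 0)
    stop("actual activity at scan time is not positive; cannot form SUV",
         call. = FALSE)
  scale <- lbm_kg * 1000 / (act_MBq * 1e6)  # (kg -> g) / (MBq -> Bq)
  suv_volume(activity_vol$values * scale,
             voxel_size_mm = activity_vol$voxel_size_mm,
             origin_mm = activity_vol$origin_mm)
}

# inverse of the SUV conversion: the activity concentration (Bq/mL) a voxel
# must hold so that to_suv_volume() maps it to `suv`; used by the synthetic
# generator so round trips are exact
suv_to_activity_conc <- function(suv, phys, rec) {
  lbm_kg <- compute_lbm(phys)
  act_MBq <- actual_activity(rec)
  suv * act_MBq * 1e6 / (lbm_kg * 1000)
}
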