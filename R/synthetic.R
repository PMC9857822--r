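#' Synthetic volume generator configuration
#'
#' Defaults (4 mm isotropic voxels, a 64^3 grid) give a desk-scale volume
#' whose 1-cm3 SUVpeak kernel spans at least two voxels per axis.
#'
#' @param seed Integer RNG seed, or `NA` to leave the RNG state untouched
#'   (useful when a caller manages its own stream).
#' @param voxel_size_mm Isotropic voxel edge length (mm, > 0).
#' @param grid_shape Integer triple of grid dimensions.
#' @param background_uptake Background tissue uptake in SUV units (>= 0).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   voxel noise (mean 1, sd `noise_cv`, clipped at 0); must be < 1.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = NA_integer_, voxel_size_mm = 4,
                             grid_shape = c(64L, 64L, 64L),
                             background_uptake = 1.0, noise_cv = 0) {
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be positive", call. = FALSE)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("grid_shape must be three positive integers", call. = FALSE)
  if (background_uptake < 0)
    stop("background_uptake must be >= 0", call. = FALSE)
  if (noise_cv < 0 || noise_cv >= 1)
    stop("noise_cv must be in [0, 1)", call. = FALSE)
  # the SUVpeak kernel must fit into the grid
  off <- kernel_offsets(voxel_size_mm)
  span <- 2L * max(abs(off)) + 1L
  if (any(grid_shape < span))
    stop(sprintf("grid dimensions must be >= %d voxels to hold the 1-cm3 kernel",
                 span), call. = FALSE)
  structure(list(seed = seed, voxel_size_mm = voxel_size_mm,
                 grid_shape = as.integer(grid_shape),
                 background_uptake = background_uptake,
                 noise_cv = noise_cv),
            class = "generator_config")
}

#' Lesion specification for the synthetic generator
#'
#' A spherical lesion of uniform uptake `true_suv`. If `true_suv_peak` is
#' supplied the lesion is built with two compartments — a single hottest
#' voxel at `true_suv` inside a cooler rim — with the rim value solved so
#' that the 1-cm3 kernel mean centered on the hot voxel equals
#' `true_suv_peak` exactly. This makes both SUVmax and SUVpeak
#' analytically known.
#'
#' @param center_mm Lesion center, physical mm.
#' @param radius_mm Lesion radius (mm); must be at least one voxel.
#' @param true_suv Uniform (or hot-voxel) uptake in SUV units (> 0).
#' @param site Anatomical site label.
#' @param true_suv_peak Optional target 1-cm3 kernel mean; must lie in
#'   `[true_suv / K, true_suv]` where `K` is the kernel voxel count.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radius_mm, true_suv,
                        site = c("liver", "lymph_node", "bone", "other"),
                        true_suv_peak = NA_real_) {
  site <- match.arg(site)
  if (!is.finite(true_suv) || true_suv <= 0)
    stop("true_suv must be positive", call. = FALSE)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("radius_mm must be positive", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 true_suv = true_suv, site = site,
                 true_suv_peak = true_suv_peak),
            class = "lesion_spec")
}

# default subject: the physiology/administration pair assumed by the
# generator when none is supplied (LBM 64.296 kg; ~740 MBq net dose,
# SPECT acquired 4 h post injection)
default_physiology <- function() patient_physiology(80, 180, "male")

default_activity_record <- function() {
  activity_record(measured_activity_MBq = 770,
                  residual_activity_MBq = 30,
                  measured_time = 0, administered_time = 0.25,
                  postinjection_time = 0.3, scan_time = 4.25)
}

check_spheres_disjoint <- function(centers, radii, labels) {
  n <- nrow(centers)
  if (n < 2L) return(invisible(TRUE))
  for (a in seq_len(n - 1L)) {
    d2 <- (centers[(a + 1L):n, 1L] - centers[a, 1L])^2 +
          (centers[(a + 1L):n, 2L] - centers[a, 2L])^2 +
          (centers[(a + 1L):n, 3L] - centers[a, 3L])^2
    bad <- which(sqrt(d2) < radii[a] + radii[(a + 1L):n])
    if (length(bad))
      stop(sprintf("spheres '%s' and '%s' overlap", labels[a],
                   labels[a + bad[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic patient activity volume
#'
#' Builds an activity-concentration volume (Bq/mL) containing spherical
#' lesions and reference-tissue spheres over a uniform background, such
#' that converting it with the paired physiology and activity record
#' ([to_suv_volume()]) recovers each lesion's `true_suv` exactly in the
#' noise-free case. Voxel membership is by voxel-center inclusion.
#' Multiplicative Gaussian noise (mean 1, sd `noise_cv`, clipped at 0) is
#' applied after the uptake field is laid down.
#'
#' @param config A [generator_config()]; if `config$seed` is not `NA` the
#'   RNG is seeded, making the volume bitwise reproducible.
#' @param lesions List of [lesion_spec()] objects.
#' @param reference_tissues List of [lesion_spec()] objects for reference
#'   tissues (uniform spheres; `site` may be any label).
#' @param phys,rec Physiology and activity record paired with the volume;
#'   defaults are an 80 kg / 180 cm male and a ~740 MBq net administration
#'   scanned 4 h post injection.
#' @return A list: `volume` (activity [voxel_volume()], Bq/mL), `suv_truth`
#'   (data frame of per-lesion ground truth), `reference_truth`,
#'   `physiology`, `activity_record`, `config`.
#' @export
generate_patient_volume <- function(config, lesions,
                                    reference_tissues = list(),
                                    phys = default_physiology(),
                                    rec = default_activity_record()) {
  stopifnot(inherits(config, "generator_config"))
  all_specs <- c(lesions, reference_tissues)
  if (!all(vapply(all_specs, inherits, logical(1L), "lesion_spec")))
    stop("lesions and reference_tissues must be lesion_spec objects",
         call. = FALSE)
  if (!is.na(config$seed)) set.seed(config$seed)

  vs <- config$voxel_size_mm
  d <- config$grid_shape
  probe <- voxel_volume(array(0, dim = d), vs)
  labels <- c(sprintf("lesion_%03d", seq_along(lesions)),
              sprintf("ref_%03d", seq_along(reference_tissues)))
  centers <- do.call(rbind, lapply(all_specs, `[[`, "center_mm"))
  radii <- vapply(all_specs, `[[`, numeric(1L), "radius_mm")
  for (s in seq_along(all_specs)) {
    if (radii[s] < vs)
      stop(sprintf("sphere '%s': radius %.1f mm is below one voxel",
                   labels[s], radii[s]), call. = FALSE)
    if (!sphere_inside_grid(probe, centers[s, ], radii[s]))
      stop(sprintf("sphere '%s' is not fully inside the grid", labels[s]),
           call. = FALSE)
  }
  check_spheres_disjoint(centers, radii, labels)

  K <- nrow(kernel_offsets(vs))
  suv <- array(config$background_uptake, dim = d)
  paint <- function(spec, label) {
    m <- sphere_voxel_indices(probe, spec$center_mm, spec$radius_mm)
    if (nrow(m) == 0L)
      stop(sprintf("sphere '%s' contains no voxel centers", label),
           call. = FALSE)
    if (is.na(spec$true_suv_peak)) {
      suv[m[, "idx"]] <<- spec$true_suv
    } else {
      pk <- spec$true_suv_peak
      if (pk > spec$true_suv + 1e-9 || pk < spec$true_suv / K - 1e-9)
        stop(sprintf(
          "sphere '%s': true_suv_peak %.3f outside attainable range [%.3f, %.3f]",
          label, pk, spec$true_suv / K, spec$true_suv), call. = FALSE)
      rim <- (K * pk - spec$true_suv) / (K - 1)
      suv[m[, "idx"]] <<- rim
      # hottest voxel: the member voxel nearest the lesion center
      cx <- probe$origin_mm[1L] + (m[, "i"] - 0.5) * vs
      cy <- probe$origin_mm[2L] + (m[, "j"] - 0.5) * vs
      cz <- probe$origin_mm[3L] + (m[, "k"] - 0.5) * vs
      hot <- which.min((cx - spec$center_mm[1L])^2 +
                       (cy - spec$center_mm[2L])^2 +
                       (cz - spec$center_mm[3L])^2)
      suv[m[hot, "idx"]] <<- spec$true_suv
    }
  }
  for (s in seq_along(lesions)) paint(lesions[[s]], labels[s])
  for (s in seq_along(reference_tissues))
    paint(reference_tissues[[s]], labels[length(lesions) + s])

  if (config$noise_cv > 0)
    suv <- suv * pmax(0, stats::rnorm(length(suv), 1, config$noise_cv))

  conc <- suv_to_activity_conc(suv, phys, rec)
  truth_df <- function(specs, labs) {
    if (!length(specs))
      return(data.frame(lesion_id = character(0), site = character(0),
                        x_mm = numeric(0), y_mm = numeric(0),
                        z_mm = numeric(0), radius_mm = numeric(0),
                        true_suv_max = numeric(0),
                        true_suv_peak = numeric(0),
                        stringsAsFactors = FALSE))
    data.frame(lesion_id = labs,
               site = vapply(specs, `[[`, character(1L), "site"),
               x_mm = vapply(specs, function(s) s$center_mm[1L], 0),
               y_mm = vapply(specs, function(s) s$center_mm[2L], 0),
               z_mm = vapply(specs, function(s) s$center_mm[3L], 0),
               radius_mm = vapply(specs, `[[`, numeric(1L), "radius_mm"),
               true_suv_max = vapply(specs, `[[`, numeric(1L), "true_suv"),
               true_suv_peak = vapply(specs, `[[`, numeric(1L),
                                      "true_suv_peak"),
               stringsAsFactors = FALSE)
  }
  list(volume = voxel_volume(conc, vs, units = "Bq/mL"),
       suv_truth = truth_df(lesions, labels[seq_along(lesions)]),
       reference_truth = truth_df(reference_tissues,
                                  labels[length(lesions) +
                                         seq_along(reference_tissues)]),
       physiology = phys, activity_record = rec, config = config)
}

# ---- truncated-normal machinery ------------------------------------------

# location parameter of a normal(mu, sd) truncated below at `lower` whose
# post-truncation mean equals `target`; solved numerically (the spread
# parameter is kept at its nominal value)
truncnorm_location <- function(target_mean, sd, lower = 0) {
  stopifnot(sd > 0, target_mean > lower)
  haz <- function(a) exp(stats::dnorm(a, log = TRUE) -
                         stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  f <- function(mu) mu + sd * haz((lower - mu) / sd) - target_mean
  stats::uniroot(f, c(target_mean - 6 * sd, target_mean + sd),
                 tol = 1e-10)$root
}

# inverse-CDF sampler for a normal truncated below at `lower`
rtruncnorm_lower <- function(n, location, sd, lower = 0) {
  plo <- stats::pnorm(lower, location, sd)
  stats::qnorm(stats::runif(n, plo, 1), location, sd)
}

#' Default uptake distribution parameters by metastatic site
#'
#' Site-stratified means and standard deviations of lesion SUVmax, lesion
#' SUVpeak, healthy reference-tissue SUVmax, the target-to-normal (TL/N)
#' ratio, and the SUVmax-SUVpeak correlation, as typically reported for
#' somatostatin-receptor SPECT/CT in metastatic neuroendocrine disease.
#' These are the calibration targets of the synthetic generator: cohorts
#' drawn from them (via location-recalibrated truncated normals) should be
#' recovered by the quantification pipeline within sampling error.
#'
#' @return Data frame with one row per site (`liver`, `lymph_node`,
#'   `bone`) and the reference tissue used for its TL/N ratio (liver
#'   background, spleen, normal vertebra respectively).
#' @export
reference_uptake_table <- function() {
  data.frame(
    site = c("liver", "lymph_node", "bone"),
    suv_max_mean = c(12.44, 11.98, 5.90),
    suv_max_sd = c(7.76, 10.45, 3.68),
    suv_peak_mean = c(10.15, 8.81, 5.55),
    suv_peak_sd = c(6.79, 7.99, 2.47),
    peak_cor = c(0.982, 0.980, 0.920),
    ref_site = c("liver", "spleen", "vertebra"),
    ref_mean = c(3.34, 8.01, 0.66),
    ref_sd = c(0.93, 5.31, 0.37),
    tln_mean = c(4.20, 1.84, 9.37),
    tln_sd = c(2.67, 1.53, 2.91),
    stringsAsFactors = FALSE
  )
}

site_params <- function(site) {
  tab <- reference_uptake_table()
  row <- tab[tab$site == site, , drop = FALSE]
  if (nrow(row) == 0L)
    stop(sprintf("no uptake parameters for site '%s'", site),
         call. = FALSE)
  row
}

# draw (suv_max, suv_peak) pairs for one site: SUVmax from a truncated
# normal with recalibrated location; SUVpeak conditionally normal with the
# site's correlation, then clipped into the attainable band
# [suv_max / K, suv_max] of the two-compartment lesion model
draw_lesion_pairs <- function(n, site, kernel_voxels) {
  p <- site_params(site)
  loc <- truncnorm_location(p$suv_max_mean, p$suv_max_sd)
  smax <- rtruncnorm_lower(n, loc, p$suv_max_sd)
  b <- p$peak_cor * p$suv_peak_sd / p$suv_max_sd
  csd <- p$suv_peak_sd * sqrt(1 - p$peak_cor^2)
  speak <- p$suv_peak_mean + b * (smax - p$suv_max_mean) +
    stats::rnorm(n, 0, csd)
  speak <- pmin(pmax(speak, smax / kernel_voxels + 1e-6), smax)
  data.frame(suv_max = smax, suv_peak = speak)
}

# ---- phantom --------------------------------------------------------------

#' Hot-sphere phantom specification
#'
#' Describes a NEMA-style phantom: a set of disjoint fillable hot spheres
#' with known true activity concentrations over a cooler background, plus
#' the fractional band within which measured concentrations may deviate
#' from truth.
#'
#' @param sphere_specs Data frame with columns `x_mm`, `y_mm`, `z_mm`,
#'   `radius_mm`, `true_concentration` (Bq/mL, > 0); defaults to the
#'   conventional six-sphere layout (10-37 mm diameters on a ring) filled
#'   at 8:1 against background.
#' @param background_concentration Background concentration (Bq/mL, >= 0).
#' @param measurement_deviation Maximum fractional measurement deviation
#'   per sphere, in `[0, 1]`; the default 0.05 matches the 0-5% band
#'   within which a calibrated system is expected to operate.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(sphere_specs = default_nema_spheres(),
                         background_concentration = 3500,
                         measurement_deviation = 0.05) {
  need <- c("x_mm", "y_mm", "z_mm", "radius_mm", "true_concentration")
  if (!is.data.frame(sphere_specs) || !all(need %in% names(sphere_specs)))
    stop("sphere_specs must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(sphere_specs$true_concentration <= 0))
    stop("sphere concentrations must be positive", call. = FALSE)
  if (background_concentration < 0)
    stop("background concentration must be >= 0", call. = FALSE)
  if (measurement_deviation < 0 || measurement_deviation > 1)
    stop("measurement_deviation must be in [0, 1]", call. = FALSE)
  check_spheres_disjoint(
    as.matrix(sphere_specs[, c("x_mm", "y_mm", "z_mm")]),
    sphere_specs$radius_mm,
    sprintf("sphere_%d", seq_len(nrow(sphere_specs))))
  structure(list(sphere_specs = sphere_specs,
                 background_concentration = background_concentration,
                 measurement_deviation = measurement_deviation),
            class = "phantom_spec")
}

#' Conventional six-sphere phantom layout
#'
#' Six fillable spheres of 10, 13, 17, 22, 28 and 37 mm diameter arranged
#' on a 114.4 mm diameter ring, filled at the given concentration.
#'
#' @param concentration Uniform true activity concentration (Bq/mL).
#' @return Data frame suitable for [phantom_spec()].
#' @export
default_nema_spheres <- function(concentration = 28000) {
  ang <- (0:5) * pi / 3
  ring <- 114.4 / 2
  data.frame(
    sphere_id = sprintf("sphere_%02.0fmm", c(10, 13, 17, 22, 28, 37)),
    x_mm = round(ring * cos(ang), 2),
    y_mm = round(ring * sin(ang), 2),
    z_mm = 0,
    radius_mm = c(10, 13, 17, 22, 28, 37) / 2,
    true_concentration = concentration,
    stringsAsFactors = FALSE
  )
}

#' Simulate a phantom calibration measurement
#'
#' Perturbs each sphere's true concentration by a fractional error drawn
#' uniformly from `[-d, d]` where `d` is the spec's
#' `measurement_deviation`, so every measured value satisfies
#' `measured = true * (1 + delta)` with `|delta| <= d`. With `d <= 0.05`
#' the accuracy equation therefore yields at least 95% for every sphere.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer RNG seed, or `NA` to use the current RNG state.
#' @return Data frame with `sphere_id`, `true_concentration`,
#'   `measured_concentration`, `deviation_frac`.
#' @export
generate_phantom <- function(spec, seed = NA_integer_) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.na(seed)) set.seed(seed)
  n <- nrow(spec$sphere_specs)
  delta <- stats::runif(n, -spec$measurement_deviation,
                        spec$measurement_deviation)
  ids <- if ("sphere_id" %in% names(spec$sphere_specs))
    spec$sphere_specs$sphere_id else sprintf("sphere_%d", seq_len(n))
  data.frame(sphere_id = ids,
             true_concentration = spec$sphere_specs$true_concentration,
             measured_concentration =
               spec$sphere_specs$true_concentration * (1 + delta),
             deviation_frac = delta,
             stringsAsFactors = FALSE)
}

# ---- longitudinal cohort ---------------------------------------------------

#' Per-patient outcome trajectory specification
#'
#' Encodes what each follow-up scan should show relative to baseline: a
#' multiplier applied to every baseline lesion's SUV (so the summed SUVmax
#' changes by exactly that factor) and whether new tumoral foci appear.
#'
#' @param multipliers Numeric vector, one per follow-up scan; each is the
#'   ratio of that scan's lesion SUVs to baseline (>= 0).
#' @param new_lesions Logical vector, same length; `TRUE` adds a new
#'   lesion to that scan.
#' @param expect Optional character vector of intended response categories
#'   per follow-up (used for validation only). Requesting `"CR"` while
#'   the multiplier leaves residual uptake is rejected.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(multipliers,
                            new_lesions = rep(FALSE, length(multipliers)),
                            expect = NULL) {
  if (length(multipliers) < 1L || any(multipliers < 0))
    stop("multipliers must be non-negative and non-empty", call. = FALSE)
  if (length(new_lesions) != length(multipliers))
    stop("new_lesions must match multipliers in length", call. = FALSE)
  if (!is.null(expect)) {
    if (length(expect) != length(multipliers) ||
        !all(expect %in% RESPONSE_CATEGORIES))
      stop("expect must name one CR/PR/SD/PD category per follow-up",
           call. = FALSE)
    bad <- which(expect == "CR" & (multipliers > 0 | new_lesions))
    if (length(bad))
      stop(sprintf(
        "follow-up %d requests CR while lesions retain uptake", bad[1L]),
        call. = FALSE)
  }
  structure(list(multipliers = multipliers,
                 new_lesions = as.logical(new_lesions), expect = expect),
            class = "trajectory_spec")
}

#' The 14-patient reference outcome plan
#'
#' A longitudinal plan matching the outcome structure of a 14-patient
#' somatostatin-receptor SPECT/CT monitoring cohort: 35 scans in total
#' (14 baselines, 21 follow-ups), four patients with multiple follow-ups
#' (continuous progression; stable-stable-partial response;
#' progression-partial response-stable; progression-stable), one
#' progression driven by new lesions despite decreasing uptake, and final
#' categories of 9 SD, 3 PR and 2 PD (64.29% / 21.43% / 14.29%).
#'
#' @return Named list of [trajectory_spec()] objects, one per patient.
#' @export
cohort14_plan <- function() {
  list(
    P01 = trajectory_spec(c(1.40, 1.80, 2.30),
                          expect = c("PD", "PD", "PD")),
    P02 = trajectory_spec(c(1.10, 1.20, 0.65),
                          expect = c("SD", "SD", "PR")),
    P03 = trajectory_spec(c(1.50, 0.65, 0.90),
                          expect = c("PD", "PR", "SD")),
    P04 = trajectory_spec(c(1.50, 1.15), expect = c("PD", "SD")),
    P05 = trajectory_spec(0.60, new_lesions = TRUE, expect = "PD"),
    P06 = trajectory_spec(0.55, expect = "PR"),
    P07 = trajectory_spec(0.65, expect = "PR"),
    P08 = trajectory_spec(0.85, expect = "SD"),
    P09 = trajectory_spec(0.95, expect = "SD"),
    P10 = trajectory_spec(1.00, expect = "SD"),
    P11 = trajectory_spec(1.05, expect = "SD"),
    P12 = trajectory_spec(1.15, expect = "SD"),
    P13 = trajectory_spec(1.25, expect = "SD"),
    P14 = trajectory_spec(0.75, expect = "SD")
  )
}

#' Generate a longitudinal synthetic cohort
#'
#' Produces per-patient physiology, immunohistochemical marker flags, a
#' ki67 proliferation index drawn independently of uptake, and per-scan
#' lesion tables whose summed SUVmax follows each patient's
#' [trajectory_spec()] exactly (follow-up lesions are baseline lesions
#' scaled by the requested multiplier, so the requested change is
#' reproduced to floating-point precision; scans with new lesions
#' additionally carry a flagged new focus).
#'
#' @param seed Integer RNG seed.
#' @param n_patients Number of patients; 0 yields a valid empty bundle.
#' @param outcome_plan List of [trajectory_spec()], one per patient;
#'   defaults to single-follow-up stable disease for every patient. Use
#'   [cohort14_plan()] for the 14-patient reference cohort.
#' @param lesions_per_patient Integer range from which each patient's
#'   baseline lesion count is drawn (default 2 to 8).
#' @param marker_mode `"exact"` assigns each marker to
#'   `round(rate * n_patients)` randomly chosen patients so cohort
#'   positivity rates are exact; `"bernoulli"` samples independently.
#' @return A list of class `synthetic_cohort`: `patients`, `scans`,
#'   `lesions` data frames and the `plan`.
#' @export
generate_cohort <- function(seed, n_patients,
                            outcome_plan = NULL,
                            lesions_per_patient = c(2L, 8L),
                            marker_mode = c("exact", "bernoulli")) {
  marker_mode <- match.arg(marker_mode)
  set.seed(seed)
  marker_rates <- c(cga = 0.857, syn = 0.929, nse = 0.214,
                    cd56 = 0.143, ser = 0.571, hiaa = 0.143)
  empty <- list(
    patients = data.frame(patient_id = character(0)),
    scans = data.frame(patient_id = character(0),
                       scan_id = character(0)),
    lesions = data.frame(patient_id = character(0),
                         scan_id = character(0)),
    plan = list())
  class(empty) <- "synthetic_cohort"
  if (n_patients == 0L) return(empty)

  if (is.null(outcome_plan))
    outcome_plan <- replicate(n_patients, trajectory_spec(1.0),
                              simplify = FALSE)
  if (length(outcome_plan) != n_patients)
    stop("outcome_plan must supply one trajectory per patient",
         call. = FALSE)
  ok <- vapply(outcome_plan, inherits, logical(1L), "trajectory_spec")
  if (!all(ok))
    stop("outcome_plan entries must be trajectory_spec objects",
         call. = FALSE)

  pids <- if (!is.null(names(outcome_plan)) &&
              all(nzchar(names(outcome_plan))))
    names(outcome_plan) else sprintf("P%02d", seq_len(n_patients))
  K <- nrow(kernel_offsets(4))
  site_pool <- c("liver", "lymph_node", "bone", "other")
  site_prob <- c(0.52, 0.203, 0.057, 0.22)

  # patient-level attributes; ki67 is drawn independently of every SUV
  sex <- ifelse(stats::runif(n_patients) < 0.643, "male", "female")
  weight <- pmin(pmax(stats::rnorm(n_patients, 75, 12), 45), 120)
  height <- pmin(pmax(stats::rnorm(n_patients, 170, 9), 150), 195)
  ki67 <- rtruncnorm_lower(n_patients,
                           truncnorm_location(7, 6.25, lower = 1),
                           6.25, lower = 1)
  markers <- sapply(marker_rates, function(rate) {
    if (marker_mode == "exact") {
      pos <- sample.int(n_patients, round(rate * n_patients))
      seq_len(n_patients) %in% pos
    } else stats::runif(n_patients) < rate
  })
  patients <- data.frame(patient_id = pids, sex = sex,
                         weight_kg = round(weight, 1),
                         height_cm = round(height, 1),
                         ki67_pct = round(ki67, 1),
                         stringsAsFactors = FALSE)
  colnames(markers) <- paste0("marker_", names(marker_rates))
  patients <- cbind(patients, as.data.frame(markers))

  scan_rows <- list()
  lesion_rows <- list()
  for (p in seq_len(n_patients)) {
    traj <- outcome_plan[[p]]
    n_les <- sample(seq(lesions_per_patient[1L], lesions_per_patient[2L]),
                    1L)
    sites <- sample(site_pool, n_les, replace = TRUE, prob = site_prob)
    base <- do.call(rbind, lapply(seq_len(n_les), function(i) {
      s <- if (sites[i] == "other") "liver" else sites[i]
      pair <- draw_lesion_pairs(1L, s, K)
      data.frame(lesion_id = sprintf("%s_L%02d", pids[p], i),
                 site = sites[i], suv_max = pair$suv_max,
                 suv_peak = pair$suv_peak, stringsAsFactors = FALSE)
    }))
    scan_ids <- sprintf("%s_S%d", pids[p],
                        0:length(traj$multipliers))
    for (k in seq_along(scan_ids)) {
      is_base <- k == 1L
      mult <- if (is_base) 1 else traj$multipliers[k - 1L]
      tab <- base
      tab$suv_max <- tab$suv_max * mult
      tab$suv_peak <- tab$suv_peak * mult
      tab$is_new <- FALSE
      new_flag <- !is_base && traj$new_lesions[k - 1L]
      if (new_flag) {
        s <- sample(site_pool, 1L, prob = site_prob)
        pair <- draw_lesion_pairs(1L, if (s == "other") "liver" else s, K)
        tab <- rbind(tab, data.frame(
          lesion_id = sprintf("%s_NEW%d", pids[p], k - 1L),
          site = s, suv_max = pair$suv_max, suv_peak = pair$suv_peak,
          is_new = TRUE, stringsAsFactors = FALSE))
      }
      tab$patient_id <- pids[p]
      tab$scan_id <- scan_ids[k]
      scan_rows[[length(scan_rows) + 1L]] <- data.frame(
        patient_id = pids[p], scan_id = scan_ids[k],
        followup_index = k - 1L, new_lesion_flag = new_flag,
        stringsAsFactors = FALSE)
      lesion_rows[[length(lesion_rows) + 1L]] <- tab
    }
  }
  out <- list(patients = patients,
              scans = do.call(rbind, scan_rows),
              lesions = do.call(rbind, lesion_rows),
              plan = outcome_plan)
  class(out) <- "synthetic_cohort"
  out
}

#' Build per-scan target lesion sets from a synthetic cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param max_targets Passed to [select_targets()].
#' @return Named list (by patient) of chronologically ordered
#'   [select_targets()] results, ready for [evaluate_patient()].
#' @export
cohort_target_sets <- function(cohort, max_targets = 5) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lapply(split(cohort$scans, cohort$scans$patient_id), function(sc) {
    sc <- sc[order(sc$followup_index), , drop = FALSE]
    lapply(seq_len(nrow(sc)), function(k) {
      les <- cohort$lesions[cohort$lesions$scan_id == sc$scan_id[k], ,
                            drop = FALSE]
      select_targets(les, max_targets = max_targets,
                     scan_id = sc$scan_id[k],
                     patient_id = sc$patient_id[k],
                     new_lesion_flag = sc$new_lesion_flag[k])
    })
  })
}

#' Evaluate every patient in a synthetic cohort
#'
#' Runs [evaluate_patient()] over each patient's scan series and tabulates
#' the final response categories.
#'
#' @param cohort A [generate_cohort()] result.
#' @param comparison_mode,background_suv Passed to [evaluate_patient()].
#' @return List with `evaluations` (per patient), `final_categories`
#'   (named character vector) and `distribution`
#'   (from [cohort_distribution()]).
#' @export
evaluate_cohort <- function(cohort, comparison_mode = "vs_baseline",
                            background_suv = NA_real_) {
  sets <- cohort_target_sets(cohort)
  evals <- lapply(sets, evaluate_patient,
                  comparison_mode = comparison_mode,
                  background_suv = background_suv)
  finals <- vapply(evals, `[[`, character(1L), "final_category")
  list(evaluations = evals, final_categories = finals,
       distribution = cohort_distribution(finals))
}
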