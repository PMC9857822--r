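#' Spherical volume of interest
#'
#' @param center_mm Sphere center in physical mm, length 3.
#' @param radius_mm Sphere radius in mm (> 0).
#' @param label Identifier string.
#' @param site Anatomical site, one of `"liver"`, `"lymph_node"`, `"bone"`,
#'   `"spleen"`, `"vertebra"`, `"other"`.
#' @return An object of class `sphere_voi`.
#' @export
sphere_voi <- function(center_mm, radius_mm, label = "voi",
                       site = c("other", "liver", "lymph_node", "bone",
                                "spleen", "vertebra")) {
  site <- match.arg(site)
  if (length(center_mm) != 3L || any(!is.finite(center_mm)))
    stop("`center_mm` must be a finite length-3 vector", call. = FALSE)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be positive", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 label = as.character(label), site = site),
            class = "sphere_voi")
}

voi_member_indices <- function(vol, voi) {
  m <- sphere_voxel_indices(vol, voi$center_mm, voi$radius_mm)
  if (nrow(m) == 0L)
    stop(sprintf("VOI '%s' contains no voxel centers", voi$label),
         call. = FALSE)
  m
}

#' Maximum SUV within a VOI
#'
#' The maximum voxel value among voxels whose centers lie inside the
#' sphere. SUVmax is the single most widely reported uptake statistic; it
#' is sensitive to voxel noise because it is an extreme value.
#'
#' @param vol A [suv_volume()] (any [voxel_volume()] is accepted).
#' @param voi A [sphere_voi()] containing at least one voxel center.
#' @return The maximum voxel value (g/mL for SUV volumes).
#' @export
suv_max <- function(vol, voi) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(voi, "sphere_voi"))
  m <- voi_member_indices(vol, voi)
  max(vol$values[m[, "idx"]])
}

# Integer voxel offsets whose centers fall within a sphere of the given
# volume (cm^3) centered on a voxel center. radius = (3 V / 4 pi)^(1/3).
kernel_offsets <- function(voxel_size_mm, kernel_volume_cm3 = 1.0) {
  r_mm <- (3 * kernel_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  r_vox <- r_mm / voxel_size_mm
  if (r_vox < 1)
    stop(sprintf(
      "kernel radius %.2f mm is below one voxel (%.2f mm); ",
      r_mm, voxel_size_mm),
      "grid too coarse for this kernel volume", call. = FALSE)
  s <- seq.int(-floor(r_vox), floor(r_vox))
  g <- as.matrix(expand.grid(di = s, dj = s, dk = s))
  g[g[, 1L]^2 + g[, 2L]^2 + g[, 3L]^2 <= r_vox^2 + 1e-9, , drop = FALSE]
}

#' Peak SUV within a VOI (1-cm3 spherical kernel)
#'
#' SUVpeak is the maximum, over spherical kernels of the stated volume
#' centered on each voxel center inside the VOI, of the mean SUV over the
#' voxel centers falling inside the kernel. The kernel may extend beyond
#' the VOI boundary (the VOI constrains only the kernel centers), but
#' placements whose kernel would leave the voxel grid are excluded.
#' Because it averages about a cubic centimetre, SUVpeak is less
#' noise-sensitive than SUVmax and never exceeds the maximum voxel value
#' over the kernels' combined support.
#'
#' @inheritParams suv_max
#' @param kernel_volume_cm3 Kernel volume in cubic centimetres (default 1,
#'   kernel radius about 6.2 mm).
#' @return The peak mean SUV.
#' @export
suv_peak <- function(vol, voi, kernel_volume_cm3 = 1.0) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(voi, "sphere_voi"))
  d <- dim(vol$values)
  off <- kernel_offsets(vol$voxel_size_mm, kernel_volume_cm3)
  span <- apply(abs(off), 2L, max)
  if (any(2L * span + 1L > d))
    stop("kernel is larger than the voxel grid", call. = FALSE)
  centers <- voi_member_indices(vol, voi)
  ok <- centers[, "i"] > span[1L] & centers[, "i"] <= d[1L] - span[1L] &
        centers[, "j"] > span[2L] & centers[, "j"] <= d[2L] - span[2L] &
        centers[, "k"] > span[3L] & centers[, "k"] <= d[3L] - span[3L]
  centers <- centers[ok, , drop = FALSE]
  if (nrow(centers) == 0L)
    stop(sprintf(
      "no kernel placement inside VOI '%s' fits within the grid",
      voi$label), call. = FALSE)
  # linear-index arithmetic: neighbor idx = center idx + offset dot strides
  strides <- c(1L, d[1L], d[1L] * d[2L])
  doff <- as.vector(off %*% strides)
  best <- -Inf
  v <- vol$values
  for (r in seq_len(nrow(centers))) {
    best <- max(best, mean(v[centers[r, "idx"] + doff]))
  }
  best
}

#' Reference-tissue SUVmax from a 10-mm sphere
#'
#' Normal-tissue uptake (liver, spleen or vertebra) is measured as the
#' SUVmax over a sphere of 10 mm radius placed inside imagistically normal
#' tissue. The sphere must lie fully inside the grid.
#'
#' @param vol A [suv_volume()].
#' @param center_mm Sphere center in physical mm.
#' @param site Reference site label (`"liver"`, `"spleen"`, `"vertebra"`,
#'   or `"other"`).
#' @param radius_mm Sphere radius in mm; 10 mm by convention.
#' @return The reference SUVmax.
#' @export
normal_tissue_suv <- function(vol, center_mm,
                              site = c("liver", "spleen", "vertebra",
                                       "other"),
                              radius_mm = 10) {
  site <- match.arg(site)
  if (!sphere_inside_grid(vol, center_mm, radius_mm))
    stop("reference sphere extends outside the voxel grid", call. = FALSE)
  suv_max(vol, sphere_voi(center_mm, radius_mm,
                          label = paste0("ref_", site), site = site))
}

#' Target-lesion to normal-tissue ratio
#'
#' Per-lesion ratio of lesion SUVmax to reference-tissue SUVmax. When no
#' reference tissue is available for a patient (e.g. spleen reference after
#' splenectomy), pass `NA` and the ratio is returned as `NA` rather than
#' computed against a degenerate reference.
#'
#' @param lesion_suv_max Lesion SUVmax (g/mL).
#' @param reference_suv_max Reference SUVmax (g/mL, > 0) or `NA` if the
#'   reference tissue is absent.
#' @return `lesion_suv_max / reference_suv_max`, or `NA_real_` when the
#'   reference is `NA`.
#' @export
tln_ratio <- function(lesion_suv_max, reference_suv_max) {
  if (is.na(reference_suv_max)) return(NA_real_)
  if (!is.finite(reference_suv_max) || reference_suv_max <= 0)
    stop("reference SUVmax must be positive (use NA for an absent reference)",
         call. = FALSE)
  lesion_suv_max / reference_suv_max
}

#' Measure a set of lesion VOIs on an SUV volume
#'
#' Convenience wrapper extracting SUVmax and SUVpeak for each lesion VOI
#' and, when a matching reference measurement is supplied, the TL/N ratio.
#'
#' @param vol A [suv_volume()].
#' @param vois List of [sphere_voi()] lesion definitions.
#' @param reference_suv Single reference SUVmax applied to all lesions, a
#'   named vector indexed by VOI label, or `NA` (default) for no ratio.
#' @param kernel_volume_cm3 Passed to [suv_peak()].
#' @return A data frame with one row per VOI: `lesion_id`, `site`,
#'   `suv_max`, `suv_peak`, `reference_suv`, `tln_ratio`.
#' @export
measure_lesions <- function(vol, vois, reference_suv = NA_real_,
                            kernel_volume_cm3 = 1.0) {
  stopifnot(inherits(vol, "suv_volume"))
  rows <- lapply(vois, function(voi) {
    smax <- suv_max(vol, voi)
    speak <- suv_peak(vol, voi, kernel_volume_cm3)
    ref <- if (length(reference_suv) > 1L) {
      unname(reference_suv[voi$label])
    } else reference_suv
    data.frame(lesion_id = voi$label, site = voi$site,
               suv_max = smax, suv_peak = speak,
               reference_suv = ref,
               tln_ratio = tln_ratio(smax, ref),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
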