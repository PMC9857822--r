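# Parameter-recovery studies: generate lesion populations calibrated to the
# site uptake table, lay them out in activity volumes, and push them through
# the full quantification pipeline (SUV conversion -> VOI statistics). These
# drive the package's validation: the pipeline must recover the generator's
# population parameters within sampling error.

# slot centers for packing many disjoint spheres into one 64^3 / 4 mm grid:
# 8 positions per axis, 30 mm apart, leaving room for an 11 mm lesion plus
# the 6.2 mm kernel overshoot at the grid faces
slot_centers <- function() {
  pos <- seq(20, by = 30, length.out = 8)
  as.matrix(expand.grid(x = pos, y = pos, z = pos))
}

#' Lesion SUVmax/SUVpeak recovery study
#'
#' Draws `n_lesions` (SUVmax, SUVpeak) pairs for one metastatic site from
#' the calibrated truncated-normal model ([reference_uptake_table()]),
#' builds two-compartment spherical lesions with those analytic values,
#' packs them into 64^3 activity volumes, converts to SUV with the paired
#' physiology/activity record and measures each lesion with [suv_max()]
#' and [suv_peak()].
#'
#' @param site `"liver"`, `"lymph_node"` or `"bone"`.
#' @param n_lesions Number of lesions to generate and measure.
#' @param seed Integer RNG seed.
#' @param noise_cv Multiplicative voxel noise CV (default 0.02).
#' @param lesion_radius_mm Lesion sphere radius; the default 11 mm keeps
#'   all interior 1-cm3 kernel placements inside the lesion.
#' @return Data frame with one row per lesion: `lesion_id`, `site`,
#'   `true_suv_max`, `true_suv_peak`, `suv_max`, `suv_peak` (the last two
#'   measured by the pipeline).
#' @export
simulate_uptake_recovery <- function(site, n_lesions, seed,
                                     noise_cv = 0.02,
                                     lesion_radius_mm = 11) {
  set.seed(seed)
  K <- nrow(kernel_offsets(4))
  pairs <- draw_lesion_pairs(n_lesions, site, K)
  slots <- slot_centers()
  per_vol <- nrow(slots)
  out <- vector("list", ceiling(n_lesions / per_vol))
  done <- 0L
  chunk <- 0L
  while (done < n_lesions) {
    chunk <- chunk + 1L
    take <- min(per_vol, n_lesions - done)
    idx <- done + seq_len(take)
    specs <- lapply(seq_len(take), function(i) {
      lesion_spec(slots[i, ], lesion_radius_mm,
                  true_suv = pairs$suv_max[idx[i]], site = site,
                  true_suv_peak = pairs$suv_peak[idx[i]])
    })
    cfg <- generator_config(noise_cv = noise_cv)
    gen <- generate_patient_volume(cfg, specs)
    suv <- to_suv_volume(gen$volume, gen$physiology, gen$activity_record)
    meas <- do.call(rbind, lapply(seq_len(take), function(i) {
      voi <- sphere_voi(slots[i, ], lesion_radius_mm,
                        label = sprintf("les_%04d", idx[i]),
                        site = if (site %in% c("liver", "lymph_node",
                                               "bone")) site else "other")
      data.frame(lesion_id = voi$label, site = site,
                 true_suv_max = pairs$suv_max[idx[i]],
                 true_suv_peak = pairs$suv_peak[idx[i]],
                 suv_max = suv_max(suv, voi),
                 suv_peak = suv_peak(suv, voi),
                 stringsAsFactors = FALSE)
    }))
    out[[chunk]] <- meas
    done <- done + take
  }
  do.call(rbind, out)
}

#' Target-to-normal ratio recovery study
#'
#' Draws per-lesion TL/N ratios and reference-tissue uptake values for one
#' site from their calibrated truncated normals, sets each lesion's SUV to
#' ratio times its reference, builds lesion/reference sphere pairs in
#' activity volumes, and measures lesion [suv_max()], reference uptake via
#' [normal_tissue_suv()] (10-mm sphere) and their [tln_ratio()].
#'
#' @param site Metastatic site whose TL/N calibration is used (`"liver"`,
#'   `"lymph_node"`, `"bone"`).
#' @param n_pairs Number of lesion/reference pairs.
#' @param seed Integer RNG seed.
#' @param noise_cv Multiplicative voxel noise CV (default 0.02).
#' @return Data frame with `true_ratio`, `true_reference`,
#'   `lesion_suv_max`, `reference_suv`, `tln_ratio` per pair.
#' @export
simulate_tln_recovery <- function(site, n_pairs, seed, noise_cv = 0.02) {
  set.seed(seed)
  p <- site_params(site)
  ratio <- rtruncnorm_lower(n_pairs,
                            truncnorm_location(p$tln_mean, p$tln_sd),
                            p$tln_sd)
  ref <- rtruncnorm_lower(n_pairs,
                          truncnorm_location(p$ref_mean, p$ref_sd),
                          p$ref_sd)
  lesion_suv <- ratio * ref
  ref_site <- p$ref_site

  slots <- slot_centers()
  pairs_per_vol <- nrow(slots) %/% 2L
  out <- vector("list", ceiling(n_pairs / pairs_per_vol))
  done <- 0L
  chunk <- 0L
  while (done < n_pairs) {
    chunk <- chunk + 1L
    take <- min(pairs_per_vol, n_pairs - done)
    idx <- done + seq_len(take)
    les_specs <- lapply(seq_len(take), function(i)
      lesion_spec(slots[2L * i - 1L, ], 8, true_suv = lesion_suv[idx[i]],
                  site = if (site == "lymph_node") "lymph_node" else site))
    ref_specs <- lapply(seq_len(take), function(i)
      lesion_spec(slots[2L * i, ], 12, true_suv = ref[idx[i]],
                  site = "other"))
    cfg <- generator_config(noise_cv = noise_cv)
    gen <- generate_patient_volume(cfg, les_specs, ref_specs)
    suv <- to_suv_volume(gen$volume, gen$physiology, gen$activity_record)
    meas <- do.call(rbind, lapply(seq_len(take), function(i) {
      lmax <- suv_max(suv, sphere_voi(slots[2L * i - 1L, ], 8,
                                      label = sprintf("les_%04d", idx[i])))
      rsuv <- normal_tissue_suv(suv, slots[2L * i, ],
                                site = if (ref_site %in%
                                           c("liver", "spleen",
                                             "vertebra")) ref_site
                                       else "other")
      data.frame(true_ratio = ratio[idx[i]],
                 true_reference = ref[idx[i]],
                 lesion_suv_max = lmax, reference_suv = rsuv,
                 tln_ratio = tln_ratio(lmax, rsuv),
                 stringsAsFactors = FALSE)
    }))
    out[[chunk]] <- meas
    done <- done + take
  }
  do.call(rbind, out)
}
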