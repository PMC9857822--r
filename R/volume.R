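#' Voxel volume container
#'
#' A minimal 3-D voxel grid with isotropic voxel size and a physical origin,
#' used for both activity-concentration volumes (Bq/mL) and SUV volumes
#' (g/mL). Voxel centers lie at `origin_mm + (index - 0.5) * voxel_size_mm`
#' along each axis, so the grid occupies the box from `origin_mm` to
#' `origin_mm + dim * voxel_size_mm`.
#'
#' @param values 3-D numeric array of voxel values.
#' @param voxel_size_mm Isotropic voxel edge length in millimetres (> 0).
#' @param origin_mm Physical coordinate (mm) of the grid corner, length 3.
#' @param units Unit string carried as metadata, e.g. `"Bq/mL"` or `"g/mL"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, voxel_size_mm, origin_mm = c(0, 0, 0),
                         units = "Bq/mL") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a single positive number", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be a finite length-3 vector", call. = FALSE)
  structure(
    list(values = values, voxel_size_mm = as.numeric(voxel_size_mm),
         origin_mm = as.numeric(origin_mm), units = units),
    class = "voxel_volume"
  )
}

#' SUV volume container
#'
#' A [voxel_volume()] whose values are standardized uptake values normalized
#' to lean body mass (g/mL). Values must be non-negative.
#'
#' @inheritParams voxel_volume
#' @return An object of class `c("suv_volume", "voxel_volume")`.
#' @export
suv_volume <- function(values, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  if (any(values < 0, na.rm = TRUE))
    stop("SUV values must be non-negative", call. = FALSE)
  vol <- voxel_volume(values, voxel_size_mm, origin_mm, units = "g/mL")
  class(vol) <- c("suv_volume", class(vol))
  vol
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, %.3g mm isotropic, units %s\n",
              class(x)[1L], d[1L], d[2L], d[3L], x$voxel_size_mm, x$units))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

# Physical coordinates (mm) of voxel centers along one axis.
voxel_axis_centers <- function(n, voxel_size_mm, origin) {
  origin + (seq_len(n) - 0.5) * voxel_size_mm
}

#' Voxel indices whose centers fall inside a sphere
#'
#' Membership is by voxel-center inclusion: a voxel belongs to the sphere
#' iff the Euclidean distance from its center to `center_mm` is at most
#' `radius_mm`. No partial-volume weighting is applied.
#'
#' @param vol A [voxel_volume()].
#' @param center_mm Sphere center, physical mm, length 3.
#' @param radius_mm Sphere radius in mm (> 0).
#' @return Integer matrix with columns `i, j, k, idx` (`idx` is the linear
#'   array index); zero rows if no voxel center lies inside.
#' @export
sphere_voxel_indices <- function(vol, center_mm, radius_mm) {
  stopifnot(inherits(vol, "voxel_volume"), length(center_mm) == 3L,
            radius_mm > 0)
  d <- dim(vol$values)
  vs <- vol$voxel_size_mm
  o <- vol$origin_mm
  rng <- lapply(1:3, function(ax) {
    lo <- ceiling((center_mm[ax] - radius_mm - o[ax]) / vs + 0.5)
    hi <- floor((center_mm[ax] + radius_mm - o[ax]) / vs + 0.5)
    seq.int(max(1L, lo), min(d[ax], hi))
  })
  if (any(lengths(rng) == 0L))
    return(matrix(integer(0), ncol = 4L,
                  dimnames = list(NULL, c("i", "j", "k", "idx"))))
  g <- as.matrix(expand.grid(i = rng[[1L]], j = rng[[2L]], k = rng[[3L]]))
  cx <- o[1L] + (g[, 1L] - 0.5) * vs
  cy <- o[2L] + (g[, 2L] - 0.5) * vs
  cz <- o[3L] + (g[, 3L] - 0.5) * vs
  keep <- (cx - center_mm[1L])^2 + (cy - center_mm[2L])^2 +
    (cz - center_mm[3L])^2 <= radius_mm^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  idx <- g[, 1L] + (g[, 2L] - 1L) * d[1L] + (g[, 3L] - 1L) * d[1L] * d[2L]
  cbind(g, idx = idx)
}

# TRUE if the sphere lies entirely inside the physical extent of the grid.
sphere_inside_grid <- function(vol, center_mm, radius_mm) {
  d <- dim(vol$values)
  lo <- vol$origin_mm
  hi <- vol$origin_mm + d * vol$voxel_size_mm
  all(center_mm - radius_mm >= lo) && all(center_mm + radius_mm <= hi)
}

#' Write a voxel volume to a NIfTI file
#'
#' Geometry metadata (voxel size and origin) is stored in the NIfTI header
#' so the volume round-trips through [read_volume_nifti()].
#'
#' @param vol A [voxel_volume()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  img <- RNifti::asNifti(vol$values)
  vs <- vol$voxel_size_mm
  # NIfTI sform: scale by voxel size, translate so voxel (1,1,1) center
  # sits at origin + vs/2
  m <- diag(c(vs, vs, vs, 1))
  m[1:3, 4] <- vol$origin_mm + vs / 2
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::pixdim(img) <- c(vs, vs, vs)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel volume from a NIfTI file
#'
#' @param path NIfTI file written by [write_volume_nifti()] or any isotropic
#'   3-D NIfTI volume.
#' @param units Unit string to attach (`"Bq/mL"` by default).
#' @return A [voxel_volume()].
#' @export
read_volume_nifti <- function(path, units = "Bq/mL") {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-6 * pd[1L])
    stop("only isotropic voxel grids are supported", call. = FALSE)
  m <- RNifti::xform(img)
  origin <- m[1:3, 4] - pd[1L] / 2
  voxel_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               voxel_size_mm = pd[1L], origin_mm = origin, units = units)
}
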