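# Independent brute-force oracles for VOI statistics. These recompute voxel
# membership and kernel means by exhaustive looping over every voxel, sharing
# no code with the package implementations.

oracle_suv_max <- function(vol, center_mm, radius_mm) {
  d <- dim(vol$values)
  vs <- vol$voxel_size_mm
  o <- vol$origin_mm
  best <- -Inf
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    cx <- o[1] + (i - 0.5) * vs
    cy <- o[2] + (j - 0.5) * vs
    cz <- o[3] + (k - 0.5) * vs
    if ((cx - center_mm[1])^2 + (cy - center_mm[2])^2 +
        (cz - center_mm[3])^2 <= radius_mm^2 + 1e-9)
      best <- max(best, vol$values[i, j, k])
  }
  best
}

# exhaustive SUVpeak: kernel centers at voxel centers inside the VOI whose
# full kernel bounding span stays inside the grid; kernel membership by
# voxel-center distance to the kernel center
oracle_suv_peak <- function(vol, center_mm, radius_mm,
                            kernel_volume_cm3 = 1.0) {
  d <- dim(vol$values)
  vs <- vol$voxel_size_mm
  o <- vol$origin_mm
  r_k <- (3 * kernel_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  span <- floor(r_k / vs)
  best <- -Inf
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    cx <- o[1] + (i - 0.5) * vs
    cy <- o[2] + (j - 0.5) * vs
    cz <- o[3] + (k - 0.5) * vs
    in_voi <- (cx - center_mm[1])^2 + (cy - center_mm[2])^2 +
      (cz - center_mm[3])^2 <= radius_mm^2 + 1e-9
    if (!in_voi) next
    if (i <= span || i > d[1] - span || j <= span || j > d[2] - span ||
        k <= span || k > d[3] - span) next
    tot <- 0; cnt <- 0
    for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
      dx <- (a - i) * vs; dy <- (b - j) * vs; dz <- (cc - k) * vs
      if (dx^2 + dy^2 + dz^2 <= r_k^2 + 1e-9) {
        tot <- tot + vol$values[a, b, cc]
        cnt <- cnt + 1
      }
    }
    best <- max(best, tot / cnt)
  }
  best
}

# closed-form paired t-test on n pairs
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

random_suv_field <- function(dims, voxel_size_mm = 2, seed = 1) {
  set.seed(seed)
  suv_volume(array(runif(prod(dims), 0, 10), dim = dims), voxel_size_mm)
}
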