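#' Specification for a synthetic 3D fluorescence stack
#'
#' @param dims stack shape `(z, y, x)` in voxels.
#' @param voxel_nm voxel edge lengths `(z, y, x)` in nm; defaults 300 nm
#'   axially and 200 nm laterally, typical of a widefield z-stack with a
#'   63x/1.4NA lens and 2x2-binned camera.
#' @param foci data.frame with columns `z, y, x` (voxel coordinates,
#'   1-based, may be fractional), `intensity` (integrated, relative units),
#'   `sigma_nm` (isotropic Gaussian width; 250 nm approximates a
#'   diffraction-limited focus).
#' @param background cytoplasmic background level per voxel.
#' @param noise_sd additive Gaussian voxel noise.
#' @param seed integer seed.
#' @return a `focus_sim_spec` list.
#' @export
focus_sim_spec <- function(dims, voxel_nm = c(300, 200, 200),
                           foci = data.frame(z = numeric(), y = numeric(),
                                             x = numeric(),
                                             intensity = numeric(),
                                             sigma_nm = numeric()),
                           background = 0, noise_sd = 0, seed = 1L) {
  assert_cols(foci, c("z", "y", "x", "intensity", "sigma_nm"), "foci")
  if (nrow(foci)) {
    if (any(foci$intensity <= 0)) stopf("focus intensities must be positive")
    if (any(foci$z < 1 | foci$z > dims[1] | foci$y < 1 | foci$y > dims[2] |
            foci$x < 1 | foci$x > dims[3]))
      stopf("focus centres must lie inside the stack")
  }
  structure(list(dims = as.integer(dims), voxel_nm = voxel_nm, foci = foci,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "focus_sim_spec")
}

#' Simulate a 3D fluorescence stack with planted foci
#'
#' Each focus is an isotropic (in physical units) Gaussian whose discrete
#' in-stack voxel sum equals its specified integrated intensity exactly at
#' zero noise, on top of a flat background. Pairs of foci whose centres lie
#' closer than 3 of the larger sigma are flagged in the truth table
#' (`overlap_warning`), since their dilated regions will contaminate each
#' other.
#'
#' @param spec a [focus_sim_spec()].
#' @return list `stack` (array `(z, y, x)` with `voxel_nm` attribute) and
#'   `truth` (the foci table plus `overlap_warning`).
#' @export
simulate_focus_stack <- function(spec) {
  stopifnot(inherits(spec, "focus_sim_spec"))
  d <- spec$dims
  stack <- array(spec$background, dim = d)
  zc <- (seq_len(d[1])) * spec$voxel_nm[1]
  yc <- (seq_len(d[2])) * spec$voxel_nm[2]
  xc <- (seq_len(d[3])) * spec$voxel_nm[3]
  for (k in seq_len(nrow(spec$foci))) {
    f <- spec$foci[k, ]
    gz <- exp(-(zc - f$z * spec$voxel_nm[1])^2 / (2 * f$sigma_nm^2))
    gy <- exp(-(yc - f$y * spec$voxel_nm[2])^2 / (2 * f$sigma_nm^2))
    gx <- exp(-(xc - f$x * spec$voxel_nm[3])^2 / (2 * f$sigma_nm^2))
    g <- outer(gz, outer(gy, gx))            # (z, y, x)
    stack <- stack + f$intensity * g / sum(g)
  }
  if (spec$noise_sd > 0)
    stack <- pmax(stack + with_seed(spec$seed,
      array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)), 0)
  truth <- spec$foci
  truth$overlap_warning <- logical(nrow(truth))
  if (nrow(truth) > 1L) {
    for (i in seq_len(nrow(truth) - 1L)) for (j in (i + 1L):nrow(truth)) {
      dist_nm <- sqrt(sum((c(truth$z[i] - truth$z[j],
                             truth$y[i] - truth$y[j],
                             truth$x[i] - truth$x[j]) * spec$voxel_nm)^2))
      if (dist_nm < 3 * max(truth$sigma_nm[i], truth$sigma_nm[j])) {
        truth$overlap_warning[c(i, j)] <- TRUE
        warnf("foci %d and %d closer than 3 sigma (%.0f nm)", i, j, dist_nm)
      }
    }
  }
  attr(stack, "voxel_nm") <- spec$voxel_nm
  list(stack = stack, truth = truth)
}
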