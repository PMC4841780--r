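## 3D morphology on voxel arrays (z, y, x): 26-connected components via
## union-find on supra-threshold voxel coordinates, and anisotropic
## ellipsoid dilation with per-axis radii derived from physical distances.

uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

components_3d <- function(coords, dims) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  key <- coords[, 1] + (coords[, 2] - 1) * dims[1] +
    (coords[, 3] - 1) * dims[1] * dims[2]
  lookup <- structure(seq_len(n), names = key)
  parent <- seq_len(n)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (o in seq_len(nrow(offs))) {
    nk <- (coords[, 1] + offs[o, 1]) +
      (coords[, 2] + offs[o, 2] - 1) * dims[1] +
      (coords[, 3] + offs[o, 3] - 1) * dims[1] * dims[2]
    j <- lookup[as.character(nk)]
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- uf_find(parent, i); rj <- uf_find(parent, j[i])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, sort(unique(roots)))
}

#' Detect fluorescence foci in a 3D stack
#'
#' Supra-threshold voxels are grouped into 26-connected components; those
#' with at least `min_voxels` voxels are returned as core regions, ordered
#' by centroid (z, then y, then x) for determinism.
#'
#' @param stack numeric array `(z, y, x)`.
#' @param threshold threshold value (absolute mode) or quantile in (0, 1)
#'   (percentile mode).
#' @param mode `"absolute"` or `"percentile"`.
#' @param min_voxels minimum component size (default 3).
#' @return list of core regions, each an integer matrix of voxel
#'   coordinates (columns z, y, x) with a `centroid` attribute. A
#'   threshold above the stack maximum yields an empty list.
#' @export
detect_foci <- function(stack, threshold, mode = c("absolute", "percentile"),
                        min_voxels = 3L) {
  mode <- match.arg(mode)
  thr <- if (mode == "percentile")
    stats::quantile(stack, threshold, names = FALSE) else threshold
  idx <- which(stack > thr)
  if (!length(idx)) return(list())
  d <- dim(stack)
  coords <- cbind(z = (idx - 1) %% d[1] + 1,
                  y = ((idx - 1) %/% d[1]) %% d[2] + 1,
                  x = (idx - 1) %/% (d[1] * d[2]) + 1)
  lab <- components_3d(coords, d)
  cores <- lapply(seq_len(max(lab)), function(l) {
    m <- coords[lab == l, , drop = FALSE]
    attr(m, "centroid") <- colMeans(m)
    m
  })
  cores <- cores[vapply(cores, nrow, integer(1)) >= min_voxels]
  cen <- t(vapply(cores, function(m) attr(m, "centroid"), numeric(3)))
  if (length(cores) > 1L)
    cores <- cores[order(cen[, 1], cen[, 2], cen[, 3])]
  cores
}

## box (per-axis) dilation: "by a fixed amount in each direction", with the
## distance converted to voxels independently per axis.
dilate_region <- function(coords, radii_vox, dims) {
  r <- pmax(1L, radii_vox)
  g <- as.matrix(expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2],
                             dx = -r[3]:r[3]))
  n <- nrow(coords); m <- nrow(g)
  zz <- rep(coords[, 1], each = m) + rep(g[, 1], n)
  yy <- rep(coords[, 2], each = m) + rep(g[, 2], n)
  xx <- rep(coords[, 3], each = m) + rep(g[, 3], n)
  clipped <- zz < 1 | zz > dims[1] | yy < 1 | yy > dims[2] |
    xx < 1 | xx > dims[3]
  lin <- unique(zz[!clipped] + (yy[!clipped] - 1) * dims[1] +
                  (xx[!clipped] - 1) * dims[1] * dims[2])
  list(lin = lin, clipped = any(clipped))
}

#' Quantify a focus with dilated-ring background subtraction
#'
#' The core region is dilated by `d1` (default 600 nm) in every direction
#' to capture the focus's full signal, and further by `d2` (default
#' 2.4 um) to delimit an outer ring whose mean (or median) intensity is
#' the per-voxel background estimate. Physical distances become per-axis
#' voxel radii by ceiling division, so dilation is anisotropic in voxel
#' space. Net signal = sum over the d1 region - background x region
#' volume; it may be negative (reported, not clipped).
#'
#' @param stack numeric array `(z, y, x)`.
#' @param core voxel-coordinate matrix from [detect_foci()].
#' @param d1 inner dilation margin, nm.
#' @param d2 background-ring dilation, nm; an increment beyond `d1` when
#'   `d2_mode = "increment"` (default), or the total outer radius when
#'   `"total"`.
#' @param voxel_nm voxel sizes `(z, y, x)` in nm (default: stack
#'   attribute).
#' @param background `"mean"` (default) or `"median"` ring statistic.
#' @param d2_mode reading of `d2`, see above.
#' @param exclude optional logical array of voxels to drop from the ring
#'   (e.g. a neighbouring focus's signal region).
#' @return data.frame: `core_voxels, region_voxels, ring_voxels,
#'   integrated, background, net, edge_flag`. Quantification is refused
#'   (all-NA row, with a warning) when the ring is empty.
#' @export
quantify_focus <- function(stack, core, d1 = 600, d2 = 2400,
                           voxel_nm = attr(stack, "voxel_nm"),
                           background = c("mean", "median"),
                           d2_mode = c("increment", "total"),
                           exclude = NULL) {
  background <- match.arg(background); d2_mode <- match.arg(d2_mode)
  if (is.null(voxel_nm)) stopf("voxel_nm is required")
  d <- dim(stack)
  r1 <- as.integer(ceiling(d1 / voxel_nm))
  outer_nm <- if (d2_mode == "increment") d1 + d2 else d2
  if (outer_nm <= d1) stopf("outer radius must exceed d1")
  r2 <- as.integer(ceiling(outer_nm / voxel_nm))
  reg1 <- dilate_region(core, r1, d)
  reg2 <- dilate_region(core, r2, d)
  ring <- setdiff(reg2$lin, reg1$lin)
  if (!is.null(exclude)) ring <- ring[!exclude[ring]]
  if (!length(ring)) {
    warnf("empty background ring; quantification refused")
    return(data.frame(core_voxels = nrow(core), region_voxels = NA,
                      ring_voxels = 0L, integrated = NA, background = NA,
                      net = NA, edge_flag = TRUE))
  }
  bgf <- if (background == "mean") mean else stats::median
  bg <- bgf(stack[ring])
  integrated <- sum(stack[reg1$lin])
  data.frame(core_voxels = nrow(core), region_voxels = length(reg1$lin),
             ring_voxels = length(ring), integrated = integrated,
             background = bg, net = integrated - bg * length(reg1$lin),
             edge_flag = reg1$clipped || reg2$clipped)
}

#' Quantify all detected foci in a stack
#'
#' Runs [quantify_focus()] per core; voxels claimed by the signal (d1)
#' regions of two or more foci are assigned to the nearest core centroid
#' (in nm) and the affected foci are flagged `overlap_flag`.
#'
#' @inheritParams quantify_focus
#' @param cores list of core regions from [detect_foci()].
#' @return data.frame, one row per focus (`focus` id column first).
#' @export
quantify_foci <- function(stack, cores, d1 = 600, d2 = 2400,
                          voxel_nm = attr(stack, "voxel_nm"), ...) {
  d <- dim(stack)
  r1 <- as.integer(ceiling(d1 / voxel_nm))
  regions <- lapply(cores, function(cc) dilate_region(cc, r1, d)$lin)
  claimed <- table(unlist(regions))
  ov <- as.integer(names(claimed)[claimed > 1L])
  owner <- rep(NA_integer_, length(ov))
  if (length(ov)) {
    vz <- ((ov - 1) %% d[1] + 1) * voxel_nm[1]
    vy <- (((ov - 1) %/% d[1]) %% d[2] + 1) * voxel_nm[2]
    vx <- ((ov - 1) %/% (d[1] * d[2]) + 1) * voxel_nm[3]
    cen <- t(vapply(cores, function(m) attr(m, "centroid") %||% colMeans(m),
                    numeric(3)))
    dist2 <- sapply(seq_along(cores), function(i)
      (vz - cen[i, 1] * voxel_nm[1])^2 + (vy - cen[i, 2] * voxel_nm[2])^2 +
        (vx - cen[i, 3] * voxel_nm[3])^2)
    owner <- max.col(-matrix(dist2, nrow = length(ov)))
  }
  out <- lapply(seq_along(cores), function(i) {
    lost <- ov[owner != i]
    excl <- NULL
    mine <- regions[[i]]
    other <- setdiff(unlist(regions[-i]), mine)
    excl <- array(FALSE, dim = d)
    excl[other] <- TRUE                  # other foci's signal out of my ring
    excl[lost] <- TRUE
    q <- quantify_focus(stack, cores[[i]], d1 = d1, d2 = d2,
                        voxel_nm = voxel_nm, exclude = excl, ...)
    q$integrated <- q$integrated - sum(stack[intersect(mine, lost)])
    q$net <- q$integrated - q$background * (q$region_voxels - length(
      intersect(mine, lost)))
    q$overlap_flag <- length(ov) > 0 && any(ov %in% mine)
    cbind(focus = i, q)
  })
  do.call(rbind, out)
}

#' Whole-cell fluorescence from a maximum projection
#'
#' Projects the stack along z by maximum, then
#' `total = sum(projection[mask]) - background x mask area`. The
#' background is the mean of projection pixels outside every supplied
#' mask (default) or the whole-image mean.
#'
#' @param stack numeric array `(z, y, x)` (a 2D matrix is used as its own
#'   projection).
#' @param mask logical matrix selecting the cell.
#' @param all_masks optional logical matrix marking every cell in the
#'   field, excluded from the background estimate.
#' @param background `"outside_mask"` (default) or `"image_mean"`.
#' @return total background-subtracted fluorescence (relative units).
#' @export
cell_total <- function(stack, mask, all_masks = mask,
                       background = c("outside_mask", "image_mean")) {
  background <- match.arg(background)
  proj <- if (length(dim(stack)) == 3L) apply(stack, c(2, 3), max) else stack
  if (!all(dim(proj) == dim(mask))) stopf("mask does not match image size")
  bg <- if (background == "image_mean") mean(proj) else {
    outside <- !(mask | all_masks)
    if (!any(outside)) 0 else mean(proj[outside])
  }
  sum(proj[mask]) - bg * sum(mask)
}
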