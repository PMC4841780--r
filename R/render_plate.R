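#' Render a colony table as a synthetic plate scan
#'
#' Colonies are drawn as filled disks of radius proportional to the square
#' root of colony area (so rendered pixel area tracks tabulated size), on a
#' uniform background with optional Gaussian pixel noise. Emulates a flatbed
#' transmission scan when `polarity = "colonies_dark"`.
#'
#' @param table a `colony_table` for a single plate.
#' @param pitch grid pitch in pixels.
#' @param origin pixel offset `(y, x)` of the grid's top-left cell corner.
#' @param radius_scale disk radius = `radius_scale * sqrt(size)`; the
#'   default 1/sqrt(pi) makes disk area equal tabulated size.
#' @param fg,bg foreground/background gray levels.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param polarity `"colonies_bright"` (reflective) or `"colonies_dark"`
#'   (transmission scan).
#' @param rotation_deg rotate the colony lattice about the image centre.
#' @param seed seed for the pixel noise.
#' @return numeric image matrix (row 1 = top) with attributes `dpi`,
#'   `polarity` and `geometry` (the true origin/pitch/rotation).
#' @export
render_plate_image <- function(table, pitch = 20, origin = c(0, 0),
                               radius_scale = 1 / sqrt(pi),
                               fg = 200, bg = 40, noise_sd = 0,
                               polarity = c("colonies_bright",
                                            "colonies_dark"),
                               rotation_deg = 0, seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(table, "data.frame"))
  n_rows <- max(table$row) + 1L
  n_cols <- max(table$col) + 1L
  h <- ceiling(origin[1] + n_rows * pitch)
  w <- ceiling(origin[2] + n_cols * pitch)
  r <- radius_scale * sqrt(ifelse(is.na(table$size), 0, table$size))
  if (any(r > pitch / 2))
    stopf("colony radius exceeds half the grid pitch (max r = %.1f px)",
          max(r))
  cy0 <- origin[1] + (table$row + 0.5) * pitch
  cx0 <- origin[2] + (table$col + 0.5) * pitch
  th <- rotation_deg * pi / 180
  mid <- c(h, w) / 2
  cy <- mid[1] + cos(th) * (cy0 - mid[1]) - sin(th) * (cx0 - mid[2])
  cx <- mid[2] + sin(th) * (cy0 - mid[1]) + cos(th) * (cx0 - mid[2])
  img <- matrix(bg, h, w)
  ## area-faithful rasterization: paint the round(pi r^2) pixel centres
  ## nearest the colony centre, so rendered pixel area equals the disk area
  ## up to rounding at every radius (binary centre-in-circle painting can
  ## deviate several percent at small radii)
  for (k in which(r > 0)) {
    n_px <- round(pi * r[k]^2)
    if (n_px < 1) next
    m <- ceiling(r[k]) + 2L
    ys <- max(1L, floor(cy[k]) - m):min(h, ceiling(cy[k]) + m)
    xs <- max(1L, floor(cx[k]) - m):min(w, ceiling(cx[k]) + m)
    d2 <- outer(((ys - 0.5) - cy[k])^2, ((xs - 0.5) - cx[k])^2, `+`)
    sel <- order(d2)[seq_len(min(n_px, length(d2)))]
    img[ys, xs][sel] <- fg
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(h * w, 0, noise_sd),
                                        h, w))
  if (polarity == "colonies_dark") img <- max(img) - img + min(img)
  structure(img, dpi = 300, polarity = polarity,
            geometry = list(origin = origin, pitch = pitch,
                            rotation_deg = rotation_deg,
                            n_rows = n_rows, n_cols = n_cols))
}
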