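## Colony measurement from plate scans: global/ per-cell Otsu thresholding,
## connected-component labelling by iterative label propagation (vectorised
## over the whole image; converges in ~blob-diameter sweeps), lattice
## fitting with a coarse rotation search, and per-cell measurement.

#' Otsu's threshold
#'
#' @param x numeric vector of intensities.
#' @param n_breaks histogram resolution.
#' @return threshold value maximizing between-class variance; pixels strictly
#'   above it are foreground.
#' @export
otsu_threshold <- function(x, n_breaks = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_breaks + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                           n_breaks))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[!is.finite(bcv)] <- -Inf
  br[which.max(bcv) + 1L]
}

shift_mat <- function(m, dr, dc, fill = Inf) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Label connected components of a binary mask
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift_mat(lab, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  ids <- sort(unique(lab[is.finite(lab)]))
  out[mask] <- match(lab[mask], ids)
  out
}

normalize_polarity <- function(image, polarity = NULL) {
  polarity <- polarity %||% attr(image, "polarity") %||% "colonies_bright"
  if (polarity == "colonies_dark") max(image) - image else image
}

#' Fit the colony lattice of a plate image
#'
#' Thresholds the image (global Otsu), extracts colony centroids, finds the
#' plate rotation by a coarse angle search minimizing the row-lattice
#' residual, then fits the full 2D lattice
#' `centre(i, j) = a + i * v + j * u` by least squares.
#'
#' @param image numeric matrix (or [render_plate_image()] output).
#' @param n_rows,n_cols expected grid dimensions.
#' @param polarity overrides the image's polarity attribute.
#' @return geometry list: `a` (origin vector, y/x of cell (0,0) centre),
#'   `v`/`u` (row/column step vectors), `pitch` (c(row, col)),
#'   `rotation_deg`, `residual` (rms centroid residual, px), `n_rows`,
#'   `n_cols`.
#' @export
fit_grid <- function(image, n_rows = 32L, n_cols = 48L, polarity = NULL) {
  img <- normalize_polarity(image, polarity)
  thr <- otsu_threshold(img)
  mask <- img > thr
  lab <- label_components(mask)
  n <- max(lab)
  if (n < 9L) stopf("fewer than 3 detectable rows or columns of colonies")
  px_r <- row(lab)[lab > 0]; px_c <- col(lab)[lab > 0]; px_l <- lab[lab > 0]
  sizes <- tabulate(px_l, n)
  keep <- which(sizes >= 5L)
  cy <- as.vector(tapply(px_r, px_l, mean))[keep]
  cx <- as.vector(tapply(px_c, px_l, mean))[keep]
  if (length(keep) < 0.5 * n_rows * n_cols)
    warnf("only %d colonies detected for a %dx%d grid", length(keep),
          n_rows, n_cols)
  lattice_rms <- function(y, n_lines) {
    p <- (max(y) - min(y)) / (n_lines - 1L)
    if (p <= 0) return(Inf)
    i <- pmin(pmax(round((y - min(y)) / p), 0L), n_lines - 1L)
    fit <- stats::lm.fit(cbind(1, i), y)
    sqrt(mean(fit$residuals^2))
  }
  angles <- seq(-3, 3, by = 0.25)
  rms <- vapply(angles, function(a) {
    th <- a * pi / 180
    yr <- cos(th) * cy + sin(th) * cx     # de-rotate
    lattice_rms(yr, n_rows)
  }, numeric(1))
  th0 <- angles[which.min(rms)] * pi / 180
  ## assignment in the de-rotated frame, then exact 2D least squares
  for (it in 1:3) {
    yr <- cos(th0) * cy + sin(th0) * cx
    xr <- -sin(th0) * cy + cos(th0) * cx
    pi_r <- (max(yr) - min(yr)) / (n_rows - 1L)
    pi_c <- (max(xr) - min(xr)) / (n_cols - 1L)
    i <- pmin(pmax(round((yr - min(yr)) / pi_r), 0L), n_rows - 1L)
    j <- pmin(pmax(round((xr - min(xr)) / pi_c), 0L), n_cols - 1L)
    X <- cbind(1, i, j)
    fy <- stats::lm.fit(X, cy)$coefficients
    fx <- stats::lm.fit(X, cx)$coefficients
    th0 <- atan2(fx[["i"]], fy[["i"]])    # row-step direction gives rotation
  }
  a <- c(fy[1], fx[1]); v <- c(fy["i"], fx["i"]); u <- c(fy["j"], fx["j"])
  res <- sqrt(mean((cy - drop(X %*% fy))^2 + (cx - drop(X %*% fx))^2))
  pitch <- c(sqrt(sum(v^2)), sqrt(sum(u^2)))
  if (res > 0.25 * min(pitch))
    warnf("lattice residual %.1f px exceeds a quarter pitch", res)
  list(a = unname(a), v = unname(v), u = unname(u), pitch = unname(pitch),
       rotation_deg = unname(atan2(-u[1], u[2]) * 180 / pi),
       residual = res, n_rows = as.integer(n_rows),
       n_cols = as.integer(n_cols))
}

#' Measure colony sizes on a fitted grid
#'
#' For each grid cell: the cell window is thresholded by Otsu's criterion on
#' its own histogram (after polarity normalization), the connected
#' foreground component nearest the cell centre is taken as the colony, and
#' its pixel count is the colony size. Cells with fewer than 5 foreground
#' pixels, or whose foreground/background contrast is below 4 background
#' standard deviations (a pure-noise Otsu split), are flagged empty.
#' Components touching the cell boundary on more than a quarter of their
#' perimeter are flagged `edge_touching`. Measurement depends only on
#' intensity order within each cell, so it is invariant to global affine
#' intensity rescaling.
#'
#' @param image plate image matrix.
#' @param geometry lattice from [fit_grid()].
#' @param layout [plate_layout()] for this plate (dimensions must match).
#' @param polarity overrides the image's polarity attribute.
#' @return `colony_table` with `size`, `circularity`, `flag_empty`,
#'   `flag_edge` per layout position.
#' @export
measure_colonies <- function(image, geometry, layout, polarity = NULL) {
  dims <- layout_dims(layout)
  if (dims["rows"] != geometry$n_rows || dims["cols"] != geometry$n_cols)
    stopf("geometry (%dx%d) does not match layout (%dx%d)",
          geometry$n_rows, geometry$n_cols, dims["rows"], dims["cols"])
  img <- normalize_polarity(image, polarity)
  half <- floor(min(geometry$pitch) / 2)
  out <- as.data.frame(layout)
  out$size <- NA_real_; out$circularity <- NA_real_
  out$flag_empty <- TRUE; out$flag_edge <- FALSE
  for (k in seq_len(nrow(out))) {
    ctr <- geometry$a + out$row[k] * geometry$v + out$col[k] * geometry$u
    ys <- max(1L, round(ctr[1]) - half):min(nrow(img), round(ctr[1]) + half)
    xs <- max(1L, round(ctr[2]) - half):min(ncol(img), round(ctr[2]) + half)
    cell <- img[ys, xs]
    thr <- otsu_threshold(cell)
    fgm <- cell > thr
    if (sum(fgm) < 5L) next
    sd_bg <- stats::sd(cell[!fgm])
    if (is.finite(sd_bg) && sd_bg > 0 &&
        (mean(cell[fgm]) - mean(cell[!fgm])) < 4 * sd_bg) next
    lab <- label_components(fgm)
    cyx <- c(ctr[1] - ys[1] + 1, ctr[2] - xs[1] + 1)
    d2 <- tapply(seq_along(lab)[lab > 0], lab[lab > 0], function(ii) {
      min((row(lab)[ii] - cyx[1])^2 + (col(lab)[ii] - cyx[2])^2)
    })
    comp <- as.integer(names(which.min(d2)))
    m <- lab == comp
    if (sum(m) < 5L) next
    out$size[k] <- sum(m)
    ## perimeter = exposed 4-neighbour edges; circularity capped at 1
    exposed <- (m & !shift_mat(m, 1, 0, FALSE)) +
      (m & !shift_mat(m, -1, 0, FALSE)) +
      (m & !shift_mat(m, 0, 1, FALSE)) + (m & !shift_mat(m, 0, -1, FALSE))
    per <- sum(exposed)
    out$circularity[k] <- min(1, 4 * pi * sum(m) / per^2)
    out$flag_empty[k] <- FALSE
    border <- m & (row(m) == 1 | row(m) == nrow(m) |
                     col(m) == 1 | col(m) == ncol(m))
    bpix <- m & exposed > 0
    if (sum(bpix) > 0 && sum(border) / sum(bpix) > 0.25)
      out$flag_edge[k] <- TRUE
  }
  as_colony_table(out, condition = attr(layout, "condition"))
}
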