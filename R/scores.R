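#' Normalize colony sizes per plate
#'
#' `plate_median` divides every size on a plate by that plate's median
#' colony size; `control_reference` divides by the mean of the designated
#' on-plate reference colonies (`is_control = TRUE`). The latter is the
#' right choice when most strains on a plate carry an effect (retest
#' plates), where the plate median itself is shifted.
#'
#' @param table a `colony_table` (may span plates; normalization is per
#'   plate).
#' @param mode `"plate_median"` or `"control_reference"`.
#' @return the table with `size` replaced by normalized size; the per-plate
#'   normalization constants are kept in `attr(, "normalizers")`.
#' @export
normalize_plate <- function(table, mode = c("plate_median",
                                            "control_reference")) {
  mode <- match.arg(mode)
  out <- as.data.frame(table)
  norms <- list()
  for (p in unique(out$plate_id)) {
    sel <- out$plate_id == p
    sz <- out$size[sel]
    if (mode == "plate_median") {
      if (sum(!is.na(sz)) < 10L)
        stopf("plate %s has fewer than 10 measured colonies", p)
      k <- stats::median(sz, na.rm = TRUE)
    } else {
      ctl <- sz[out$is_control[sel] & !is.na(sz)]
      if (length(ctl) < 4L)
        stopf("plate %s has fewer than 4 measured control colonies", p)
      k <- mean(ctl)
    }
    if (!is.finite(k) || k <= 0)
      stopf("normalizer for plate %s is zero or undefined", p)
    out$size[sel] <- sz / k
    norms[[p]] <- k
  }
  out <- as_colony_table(out, condition = attr(table, "condition"))
  attr(out, "normalizers") <- unlist(norms)
  out
}

#' Log growth ratios of fusion vs control, per strain
#'
#' `lgr = ln(mean normalized control size / mean normalized fusion size)`
#' over each strain's replicates; absent replicates are excluded from the
#' means. Positive values mean a growth defect of the fusion. A zero fusion
#' mean (total lethality) yields `lgr = +Inf` with `flag_inf = TRUE`; such
#' values are excluded from z-score distribution fits but reported as
#' maximal hits.
#'
#' @param fusion,control normalized `colony_table`s sharing strain ids.
#' @param control_name label recorded in the result.
#' @return data.frame `strain, lgr, n_fusion, n_control, flag_inf,
#'   plate_id, row, col` (anchor position of the strain's block on the
#'   fusion plate).
#' @export
compute_lgr <- function(fusion, control, control_name = "control") {
  strains <- intersect(unique(fusion$strain), unique(control$strain))
  if (!length(strains)) stopf("fusion and control share no strains")
  agg <- function(tab) {
    ok <- !is.na(tab$size)
    n <- tapply(ok, tab$strain, sum)
    mu <- tapply(ifelse(ok, tab$size, NA), tab$strain, mean, na.rm = TRUE)
    list(n = n, mu = mu)
  }
  f <- agg(fusion); ctl <- agg(control)
  anchor <- fusion[!duplicated(fusion$strain), c("strain", "plate_id",
                                                 "row", "col")]
  out <- data.frame(strain = strains,
                    lgr = as.numeric(log(ctl$mu[strains] / f$mu[strains])),
                    n_fusion = as.integer(f$n[strains]),
                    n_control = as.integer(ctl$n[strains]),
                    stringsAsFactors = FALSE)
  out$lgr[out$n_fusion == 0L | out$n_control == 0L] <- NA
  out$flag_inf <- is.infinite(out$lgr)
  out <- merge(out, anchor, by = "strain", sort = TRUE)
  attr(out, "control_name") <- control_name
  out
}

#' Robust z-scores against both controls
#'
#' Standardizes each control's LGR distribution with median location and
#' 1.4826 x MAD scale (robust to the one-sided tail of true hits), and
#' averages the two control z-scores into `z_mean` (the single growth score
#' used downstream). Infinite LGRs keep `z = +Inf`.
#'
#' @param lgr_target,lgr_gbp [compute_lgr()] outputs for the target-only
#'   and GBP-only controls.
#' @param min_n minimum finite LGRs required per control (default 30).
#' @return `score_table` data.frame: `query, z_t, z_g, z_mean, plate_id,
#'   row, col`.
#' @export
compute_z <- function(lgr_target, lgr_gbp, min_n = 30L) {
  zscore <- function(lgr) {
    fin <- lgr$lgr[is.finite(lgr$lgr)]
    if (length(fin) < min_n)
      stopf("fewer than %d finite LGRs (%d)", min_n, length(fin))
    s <- stats::mad(fin)
    if (s == 0) stopf("zero MAD scale in LGR distribution")
    (lgr$lgr - stats::median(fin)) / s
  }
  stopifnot(identical(lgr_target$strain, lgr_gbp$strain))
  zt <- zscore(lgr_target); zg <- zscore(lgr_gbp)
  zm <- rowMeans(cbind(zt, zg), na.rm = TRUE)
  zm[is.na(zt) & is.na(zg)] <- NA
  out <- data.frame(query = lgr_target$strain, z_t = zt, z_g = zg,
                    z_mean = zm, plate_id = lgr_target$plate_id,
                    row = lgr_target$row, col = lgr_target$col,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Smooth one plate's z-field by local background subtraction
#'
#' For each grid position the local background is the chosen statistic of z
#' over the `(2w+1) x (2w+1)` window centred there, excluding the centre
#' position and every position carrying the centre's strain (so a strain's
#' own replicate block never contributes to its background); the window is
#' truncated at plate edges. Returns `z - background`.
#'
#' @param zmat numeric matrix of z values on the plate grid (NA = empty).
#' @param strain_mat character matrix of strain ids, same shape.
#' @param w window half-width (>= 1); `w = 0` returns `zmat` unchanged.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return list `z_smoothed` (matrix) and `no_neighbors` (logical matrix
#'   flagging positions whose window had no eligible neighbour, where
#'   `z_smoothed = z`).
#' @export
smooth_grid <- function(zmat, strain_mat, w = 3L,
                        statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (w == 0L) return(list(z_smoothed = zmat,
                           no_neighbors = matrix(FALSE, nrow(zmat),
                                                 ncol(zmat))))
  R <- nrow(zmat); C <- ncol(zmat)
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  zp <- matrix(NA_real_, R + 2L * w, C + 2L * w)
  zp[w + seq_len(R), w + seq_len(C)] <- zmat
  sp <- matrix(NA_character_, R + 2L * w, C + 2L * w)
  sp[w + seq_len(R), w + seq_len(C)] <- strain_mat
  nb <- matrix(NA_real_, R * C, nrow(offs))
  ctr_strain <- as.vector(strain_mat)
  for (o in seq_len(nrow(offs))) {
    rs <- w + offs$dr[o] + seq_len(R)
    cs <- w + offs$dc[o] + seq_len(C)
    v <- as.vector(zp[rs, cs])
    s <- as.vector(sp[rs, cs])
    v[!is.na(s) & !is.na(ctr_strain) & s == ctr_strain] <- NA
    nb[, o] <- v
  }
  stat <- if (statistic == "median") function(x) stats::median(x, na.rm = TRUE)
  else function(x) mean(x, na.rm = TRUE)
  bg <- apply(nb, 1L, stat)
  none <- !is.finite(bg)
  bg[none] <- 0
  list(z_smoothed = matrix(as.vector(zmat) - bg, R, C),
       no_neighbors = matrix(none & !is.na(zmat), R, C))
}

#' Spatial smoothing of a score table
#'
#' Applies [smooth_grid()] per plate to each control's z-field separately,
#' then recomputes the mean score from the smoothed per-control values
#' (smoothing precedes averaging). Each strain's replicate positions carry
#' its z; the strain-level smoothed z is the mean over its positions.
#'
#' @param scores a `score_table` from [compute_z()].
#' @param layout the fusion-condition [plate_layout()] (supplies every
#'   replicate position of every strain).
#' @param w window half-width (default 3, i.e. a 7x7 window: wider than one
#'   2x2 replicate block but still local). `w = 0` skips smoothing.
#' @param statistic window statistic, `"median"` default.
#' @return the score table with added `z_t_smoothed, z_g_smoothed,
#'   z_smoothed, flag_no_neighbors`.
#' @export
smooth_spatial <- function(scores, layout, w = 3L,
                           statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (w == 0L) {
    scores$z_t_smoothed <- scores$z_t
    scores$z_g_smoothed <- scores$z_g
    scores$z_smoothed <- scores$z_mean
    scores$flag_no_neighbors <- FALSE
    return(scores)
  }
  lay <- as.data.frame(layout)
  dims <- layout_dims(layout)
  for (col_in in c("z_t", "z_g")) {
    sm <- rep(NA_real_, nrow(scores)); flg <- rep(FALSE, nrow(scores))
    zq <- structure(scores[[col_in]], names = scores$query)
    for (p in unique(lay$plate_id)) {
      sel <- lay$plate_id == p
      smat <- matrix(NA_character_, dims["rows"], dims["cols"])
      smat[cbind(lay$row[sel] + 1L, lay$col[sel] + 1L)] <- lay$strain[sel]
      zmat <- matrix(zq[smat], dims["rows"], dims["cols"])
      zmat[is.infinite(zmat)] <- NA       # lethal hits excluded from fields
      res <- smooth_grid(zmat, smat, w, statistic)
      zsm <- tapply(as.vector(res$z_smoothed), as.vector(smat), mean,
                    na.rm = TRUE)
      nn <- tapply(as.vector(res$no_neighbors), as.vector(smat), any)
      idx <- match(names(zsm), scores$query)
      ok <- !is.na(idx)
      sm[idx[ok]] <- zsm[ok]; flg[idx[ok]] <- nn[ok]
    }
    inf <- is.infinite(scores[[col_in]])
    sm[inf] <- scores[[col_in]][inf]
    scores[[paste0(col_in, "_smoothed")]] <- sm
    if (col_in == "z_t") scores$flag_no_neighbors <- flg
    else scores$flag_no_neighbors <- scores$flag_no_neighbors | flg
  }
  zm <- rowMeans(cbind(scores$z_t_smoothed, scores$z_g_smoothed),
                 na.rm = TRUE)
  zm[is.na(scores$z_t_smoothed) & is.na(scores$z_g_smoothed)] <- NA
  scores$z_smoothed <- zm
  scores
}

#' Score a screen end to end
#'
#' Chains [normalize_plate()], [compute_lgr()] against both controls,
#' [compute_z()] and [smooth_spatial()].
#'
#' @param fusion,control_target,control_gbp `colony_table`s.
#' @param layout fusion-condition layout (for smoothing positions).
#' @param normalize_mode passed to [normalize_plate()].
#' @param w,statistic passed to [smooth_spatial()].
#' @param min_n passed to [compute_z()].
#' @return a `score_table` with raw and smoothed z columns.
#' @export
score_screen <- function(fusion, control_target, control_gbp, layout,
                         normalize_mode = "plate_median", w = 3L,
                         statistic = "median", min_n = 30L) {
  fn <- normalize_plate(fusion, normalize_mode)
  tn <- normalize_plate(control_target, normalize_mode)
  gn <- normalize_plate(control_gbp, normalize_mode)
  lt <- compute_lgr(fn, tn, "target_only")
  lg <- compute_lgr(fn, gn, "gbp_only")
  z <- compute_z(lt, lg, min_n = min_n)
  z$lgr_t <- lt$lgr[match(z$query, lt$strain)]
  z$lgr_g <- lg$lgr[match(z$query, lg$strain)]
  smooth_spatial(z, layout, w = w, statistic = statistic)
}

#' Write a score table TSV
#'
#' Columns mirror the published per-screen score listings: one row per
#' query with each control's z, their mean, and the smoothed mean.
#' @param scores `score_table`.
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  write_tsv_commented(as.data.frame(scores), path,
                      "z columns: z_t (vs target-only), z_g (vs GBP-only), z_mean, z_smoothed")
}
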