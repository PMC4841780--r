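#' Build an arrayed-plate layout
#'
#' Arranges strains on 1536-format plates (32 rows x 48 columns by default)
#' with `replicate_block` colonies per strain placed as contiguous square
#' blocks (2x2 for the default four replicates), mirroring the standard
#' 384-to-1536 pinning expansion. Strains that do not fit on one plate
#' overflow onto further plates.
#'
#' Grid coordinates are 0-based `(row, col)` with row 0 at the image top;
#' every file written by this package states this convention in its header.
#'
#' @param strains character vector of strain (query) identifiers.
#' @param n_rows,n_cols plate grid dimensions.
#' @param replicate_block colonies per strain; must be a perfect square
#'   (1 or 4 are the usual values).
#' @param condition one of `"fusion"`, `"control_target_only"`,
#'   `"control_gbp_only"`.
#' @param plate_prefix prefix for generated plate identifiers.
#' @param control_positions optional character vector of strain ids to treat
#'   as on-plate reference controls (used by control-reference
#'   normalization).
#' @return a `plate_layout`: a data.frame with columns
#'   `plate_id, row, col, strain, is_control` and attributes
#'   `n_rows`, `n_cols`, `replicate_block`, `condition`.
#' @export
plate_layout <- function(strains, n_rows = 32L, n_cols = 48L,
                         replicate_block = 4L,
                         condition = c("fusion", "control_target_only",
                                       "control_gbp_only"),
                         plate_prefix = "plate",
                         control_positions = character()) {
  condition <- match.arg(condition)
  if (anyDuplicated(strains)) stopf("strain identifiers must be unique")
  b <- as.integer(round(sqrt(replicate_block)))
  if (b * b != replicate_block)
    stopf("replicate_block must be a perfect square (got %d)", replicate_block)
  if (n_rows %% b != 0 || n_cols %% b != 0)
    stopf("plate dimensions must be divisible by the replicate block side")
  blocks_per_plate <- (n_rows %/% b) * (n_cols %/% b)
  n <- length(strains)
  n_plates <- ceiling(n / blocks_per_plate)
  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1L) * blocks_per_plate + 1L):min(p * blocks_per_plate, n)
    k <- seq_along(idx) - 1L                       # block index, row-major
    br <- k %/% (n_cols %/% b)
    bc <- k %% (n_cols %/% b)
    off <- expand.grid(dr = 0:(b - 1L), dc = 0:(b - 1L))
    out[[p]] <- data.frame(
      plate_id = sprintf("%s%02d", plate_prefix, p),
      row = rep(br * b, each = nrow(off)) + rep(off$dr, length(idx)),
      col = rep(bc * b, each = nrow(off)) + rep(off$dc, length(idx)),
      strain = rep(strains[idx], each = nrow(off)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  out$is_control <- out$strain %in% control_positions
  structure(out, class = c("plate_layout", "data.frame"),
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            replicate_block = as.integer(replicate_block),
            condition = condition)
}

layout_dims <- function(layout) {
  c(rows = attr(layout, "n_rows") %||% (max(layout$row) + 1L),
    cols = attr(layout, "n_cols") %||% (max(layout$col) + 1L))
}
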