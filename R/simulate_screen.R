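#' Specification for a synthetic SPI screen
#'
#' Describes the generative model for one or more arrayed screens: each query
#' strain is pinned in replicate blocks under three conditions (the GBP-GFP
#' fusion and the two control constructs). Colony size is
#' \deqn{base \times control\_effect_q \times gradient(row, col) \times
#'   (1 - effect_{q,t})^{[fusion]} \times e^{\sigma Z}}
#' with lognormal multiplicative noise (colony areas are positive and
#' right-skewed) and a smooth positive spatial gradient shared by all three
#' conditions. A planted SPI reduces size in the fusion condition only.
#'
#' @param n_queries number of query strains.
#' @param n_targets number of target screens (each gets its own fusion
#'   plates; the control conditions are per-target as in the screen design).
#' @param replicate_count colonies per strain (perfect square; default 4,
#'   arranged 2x2).
#' @param gradient_model named coefficients of a low-order polynomial over
#'   normalized coordinates `u = row/(n_rows-1)`, `v = col/(n_cols-1)`:
#'   any of `intercept, row, col, row2, col2, rowcol`. The resulting
#'   multiplier must be positive over the plate.
#' @param noise_sigma lognormal shape parameter of colony size (default 0.2,
#'   a typical replicate CV for pinned colony areas; the source screens do
#'   not report per-colony variance).
#' @param spi_set data.frame with columns `query, target, effect`; effects
#'   are fractional size reductions in (0, 1].
#' @param control_effects per-query baseline fitness multipliers (named or
#'   in query order), applied identically to all three conditions.
#' @param base_size mean colony area in pixels at gradient 1.
#' @param n_rows,n_cols plate dimensions.
#' @param seed integer seed.
#' @return a `screen_sim_spec` list.
#' @export
screen_sim_spec <- function(n_queries, n_targets = 1L, replicate_count = 4L,
                            gradient_model = c(intercept = 1),
                            noise_sigma = 0.2, spi_set = NULL,
                            control_effects = NULL, base_size = 200,
                            n_rows = 32L, n_cols = 48L, seed = 1L) {
  queries <- sprintf("Q%04d", seq_len(n_queries))
  targets <- sprintf("T%02d", seq_len(n_targets))
  if (is.null(spi_set))
    spi_set <- data.frame(query = character(), target = character(),
                          effect = numeric())
  assert_cols(spi_set, c("query", "target", "effect"), "spi_set")
  if (nrow(spi_set)) {
    if (!all(spi_set$query %in% queries))
      stopf("spi_set references unknown query strain(s)")
    if (!all(spi_set$target %in% targets))
      stopf("spi_set references unknown target(s)")
    if (any(spi_set$effect <= 0 | spi_set$effect > 1))
      stopf("SPI effects must lie in (0, 1]")
  }
  if (is.null(control_effects)) control_effects <- rep(1, n_queries)
  if (is.null(names(control_effects))) names(control_effects) <- queries
  g <- gradient_values(gradient_model, n_rows, n_cols)
  if (any(g <= 0)) stopf("gradient multiplier must be positive over the plate")
  structure(list(queries = queries, targets = targets,
                 replicate_count = as.integer(replicate_count),
                 gradient_model = gradient_model, noise_sigma = noise_sigma,
                 spi_set = spi_set, control_effects = control_effects,
                 base_size = base_size, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), seed = as.integer(seed)),
            class = "screen_sim_spec")
}

gradient_values <- function(coef, n_rows, n_cols) {
  known <- c("intercept", "row", "col", "row2", "col2", "rowcol")
  bad <- setdiff(names(coef), known)
  if (length(bad)) stopf("unknown gradient coefficient(s): %s",
                         paste(bad, collapse = ", "))
  u <- matrix(seq(0, 1, length.out = n_rows), n_rows, n_cols)
  v <- matrix(seq(0, 1, length.out = n_cols), n_rows, n_cols, byrow = TRUE)
  cf <- function(k) if (k %in% names(coef)) coef[[k]] else 0
  cf("intercept") + cf("row") * u + cf("col") * v +
    cf("row2") * u^2 + cf("col2") * v^2 + cf("rowcol") * u * v
}

sim_condition_sizes <- function(spec, layout, effect_by_strain) {
  g <- gradient_values(spec$gradient_model, spec$n_rows, spec$n_cols)
  ce <- spec$control_effects[layout$strain]
  ce[is.na(ce)] <- 1                      # reference controls
  eff <- effect_by_strain[layout$strain]
  eff[is.na(eff)] <- 0
  mu <- spec$base_size * ce * g[cbind(layout$row + 1L, layout$col + 1L)] *
    (1 - eff)
  mu * exp(stats::rnorm(nrow(layout), 0, spec$noise_sigma))
}

#' Simulate a synthetic SPI screen with planted ground truth
#'
#' Generates, per target, colony tables for the fusion condition and the two
#' controls, plus a truth table of the planted SPIs. Deterministic per
#' `spec$seed`; the caller's RNG state is untouched.
#'
#' @param spec a [screen_sim_spec()].
#' @return For a single-target spec: a list
#'   `fusion, control_target, control_gbp` (colony tables), `truth`
#'   (data.frame `query, target, effect`), and `layout`. For multi-target
#'   specs the per-target lists sit under `$screens[[target]]`.
#' @export
simulate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  with_seed(spec$seed, {
    layouts <- lapply(
      c(fusion = "fusion", control_target = "control_target_only",
        control_gbp = "control_gbp_only"),
      function(cond) plate_layout(spec$queries, spec$n_rows, spec$n_cols,
                                  spec$replicate_count, condition = cond))
    screens <- lapply(spec$targets, function(tg) {
      eff <- structure(numeric(length(spec$queries)), names = spec$queries)
      pl <- spec$spi_set[spec$spi_set$target == tg, ]
      eff[pl$query] <- pl$effect
      none <- structure(numeric(length(spec$queries)), names = spec$queries)
      out <- list(
        fusion = sim_condition_sizes(spec, layouts$fusion, eff),
        control_target = sim_condition_sizes(spec, layouts$control_target,
                                             none),
        control_gbp = sim_condition_sizes(spec, layouts$control_gbp, none))
      lapply(seq_along(out), function(i) {
        lay <- as.data.frame(layouts[[i]])
        lay$size <- out[[i]]
        as_colony_table(lay, condition = attr(layouts[[i]], "condition"))
      }) |> stats::setNames(names(out))
    }) |> stats::setNames(spec$targets)
    truth <- spec$spi_set
    if (length(spec$targets) == 1L)
      c(screens[[1L]], list(truth = truth, layout = layouts$fusion))
    else list(screens = screens, truth = truth, layout = layouts$fusion)
  })
}

#' Simulate 16-replicate retest plates for candidate strains
#'
#' Reproduces the confirmation design: each candidate is pinned with
#' `replicate_count` replicates alongside `controls_per_plate` neutral
#' reference strains per plate, under the fusion and both control
#' conditions. With the defaults, 80 candidates plus 16 references fill one
#' 1536-position plate exactly. Larger candidate lists split across plates.
#'
#' @param candidates character vector of strain ids to retest.
#' @param truth truth table (`query, target, effect`); candidates absent
#'   from it carry no effect.
#' @param target target id the retest belongs to (default: first in truth,
#'   else "T01").
#' @param replicate_count replicates per strain (default 16, pinned 4x4).
#' @param controls_per_plate neutral reference strains per plate (default 16).
#' @param noise_sigma,base_size,n_rows,n_cols as in [screen_sim_spec()].
#' @param seed integer seed.
#' @return list `fusion, control_target, control_gbp` colony tables (the
#'   reference strains carry `is_control = TRUE`), plus `n_plates`.
#' @export
simulate_retest_plate <- function(candidates, truth, target = NULL,
                                  replicate_count = 16L,
                                  controls_per_plate = 16L,
                                  noise_sigma = 0.2, base_size = 200,
                                  n_rows = 32L, n_cols = 48L, seed = 1L) {
  if (!length(candidates)) stopf("candidate list is empty")
  if (is.null(target))
    target <- if (nrow(truth)) truth$target[1] else "T01"
  b <- as.integer(round(sqrt(replicate_count)))
  blocks_per_plate <- (n_rows %/% b) * (n_cols %/% b)
  per_plate <- blocks_per_plate - controls_per_plate
  if (per_plate < 1L) stopf("controls_per_plate leaves no candidate capacity")
  n_plates <- ceiling(length(candidates) / per_plate)
  eff <- structure(numeric(length(candidates)), names = candidates)
  tr <- truth[truth$target == target & truth$query %in% candidates, ]
  eff[tr$query] <- tr$effect
  conds <- c(fusion = "fusion", control_target = "control_target_only",
             control_gbp = "control_gbp_only")
  spec <- list(gradient_model = c(intercept = 1), noise_sigma = noise_sigma,
               base_size = base_size, n_rows = n_rows, n_cols = n_cols,
               control_effects = structure(numeric(0), names = character(0)))
  with_seed(seed, {
    out <- lapply(conds, function(cond) {
      tabs <- lapply(seq_len(n_plates), function(p) {
        idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate,
                                               length(candidates))
        refs <- sprintf("ref_p%02d_%02d", p, seq_len(controls_per_plate))
        lay <- plate_layout(c(candidates[idx], refs), n_rows, n_cols,
                            replicate_count, condition = cond,
                            plate_prefix = sprintf("retest_p%02d_", p),
                            control_positions = refs)
        lay <- as.data.frame(lay)
        e <- if (cond == "fusion") eff else
          structure(numeric(length(candidates)), names = candidates)
        lay$size <- sim_condition_sizes(
          modifyList(spec, list()), lay,
          c(e, structure(numeric(length(refs)), names = refs)))
        lay
      })
      as_colony_table(do.call(rbind, tabs), condition = cond)
    })
    c(out, list(n_plates = n_plates))
  })
}
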