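## Declarative pipeline driver: one JSON config names the inputs, output
## directory and every stage parameter; all defaults are echoed into the
## run log so a report is auditable. Outputs are bit-reproducible from
## config + seed (no timestamps in any output file).

pipeline_defaults <- function() {
  list(
    seed = NULL,
    seed_auto_generated = FALSE,
    outdir = "spi_out",
    simulate = NULL,
    inputs = NULL,
    normalize_mode = "plate_median",
    smoothing = list(w = 3, statistic = "median"),
    retest = list(batch_size = 20, stop_fdr = 0.4, tau = 0.15, alpha = 0.05,
                  max_candidates = 80, replicates = 16,
                  controls_per_plate = 16, require = "both",
                  noise_sigma = 0.2),
    cluster = FALSE
  )
}

merge_config <- function(defaults, cfg, path = "") {
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad))
    stopf("unknown config key%s: %s", if (length(bad) > 1) "s" else "",
          paste0(path, bad, collapse = ", "))
  for (k in names(cfg)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(cfg[[k]]) &&
                         !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], cfg[[k]], paste0(k, "."))
    else cfg[[k]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' @param path JSON config file. Unknown keys are an error; omitted keys
#'   take the documented defaults. A missing seed is drawn once and
#'   logged.
#' @return config list with all defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(pipeline_defaults(), cfg)
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(.Machine$integer.max, 1L)
    cfg$seed_auto_generated <- TRUE
  }
  cfg
}

#' Write / read a plate layout TSV
#' @param layout a [plate_layout()].
#' @param path file path.
#' @export
write_layout <- function(layout, path) {
  dims <- layout_dims(layout)
  write_tsv_commented(as.data.frame(layout), path,
                      c(sprintf("n_rows: %d", dims["rows"]),
                        sprintf("n_cols: %d", dims["cols"]),
                        sprintf("replicate_block: %d",
                                attr(layout, "replicate_block") %||% 4L),
                        sprintf("condition: %s",
                                attr(layout, "condition") %||% "fusion")))
}

#' @rdname write_layout
#' @param condition condition label to attach.
#' @export
read_layout <- function(path, condition = "fusion") {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  tab <- read_tsv_commented(path)
  assert_cols(tab, c("plate_id", "row", "col", "strain"), "layout")
  if (is.null(tab$is_control)) tab$is_control <- FALSE
  num <- function(key, fallback)
    if (any(g <- grepl(key, hdr)))
      as.integer(sub(".*: *", "", hdr[g][1])) else fallback
  structure(tab, class = c("plate_layout", "data.frame"),
            n_rows = num("n_rows", max(tab$row) + 1L),
            n_cols = num("n_cols", max(tab$col) + 1L),
            replicate_block = num("replicate_block", 4L),
            condition = condition)
}

#' Run the full screening pipeline from a config file
#'
#' Stages: obtain colony tables (simulated with planted truth, or read
#' from TSV inputs), score (normalize, LGR vs both controls, robust z),
#' smooth spatially (skipped and logged when `smoothing.w` is 0), rank,
#' sequentially retest with FDR stopping (simulated retests when running
#' from synthetic truth), and export score/SPI/FDR tables plus an optional
#' cluster export. Every parameter in effect is echoed to `log.txt`.
#'
#' @param config path to a JSON config, or a config list from
#'   [read_config()].
#' @return invisibly, a list with the score table, SPI calls, FDR
#'   trajectory and output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else
    merge_config(pipeline_defaults(), config)
  if (is.null(cfg$seed)) { cfg$seed <- 271828L; cfg$seed_auto_generated <- TRUE }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(cfg$outdir, "log.txt")
  logger <- function(...) cat(sprintf(...), "\n", sep = "", file = log,
                              append = TRUE)
  cat("spiscreen pipeline log\n", file = log)
  logger("parameters: %s",
         jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"))
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    spi <- NULL
    if (!is.null(sim$spi))
      spi <- with_seed(cfg$seed, data.frame(
        query = sample(sprintf("Q%04d", seq_len(sim$n_queries)), sim$spi$n),
        target = "T01",
        effect = stats::runif(sim$spi$n, sim$spi$effect_min,
                              sim$spi$effect_max)))
    spec <- screen_sim_spec(
      n_queries = sim$n_queries, replicate_count = sim$replicate_count %||% 4L,
      gradient_model = unlist(sim$gradient %||% c(intercept = 1)),
      noise_sigma = sim$noise_sigma %||% 0.2, spi_set = spi,
      seed = cfg$seed)
    scr <- simulate_screen(spec)
    truth <- scr$truth
    fusion <- scr$fusion; ctl_t <- scr$control_target
    ctl_g <- scr$control_gbp; layout <- scr$layout
    write_tsv_commented(truth, file.path(cfg$outdir, "truth.tsv"))
    logger("simulated screen: %d queries, %d planted SPIs",
           sim$n_queries, nrow(truth))
  } else if (!is.null(cfg$inputs)) {
    for (f in unlist(cfg$inputs))
      if (!file.exists(f)) stopf("missing input file: %s", f)
    layout <- read_layout(cfg$inputs$layout)
    fusion <- read_colony_table(cfg$inputs$fusion, layout)
    ctl_t <- read_colony_table(cfg$inputs$control_target, layout)
    ctl_g <- read_colony_table(cfg$inputs$control_gbp, layout)
  } else stopf("config must provide either 'simulate' or 'inputs'")
  w <- cfg$smoothing$w
  if (w == 0) logger("smoothing stage skipped (window 0)")
  scores <- score_screen(fusion, ctl_t, ctl_g, layout,
                         normalize_mode = cfg$normalize_mode,
                         w = w, statistic = cfg$smoothing$statistic)
  write_score_table(scores, file.path(cfg$outdir, "scores.tsv"))
  ranked <- rank_candidates(scores)
  res <- NULL
  if (!is.null(truth) && cfg$retest$max_candidates > 0) {
    cands <- utils::head(ranked, cfg$retest$max_candidates)
    retest <- simulate_retest_plate(
      cands, truth, replicate_count = cfg$retest$replicates,
      controls_per_plate = cfg$retest$controls_per_plate,
      noise_sigma = cfg$retest$noise_sigma, seed = cfg$seed + 1L)
    src <- retest_source(retest)
    res <- sequential_fdr(ranked, src, batch_size = cfg$retest$batch_size,
                          stop_fdr = cfg$retest$stop_fdr,
                          max_candidates = cfg$retest$max_candidates,
                          tau = cfg$retest$tau, alpha = cfg$retest$alpha,
                          require = cfg$retest$require)
    write_tsv_commented(res$calls, file.path(cfg$outdir, "spi_calls.tsv"))
    write_tsv_commented(res$batches,
                        file.path(cfg$outdir, "fdr_trajectory.tsv"))
    logger("retest: %d batches, stopped at %s, %d confirmed",
           nrow(res$batches), res$stopped_at, sum(res$calls$confirmed))
  }
  if (isTRUE(cfg$cluster)) {
    m <- cbind(z_t = scores$z_t_smoothed %||% scores$z_t,
               z_g = scores$z_g_smoothed %||% scores$z_g)
    rownames(m) <- scores$query
    keep <- rowSums(is.finite(m)) >= 2
    tree <- cluster_profiles(m[keep, , drop = FALSE])
    write_cdt(m[keep, , drop = FALSE], row_tree = tree,
              path_prefix = file.path(cfg$outdir, "clustered"))
  }
  logger("done")
  invisible(list(scores = scores, spi = res, outdir = cfg$outdir,
                 truth = truth, config = cfg))
}
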