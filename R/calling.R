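#' Rank screen candidates by descending z
#'
#' Orders queries from strongest to weakest growth defect using
#' `z_smoothed` when present (falling back to `z_mean`); ties are broken by
#' the GBP-only control z, then lexicographic query id, so the ranking is
#' deterministic.
#'
#' @param scores a `score_table`.
#' @return character vector of query ids, strongest defect first. Queries
#'   with no defined score are dropped.
#' @export
rank_candidates <- function(scores) {
  z <- scores$z_smoothed %||% scores$z_mean
  if (is.null(z)) z <- scores$z_mean
  keep <- !is.na(z)
  ord <- order(-z[keep], -scores$z_g[keep], scores$query[keep],
               method = "radix")
  scores$query[keep][ord]
}

#' Confirm one strain from 16-replicate retest data
#'
#' A strain is confirmed when, against BOTH controls (or either, if
#' `require = "either"`), the log growth ratio reaches the effect-size
#' floor `tau` and a one-sided rank-sum test of control vs fusion replicate
#' sizes rejects at level `alpha` (exact null for these replicate numbers,
#' normal approximation under ties).
#'
#' @param fusion,control_a,control_b numeric replicate size vectors
#'   (normalized; NA = absent colony).
#' @param tau minimum LGR (default 0.15).
#' @param alpha test level (default 0.05).
#' @param min_replicates minimum non-absent replicates per condition
#'   (default 12); below it the call is indeterminate.
#' @param require `"both"` or `"either"` control to be defeated.
#' @return list: `confirmed`, `indeterminate`, `lgr_a`, `lgr_b`, `p_a`,
#'   `p_b`.
#' @export
confirm_strain <- function(fusion, control_a, control_b, tau = 0.15,
                           alpha = 0.05, min_replicates = 12L,
                           require = c("both", "either")) {
  require <- match.arg(require)
  f <- fusion[!is.na(fusion)]
  a <- control_a[!is.na(control_a)]
  b <- control_b[!is.na(control_b)]
  if (min(length(f), length(a), length(b)) < min_replicates)
    return(list(confirmed = FALSE, indeterminate = TRUE,
                lgr_a = NA, lgr_b = NA, p_a = NA, p_b = NA))
  test1 <- function(ctl) {
    lgr <- log(mean(ctl) / mean(f))
    p <- suppressWarnings(
      stats::wilcox.test(ctl, f, alternative = "greater"))$p.value
    c(lgr = lgr, p = p)
  }
  ta <- test1(a); tb <- test1(b)
  pass_a <- is.finite(ta["lgr"]) && ta["lgr"] >= tau && ta["p"] < alpha
  pass_b <- is.finite(tb["lgr"]) && tb["lgr"] >= tau && tb["p"] < alpha
  ok <- if (require == "both") pass_a && pass_b else pass_a || pass_b
  list(confirmed = ok, indeterminate = FALSE,
       lgr_a = unname(ta["lgr"]), lgr_b = unname(tb["lgr"]),
       p_a = unname(ta["p"]), p_b = unname(tb["p"]))
}

#' Build a retest data source from retest colony tables
#'
#' Normalizes each condition by the on-plate reference controls (the plate
#' median is unusable on retest plates, where most strains carry an effect)
#' and returns a lookup closure for [sequential_fdr()].
#'
#' @param retest output of [simulate_retest_plate()] (or any list with
#'   `fusion`, `control_target`, `control_gbp` colony tables carrying
#'   `is_control` reference positions).
#' @return `function(strain)` returning a list of the three normalized
#'   replicate-size vectors, or `NULL` if the strain is absent.
#' @export
retest_source <- function(retest) {
  norm <- lapply(retest[c("fusion", "control_target", "control_gbp")],
                 normalize_plate, mode = "control_reference")
  function(strain) {
    if (!strain %in% norm$fusion$strain) return(NULL)
    lapply(norm, function(tab) tab$size[tab$strain == strain])
  }
}

#' Sequential retest with batchwise FDR stopping
#'
#' Works down the ranked candidate list in batches (20 strains by default),
#' confirming each strain with [confirm_strain()]. Each batch's FDR is the
#' fraction of its retested strains failing confirmation (the 16-replicate
#' retest is treated as ground truth), and a trailing 3-point moving
#' average of batch FDRs is compared against `stop_fdr`: the procedure
#' stops after the first batch whose moving average reaches it. Confirmed
#' strains from every processed batch - including the stopping batch - are
#' the screen's SPIs.
#'
#' @param ranked character vector from [rank_candidates()].
#' @param source retest lookup from [retest_source()] (a
#'   `function(strain)`).
#' @param batch_size strains per batch (default 20).
#' @param stop_fdr moving-average threshold (default 0.40).
#' @param max_candidates retest at most this many ranked strains (default
#'   80, the retest-plate capacity; further plates are used if the FDR
#'   stays low).
#' @param tau,alpha,require passed to [confirm_strain()].
#' @return list: `calls` (data.frame `query, rank, batch, confirmed,
#'   indeterminate, lgr_t, lgr_g, p_t, p_g`), `batches` (data.frame
#'   `batch, n, n_confirmed, fdr, moving_avg_fdr`), `stopped_at` (index of
#'   the stopping batch, or NA if the list was exhausted).
#' @export
sequential_fdr <- function(ranked, source, batch_size = 20L,
                           stop_fdr = 0.40, max_candidates = 80L,
                           tau = 0.15, alpha = 0.05,
                           require = c("both", "either")) {
  require <- match.arg(require)
  if (!length(ranked)) stopf("ranked candidate list is empty")
  ranked <- utils::head(ranked, max_candidates)
  calls <- list(); batches <- list(); fdrs <- numeric(0)
  stopped_at <- NA_integer_
  n_batches <- ceiling(length(ranked) / batch_size)
  for (bi in seq_len(n_batches)) {
    idx <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(ranked))
    rows <- lapply(idx, function(i) {
      dat <- source(ranked[i])
      if (is.null(dat)) {
        warnf("no retest data for strain %s; skipped", ranked[i])
        return(NULL)
      }
      cc <- confirm_strain(dat$fusion, dat$control_target, dat$control_gbp,
                           tau = tau, alpha = alpha, require = require)
      data.frame(query = ranked[i], rank = i, batch = bi,
                 confirmed = cc$confirmed, indeterminate = cc$indeterminate,
                 lgr_t = cc$lgr_a, lgr_g = cc$lgr_b,
                 p_t = cc$p_a, p_g = cc$p_b, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows) || !nrow(rows)) next
    fdr <- mean(!rows$confirmed)
    fdrs <- c(fdrs, fdr)
    ma <- mean(utils::tail(fdrs, 3L))
    batches[[length(batches) + 1L]] <-
      data.frame(batch = bi, n = nrow(rows),
                 n_confirmed = sum(rows$confirmed), fdr = fdr,
                 moving_avg_fdr = ma)
    calls[[length(calls) + 1L]] <- rows
    if (ma >= stop_fdr) { stopped_at <- bi; break }
  }
  list(calls = do.call(rbind, calls), batches = do.call(rbind, batches),
       stopped_at = stopped_at)
}

#' Classify haploid/diploid suppression of confirmed SPIs
#'
#' A SPI is `suppressed` when it is confirmed in the haploid but not in the
#' heterozygous diploid (the untagged copy complements), and `dominant`
#' when confirmed in both. Confirmation defaults to the effect-size floor
#' `lgr >= tau`; pass explicit confirmation calls (from the full
#' [confirm_strain()] rule) to override.
#'
#' @param haploid_lgr,diploid_lgr named numeric vectors of retest LGRs.
#' @param tau minimum LGR (default 0.15).
#' @param haploid_confirmed,diploid_confirmed optional named logical
#'   vectors overriding the threshold rule.
#' @return data.frame `strain, class` with class in
#'   `{"dominant", "suppressed", "none"}` ("none": not a haploid SPI).
#' @export
classify_suppression <- function(haploid_lgr, diploid_lgr, tau = 0.15,
                                 haploid_confirmed = NULL,
                                 diploid_confirmed = NULL) {
  strains <- names(haploid_lgr)
  if (is.null(strains)) stopf("haploid_lgr must be named by strain")
  h <- haploid_confirmed %||% (haploid_lgr >= tau)
  d <- diploid_confirmed %||% (diploid_lgr[strains] >= tau)
  cls <- ifelse(!h, "none", ifelse(d, "dominant", "suppressed"))
  data.frame(strain = strains, class = unname(cls),
             stringsAsFactors = FALSE)
}
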