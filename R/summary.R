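#' Headline screen proportions from explicit counts
#'
#' Computes the summary proportions of a proteome-wide screen from
#' numerator/denominator pairs, keeping the provenance of every number.
#' Percentages are rounded half away from zero to `digits`; the
#' SPIs-per-query mean is reported to one decimal. A zero denominator
#' yields NA (undefined), never 0.
#'
#' @param counts named list of `c(numerator, denominator)` pairs. Known
#'   names (others pass through as plain percentages):
#'   `benign` (benign fraction of all combinations), `colocalized`
#'   (colocalized fraction of scorable cross-compartment pairs),
#'   `same_compartment_scorable`, `spis_per_query` (confirmed SPIs /
#'   SPI queries; reported as a mean, 1 decimal), `human_homolog`
#'   (SPI queries with human homologs), `nonfrequent_diploid`
#'   (non-frequent SPIs reproduced in diploids).
#' @param digits decimals for percentage rounding (default 0).
#' @return data.frame `stat, numerator, denominator, raw, value` where
#'   `value` is on the reported scale (percent, or mean for
#'   `spis_per_query`).
#' @export
headline_stats <- function(counts, digits = 0) {
  rows <- lapply(names(counts), function(nm) {
    num <- counts[[nm]][1]; den <- counts[[nm]][2]
    if (is.na(den) || den == 0)
      return(data.frame(stat = nm, numerator = num, denominator = den,
                        raw = NA_real_, value = NA_real_))
    raw <- num / den
    if (nm == "spis_per_query")
      data.frame(stat = nm, numerator = num, denominator = den, raw = raw,
                 value = round_half_up(raw, 1))
    else
      data.frame(stat = nm, numerator = num, denominator = den,
                 raw = 100 * raw, value = round_half_up(100 * raw, digits))
  })
  do.call(rbind, rows)
}

#' Summary report of a screen's headline proportions
#'
#' Assembles the counts behind each headline statistic from the available
#' inputs and delegates the arithmetic to [headline_stats()]. Statistics
#' whose inputs are missing are omitted; statistics whose denominator is
#' zero are reported as NA.
#'
#' @param spi_calls data.frame `query, target, confirmed` across screens
#'   (or NULL).
#' @param annotations annotation data.frame with `protein`,
#'   `human_homolog`, `validated_gfp` (or NULL).
#' @param colocalization data.frame per imaged combination with logical
#'   columns `scorable`, `same_compartment`, `colocalized` (or NULL).
#' @param suppression output of [classify_suppression()] for the
#'   non-frequent cohort (or NULL).
#' @param n_total_combinations total query x target combinations assayed
#'   (needed for the benign fraction).
#' @param counts optional pre-tabulated count pairs (as in
#'   [headline_stats()]); these override derived ones, supporting exact
#'   recomputation from a published table.
#' @return the [headline_stats()] data.frame.
#' @export
summary_stats <- function(spi_calls = NULL, annotations = NULL,
                          colocalization = NULL, suppression = NULL,
                          n_total_combinations = NULL, counts = list()) {
  derived <- list()
  if (!is.null(spi_calls)) {
    conf <- spi_calls[spi_calls$confirmed, c("query", "target")]
    conf <- conf[!duplicated(conf), ]
    n_spi <- nrow(conf)
    spi_q <- unique(conf$query)
    if (!is.null(n_total_combinations))
      derived$benign <- c(n_total_combinations - n_spi,
                          n_total_combinations)
    derived$spis_per_query <- c(n_spi, length(spi_q))
    if (!is.null(annotations)) {
      hh <- annotations$human_homolog[match(spi_q, annotations$protein)]
      derived$human_homolog <- c(sum(hh, na.rm = TRUE), length(spi_q))
      val <- annotations$protein[annotations$validated_gfp]
      derived$validated_spi_queries <- c(sum(spi_q %in% val), length(val))
    }
  }
  if (!is.null(colocalization)) {
    sc <- colocalization[colocalization$scorable, ]
    derived$same_compartment_scorable <- c(sum(sc$same_compartment),
                                           nrow(sc))
    cross <- sc[!sc$same_compartment, ]
    derived$colocalized <- c(sum(cross$colocalized), nrow(cross))
  }
  if (!is.null(suppression)) {
    called <- suppression$class != "none"
    derived$nonfrequent_diploid <- c(sum(suppression$class == "dominant"),
                                     sum(called))
  }
  headline_stats(utils::modifyList(derived, counts))
}
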