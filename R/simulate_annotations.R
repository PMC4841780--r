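#' Simulate a protein annotation table and interaction network
#'
#' Annotations emulate the standard per-protein metadata used downstream:
#' cellular compartment (multinomial over `compartments`), abundance
#' (lognormal molecules-per-cell, a small fraction missing), essentiality,
#' GFP-validation and human-homolog flags. Optionally a designated
#' compartment is over-represented among a supplied set of SPI queries
#' (to exercise enrichment tests), and network edges are planted
#' preferentially inside a designated module (to exercise
#' interaction-density ranking).
#'
#' @param n_proteins number of proteins.
#' @param compartments named numeric vector of compartment proportions
#'   (must sum to 1).
#' @param abundance_meanlog,abundance_sdlog lognormal abundance parameters
#'   (defaults approximate yeast protein copy numbers, median ~3000/cell).
#' @param missing_abundance fraction of proteins with unknown abundance.
#' @param essential_prob,human_homolog_prob,validated_prob Bernoulli rates
#'   for the boolean flags (defaults 0.18, 0.56 and 0.65, typical of the
#'   yeast proteome).
#' @param spi_queries optional protein ids to receive compartment
#'   enrichment.
#' @param enriched_compartment,enrichment compartment name and multiplicative
#'   over-representation factor among `spi_queries` (1 = no planted signal).
#' @param module protein ids (or a count, taken from the start) forming the
#'   dense network module.
#' @param p_in,p_out edge probabilities inside/outside the module.
#' @param seed integer seed.
#' @return list with `annotations` (data.frame `protein, compartment,
#'   abundance, essential, validated_gfp, human_homolog`) and `network`
#'   (data.frame `a, b, type`, deduplicated undirected edges, no
#'   self-edges).
#' @export
simulate_annotations <- function(n_proteins,
                                 compartments = c(nucleus = 0.3,
                                                  cytoplasm = 0.4,
                                                  membrane = 0.2,
                                                  mitochondria = 0.1),
                                 abundance_meanlog = 8, abundance_sdlog = 1.5,
                                 missing_abundance = 0.05,
                                 essential_prob = 0.18,
                                 human_homolog_prob = 0.56,
                                 validated_prob = 0.65,
                                 spi_queries = character(),
                                 enriched_compartment = NULL,
                                 enrichment = 1,
                                 module = integer(), p_in = 0.3, p_out = 0.01,
                                 seed = 1L) {
  if (abs(sum(compartments) - 1) > 1e-8)
    stopf("compartment proportions must sum to 1")
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  with_seed(seed, {
    comp <- sample(names(compartments), n_proteins, replace = TRUE,
                   prob = compartments)
    if (!is.null(enriched_compartment) && enrichment != 1 &&
        length(spi_queries)) {
      w <- compartments
      w[enriched_compartment] <- w[enriched_compartment] * enrichment
      idx <- match(intersect(spi_queries, proteins), proteins)
      comp[idx] <- sample(names(w), length(idx), replace = TRUE,
                          prob = w / sum(w))
    }
    abundance <- stats::rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
    abundance[stats::runif(n_proteins) < missing_abundance] <- NA
    ann <- data.frame(
      protein = proteins, compartment = comp, abundance = abundance,
      essential = stats::runif(n_proteins) < essential_prob,
      validated_gfp = stats::runif(n_proteins) < validated_prob,
      human_homolog = stats::runif(n_proteins) < human_homolog_prob,
      stringsAsFactors = FALSE)
    if (is.numeric(module) && length(module) == 1L)
      module <- proteins[seq_len(module)]
    pairs <- utils::combn(n_proteins, 2L)
    inside <- proteins[pairs[1, ]] %in% module &
      proteins[pairs[2, ]] %in% module
    p <- ifelse(inside, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < p
    net <- data.frame(a = proteins[pairs[1, keep]],
                      b = proteins[pairs[2, keep]],
                      type = sample(c("physical", "genetic"), sum(keep),
                                    replace = TRUE),
                      stringsAsFactors = FALSE)
    list(annotations = ann, network = net)
  })
}
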