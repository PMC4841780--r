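## Independent oracles. These deliberately avoid the package's code paths:
## the Fisher oracle enumerates table probabilities from binomial
## coefficients, and the clustering oracle re-derives every distance from
## the raw matrix at every step.

## One-sided (greater) Fisher p by brute-force enumeration over all tables
## with the observed margins, summing the probabilities of tables whose
## top-left cell is >= the observed one.
fisher_oracle <- function(a, b, c_, d) {
  n1 <- a + b; n2 <- c_ + d; k <- a + c_
  lo <- max(0, k - n2); hi <- min(k, n1)
  probs <- vapply(lo:hi, function(x)
    choose(n1, x) * choose(n2, k - x) / choose(n1 + n2, k), numeric(1))
  sum(probs[(lo:hi) >= a])
}

## Brute-force centroid linkage: at every step recompute all centroids from
## the original rows and scan all active pairs for the minimum 1 - Pearson
## distance, breaking ties by the sorted pair of smallest member indices.
centroid_linkage_oracle <- function(m) {
  n <- nrow(m)
  clusters <- lapply(seq_len(n), identity)   # member index sets
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      ci <- colMeans(m[clusters[[i]], , drop = FALSE], na.rm = TRUE)
      cj <- colMeans(m[clusters[[j]], , drop = FALSE], na.rm = TRUE)
      ok <- is.finite(ci) & is.finite(cj)
      dd <- if (sum(ok) < 2 || sd(ci[ok]) == 0 || sd(cj[ok]) == 0) 2 else
        1 - cor(ci[ok], cj[ok])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(d = dd, i = i, j = j, key = key)
    }
    i <- best$i; j <- best$j
    a <- ids[i]; b <- ids[j]
    if (min(clusters[[j]]) < min(clusters[[i]])) { t <- a; a <- b; b <- t }
    merges[step, ] <- c(a, b)
    heights[step] <- best$d
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merges, height = heights)
}

## small convenience: one simulated single-target screen
quick_screen <- function(n_queries = 200, n_spi = 0, effect = 0.5,
                         noise_sigma = 0.2, seed = 1,
                         gradient = c(intercept = 1), ...) {
  spi <- if (n_spi > 0) {
    qs <- with_seed_local(seed + 1000, sample(sprintf("Q%04d",
                                                      seq_len(n_queries)),
                                              n_spi))
    data.frame(query = qs, target = "T01", effect = effect)
  } else NULL
  spec <- screen_sim_spec(n_queries, spi_set = spi,
                          noise_sigma = noise_sigma,
                          gradient_model = gradient, seed = seed, ...)
  simulate_screen(spec)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
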