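#' Screen-screen Spearman correlation
#'
#' Spearman rank correlation (average ranks for ties) between screen score
#' columns, computed over pairwise-complete rows. Pairs sharing fewer than
#' `min_shared` finite rows are NA with a warning.
#'
#' @param matrix numeric matrix, rows = queries, columns = screens.
#' @param min_shared minimum shared finite rows per pair (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
screen_correlation <- function(matrix, min_shared = 3L) {
  cc <- stats::cor(matrix, method = "spearman",
                   use = "pairwise.complete.obs")
  fin <- is.finite(matrix)
  shared <- t(fin * 1) %*% (fin * 1)
  if (any(shared < min_shared)) {
    warnf("screen pair(s) share fewer than %d finite rows; set to NA",
          min_shared)
    cc[shared < min_shared] <- NA
  }
  diag(cc) <- 1
  cc
}

profile_distance <- function(c1, c2) {
  ok <- is.finite(c1) & is.finite(c2)
  if (sum(ok) < 2L) return(2)
  if (stats::sd(c1[ok]) == 0 || stats::sd(c2[ok]) == 0) return(2)
  1 - stats::cor(c1[ok], c2[ok])
}

#' Hierarchical centroid-linkage clustering of score profiles
#'
#' Agglomerative clustering with distance `1 - Pearson r` (centred) between
#' cluster centroids (the mean profile of members, missing entries
#' excluded), the scheme used by Cluster 3.0 for correlation-based centroid
#' linkage. Ties are broken deterministically by the smallest original leaf
#' index involved. Centroid linkage can produce height inversions; they are
#' recorded, not hidden. Rows with fewer than 2 finite entries are dropped
#' with a warning; zero-variance rows sit at the maximal distance (2) from
#' everything and are flagged.
#'
#' @param matrix numeric matrix with row names; rows are clustered.
#' @param axis `"rows"` (default) or `"cols"` (clusters the transpose).
#' @return an `spi_hclust` list: `merge`, `height` (hclust conventions),
#'   `order`, `labels`, `inversions` (logical per merge), `dropped`,
#'   `zero_variance`, and `method = "centroid"`.
#' @export
cluster_profiles <- function(matrix, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") matrix <- t(matrix)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- sprintf("row%d", seq_len(nrow(matrix)))
  fin <- rowSums(is.finite(matrix))
  dropped <- rownames(matrix)[fin < 2L]
  if (length(dropped)) {
    warnf("dropping %d row(s) with fewer than 2 finite entries",
          length(dropped))
    matrix <- matrix[fin >= 2L, , drop = FALSE]
  }
  n <- nrow(matrix)
  if (n < 2L) stopf("need at least 2 clusterable rows")
  zv <- apply(matrix, 1L, function(r) stats::sd(r[is.finite(r)]) == 0)
  ## active clusters: centroids, member leaf sets, merge-step id
  cent <- lapply(seq_len(n), function(i) matrix[i, ])
  members <- as.list(seq_len(n))
  id <- -seq_len(n)                        # hclust convention
  minleaf <- seq_len(n)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- profile_distance(cent[[i]], cent[[j]])
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    dmin <- Inf; pick <- NULL
    for (i in which(active)) for (j in which(active)) {
      if (j <= i) next
      d <- D[i, j]
      better <- d < dmin - 1e-12
      tie <- abs(d - dmin) <= 1e-12 && !is.null(pick)
      if (tie) {
        key_new <- sort(c(minleaf[i], minleaf[j]))
        key_old <- sort(c(minleaf[pick[1]], minleaf[pick[2]]))
        better <- key_new[1] < key_old[1] ||
          (key_new[1] == key_old[1] && key_new[2] < key_old[2])
      }
      if (better || is.null(pick)) { dmin <- min(d, dmin); pick <- c(i, j) }
    }
    i <- pick[1]; j <- pick[2]
    a <- id[i]; b <- id[j]
    if (minleaf[j] < minleaf[i]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(a, b)
    height[step] <- dmin
    members[[i]] <- c(members[[i]], members[[j]])
    cent[[i]] <- colMeans(matrix[members[[i]], , drop = FALSE], na.rm = TRUE)
    id[i] <- step
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active[j] <- FALSE
    for (k in which(active)) {
      if (k == i) next
      d <- profile_distance(cent[[i]], cent[[k]])
      D[min(i, k), max(i, k)] <- d
    }
  }
  ## leaf order: at each node the branch holding the lexicographically
  ## smallest label comes first, so the flattening is invariant to row
  ## permutation of the input
  labs <- rownames(matrix)
  flatten <- function(node) {
    if (node < 0) return(-node)
    l <- flatten(merge[node, 1]); r <- flatten(merge[node, 2])
    if (min(labs[l]) <= min(labs[r])) c(l, r) else c(r, l)
  }
  ord <- flatten(n - 1L)
  structure(list(merge = merge, height = height, order = ord,
                 labels = rownames(matrix),
                 inversions = height < cummax(c(0, height[-length(height)])),
                 dropped = dropped,
                 zero_variance = rownames(matrix)[zv],
                 method = "centroid", dist.method = "1 - pearson"),
            class = c("spi_hclust", "hclust"))
}

#' Per-query SPI counts and the frequent-SPI flag
#'
#' @param calls data.frame with `query`, `target`, `confirmed` across
#'   screens.
#' @param frequent_min minimum confirmed targets to call a query a
#'   "frequent SPI" (default 10).
#' @return data.frame `query, n_spi, frequent` (queries with >= 1
#'   confirmed SPI), with the full count histogram in
#'   `attr(, "histogram")`.
#' @export
spi_frequency <- function(calls, frequent_min = 10L) {
  assert_cols(calls, c("query", "target", "confirmed"), "calls")
  conf <- calls[calls$confirmed, c("query", "target")]
  conf <- conf[!duplicated(conf), ]
  n <- table(conf$query)
  out <- data.frame(query = names(n), n_spi = as.integer(n),
                    stringsAsFactors = FALSE)
  out$frequent <- out$n_spi >= frequent_min
  out <- out[order(-out$n_spi, out$query), ]
  rownames(out) <- NULL
  attr(out, "histogram") <- table(factor(out$n_spi,
                                         levels = seq_len(max(out$n_spi, 1))))
  out
}

#' Equal-count abundance bins and per-bin SPI proportions
#'
#' Proteins with known abundance are sorted and split into `n_bins`
#' equal-count bins (any remainder goes to the lowest bins, which is
#' recorded); for each bin the fraction of proteins with at least one
#' confirmed SPI is reported against the uniform expectation (the overall
#' SPI fraction).
#'
#' @param annotations data.frame with `protein` and `abundance`.
#' @param spi_queries character vector of proteins with >= 1 confirmed SPI.
#' @param n_bins number of bins (default 8).
#' @return data.frame `bin, n, abundance_lo, abundance_hi, n_spi,
#'   proportion`; `attr(, "expected")` is the overall SPI fraction,
#'   `attr(, "remainder")` the number of oversized low bins.
#' @export
abundance_binning <- function(annotations, spi_queries, n_bins = 8L) {
  assert_cols(annotations, c("protein", "abundance"), "annotations")
  ann <- annotations[!is.na(annotations$abundance), ]
  ann <- ann[order(ann$abundance, ann$protein), ]
  n <- nrow(ann)
  base <- n %/% n_bins; rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin <- rep(seq_len(n_bins), sizes)
  is_spi <- ann$protein %in% spi_queries
  out <- data.frame(
    bin = seq_len(n_bins), n = sizes,
    abundance_lo = tapply(ann$abundance, bin, min),
    abundance_hi = tapply(ann$abundance, bin, max),
    n_spi = as.integer(tapply(is_spi, bin, sum)))
  out$proportion <- out$n_spi / out$n
  attr(out, "expected") <- mean(is_spi)
  attr(out, "remainder") <- rem
  out
}

#' One-sided Fisher's exact test for enrichment
#'
#' Tests whether the in-group hit rate exceeds the background rate, by
#' direct hypergeometric tail summation over the 2x2 table
#' `rbind(in_group, background)` (rows are hit/miss count pairs). The odds
#' ratio uses the Haldane 0.5 correction when any cell is zero (flagged).
#'
#' @param in_group integer pair `c(hits, misses)` in the group of interest.
#' @param background integer pair `c(hits, misses)` outside it.
#' @return list `odds_ratio`, `p`, `haldane`, `table`.
#' @export
fisher_enrichment <- function(in_group, background) {
  a <- in_group[1]; b <- in_group[2]; c_ <- background[1]; d <- background[2]
  if (any(c(a, b, c_, d) < 0)) stopf("counts must be nonnegative")
  N <- a + b + c_ + d; K <- a + c_; n <- a + b
  if (n == 0 || (c_ + d) == 0)
    stopf("row margins of the 2x2 table must be positive")
  kmax <- min(K, n)
  p <- if (a == 0) 1 else sum(stats::dhyper(a:kmax, K, N - K, n))
  hald <- any(c(a, b, c_, d) == 0)
  if (hald) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  list(odds_ratio = (a * d) / (b * c_), p = min(1, p), haldane = hald,
       table = matrix(c(in_group, background), 2, byrow = TRUE))
}

#' Hypergeometric term enrichment with BH adjustment
#'
#' Generic annotation-set enrichment over user-supplied term sets: for each
#' term, the upper hypergeometric tail of the overlap between `gene_set`
#' and the term's members within `universe`, with Benjamini-Hochberg
#' adjustment across terms. Terms with zero overlap report p = 1.
#'
#' @param gene_set character vector (subset of `universe`).
#' @param annotation_sets named list of character vectors (each a subset of
#'   `universe`).
#' @param universe character vector of all genes.
#' @return data.frame `term, overlap, set_size, p, q`, sorted by p.
#' @export
term_enrichment <- function(gene_set, annotation_sets, universe) {
  if (!all(gene_set %in% universe)) stopf("gene_set must lie in universe")
  N <- length(unique(universe)); n <- length(unique(gene_set))
  res <- lapply(names(annotation_sets), function(tm) {
    s <- intersect(annotation_sets[[tm]], universe)
    k <- length(intersect(gene_set, s))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, length(s), N - length(s), n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, set_size = length(s), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out[order(out$p, out$term), ]
}

#' Interaction density along a ranked protein list
#'
#' A rank-block reimplementation of cutoff-by-interaction-density analysis:
#' for a log-spaced schedule of cutoffs k, `d(k)` is the edge density of
#' the known-interaction subgraph induced by the top-k ranked proteins.
#' The null distribution comes from shuffling the ranking `n_perm` times;
#' the enrichment block `k*` maximizes `(d(k) - null mean)/null sd`, and
#' the empirical p-value compares `d(k*)` with its permuted values. This is
#' deliberately simpler than kernel-density CLIK and is validated against
#' planted-module ground truth, not against the published tool.
#'
#' @param ranking character vector, strongest hit first.
#' @param network data.frame with columns `a, b` (undirected edges; edges
#'   with endpoints outside the ranking are ignored).
#' @param n_perm number of permutations (>= 100).
#' @param ks optional cutoff schedule (default: ~60 log-spaced values in
#'   [2, length(ranking)]).
#' @param seed permutation seed.
#' @return list `k, d, null_mean, null_sd, z, k_star, p, n_edges`.
#' @export
interaction_density_rank <- function(ranking, network, n_perm = 199L,
                                     ks = NULL, seed = 1L) {
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  n <- length(ranking)
  if (is.null(ks))
    ks <- unique(pmax(2L, round(exp(seq(log(2), log(n),
                                        length.out = 60L)))))
  ks <- sort(unique(ks[ks >= 2L & ks <= n]))
  pos <- structure(seq_len(n), names = ranking)
  keep <- network$a %in% ranking & network$b %in% ranking &
    network$a != network$b
  ea <- pos[network$a[keep]]; eb <- pos[network$b[keep]]
  dup <- duplicated(paste(pmin(ea, eb), pmax(ea, eb)))
  ea <- ea[!dup]; eb <- eb[!dup]
  dens <- function(pa, pb) {
    m <- sort(pmax(pa, pb))
    e_k <- findInterval(ks, m)
    2 * e_k / (ks * (ks - 1))
  }
  d <- dens(ea, eb)
  if (!length(ea))
    return(list(k = ks, d = d, null_mean = d * 0, null_sd = d * 0,
                z = d * NA, k_star = NA, p = 1, n_edges = 0L))
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      sh <- sample.int(n)
      dens(sh[ea], sh[eb])
    }, numeric(length(ks))))
  })
  mu <- colMeans(perm)
  sdv <- apply(perm, 2L, stats::sd)
  z <- (d - mu) / sdv
  z[!is.finite(z)] <- -Inf
  istar <- which.max(z)
  p <- (1 + sum(perm[, istar] >= d[istar])) / (n_perm + 1)
  list(k = ks, d = d, null_mean = mu, null_sd = sdv, z = z,
       k_star = ks[istar], p = p, n_edges = length(ea))
}
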