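test_that("screen correlations behave and respect monotone transforms", {
  m <- with_seed_local(1, matrix(rnorm(200), 50, 4,
                                 dimnames = list(NULL,
                                                 paste0("S", 1:4))))
  m[, 2] <- m[, 1]                       # duplicate screen
  m[, 3] <- -m[, 1]                      # negated screen
  cc <- screen_correlation(m)
  expect_equal(cc["S1", "S2"], 1)
  expect_equal(cc["S1", "S3"], -1)
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)
  ## strictly monotone transform leaves Spearman unchanged
  m2 <- m; m2[, 4] <- exp(3 * m[, 4])
  expect_equal(screen_correlation(m2)["S1", "S4"], cc["S1", "S4"])
  ## shared-SPI screens correlate above unrelated ones
  wins <- vapply(1:10, function(s) {
    z <- with_seed_local(s, {
      base <- rnorm(300)
      cbind(a = base + rnorm(300), b = base + rnorm(300), c = rnorm(300, 0, 1.5))
    })
    cc <- screen_correlation(z)
    cc["a", "b"] > max(cc["a", "c"], cc["b", "c"])
  }, logical(1))
  expect_gte(mean(wins), 0.9)
  ## too little overlap -> NA with warning
  m3 <- matrix(NA_real_, 10, 2, dimnames = list(NULL, c("x", "y")))
  m3[1:5, 1] <- rnorm(5); m3[6:10, 2] <- rnorm(5)
  expect_warning(c3 <- screen_correlation(m3), "fewer than")
  expect_true(is.na(c3["x", "y"]))
})

test_that("centroid clustering matches the brute-force oracle", {
  for (s in 1:30) {
    n <- with_seed_local(s, sample(3:6, 1))
    m <- with_seed_local(s + 100, matrix(rnorm(n * 5), n, 5))
    rownames(m) <- paste0("r", seq_len(n))
    got <- cluster_profiles(m)
    want <- centroid_linkage_oracle(m)
    expect_identical(got$merge, want$merge, label = paste("seed", s))
    expect_equal(got$height, want$height, tolerance = 1e-9)
  }
})

test_that("clustering handles structure, permutation, degenerate rows", {
  ## identical rows merge first at height 0
  m <- with_seed_local(2, matrix(rnorm(20), 4, 5))
  m[2, ] <- m[1, ]
  rownames(m) <- paste0("r", 1:4)
  tr <- cluster_profiles(m)
  expect_equal(tr$merge[1, ], c(-1L, -2L))
  expect_equal(tr$height[1], 0, tolerance = 1e-12)

  ## two planted groups split at the top level
  ok <- vapply(1:10, function(s) {
    base1 <- with_seed_local(s, rnorm(8)); base2 <- with_seed_local(s + 50, rnorm(8))
    m <- rbind(t(sapply(1:4, function(i) base1 + rnorm(8, 0, 0.3))),
               t(sapply(1:4, function(i) base2 + rnorm(8, 0, 0.3))))
    rownames(m) <- paste0("r", 1:8)
    tr <- cluster_profiles(m)
    ## the last merge joins the two groups: its children partition 1:4 / 5:8
    kids <- tr$merge[nrow(tr$merge), ]
    leaves <- function(node) if (node < 0) -node else
      unlist(lapply(tr$merge[node, ], leaves))
    setequal(leaves(kids[1]), 1:4) || setequal(leaves(kids[1]), 5:8)
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  ## row permutation: same tree structure on relabelled leaves
  m2 <- with_seed_local(3, matrix(rnorm(30), 6, 5,
                                  dimnames = list(paste0("r", 1:6), NULL)))
  p <- c(4, 1, 6, 2, 3, 5)
  t1 <- cluster_profiles(m2)
  t2 <- cluster_profiles(m2[p, ])
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-9)
  expect_identical(t1$labels[t1$order], t2$labels[t2$order])

  ## zero-variance and too-sparse rows are flagged/dropped
  m3 <- m2; m3[1, ] <- 7
  t3 <- cluster_profiles(m3)
  expect_equal(t3$zero_variance, "r1")
  m4 <- m2; m4[2, 2:5] <- NA
  expect_warning(t4 <- cluster_profiles(m4), "fewer than 2 finite")
  expect_false("r2" %in% t4$labels)
})

test_that("SPI frequency counts and boundary", {
  calls <- rbind(
    data.frame(query = "A", target = sprintf("T%02d", 1:10),
               confirmed = TRUE),
    data.frame(query = "B", target = sprintf("T%02d", 1:9),
               confirmed = TRUE),
    data.frame(query = "C", target = "T01", confirmed = FALSE))
  fr <- spi_frequency(calls)
  expect_true(fr$frequent[fr$query == "A"])
  expect_false(fr$frequent[fr$query == "B"])
  expect_false("C" %in% fr$query)
  expect_equal(sum(attr(fr, "histogram")), 2)
})

test_that("abundance binning is equal-count with a uniform reference", {
  ann <- data.frame(protein = sprintf("P%04d", 1:3368),
                    abundance = with_seed_local(4, rlnorm(3368, 8, 1.5)))
  ## uniform SPIs across abundance
  spis <- with_seed_local(5, sample(ann$protein, 400))
  ab <- abundance_binning(ann, spis, 8)
  expect_equal(ab$n, rep(421L, 8))
  expect_lt(max(abs(ab$proportion - attr(ab, "expected"))),
            4 * sqrt(0.12 * 0.88 / 421))
  ## SPIs concentrated in the lowest bin
  low <- ann$protein[order(ann$abundance)][1:300]
  ab2 <- abundance_binning(ann, low, 8)
  expect_gt(ab2$proportion[1], 7 * mean(ab2$proportion))
  ## remainder goes to the lowest bins
  ann2 <- data.frame(protein = sprintf("X%04d", 1:3370),
                     abundance = with_seed_local(6, rlnorm(3370, 8, 1.5)))
  ab3 <- abundance_binning(ann2, character(), 8)
  expect_equal(ab3$n, c(422L, 422L, rep(421L, 6)))
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  expect_equal(fisher_enrichment(c(5, 5), c(5, 5))$p,
               fisher_oracle(5, 5, 5, 5))
  expect_equal(fisher_enrichment(c(10, 0), c(0, 10))$p, 1 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_enrichment(c(0, 10), c(5, 5))$p, 1)
  ## Haldane correction flagged on zero cells
  fe <- fisher_enrichment(c(10, 0), c(0, 10))
  expect_true(fe$haldane)
  expect_equal(fe$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  ## random spot-checks against the oracle (full sweep in acceptance)
  for (s in 1:50) {
    tb <- with_seed_local(s, sample(0:12, 4, replace = TRUE))
    if (sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0) next
    expect_equal(fisher_enrichment(tb[1:2], tb[3:4])$p,
                 fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12, label = paste(tb, collapse = ","))
  }
})

test_that("term enrichment ranks planted sets and calibrates on null", {
  uni <- sprintf("G%03d", 1:200)
  sets <- list(hit = uni[1:20], other = uni[21:60],
               disjoint = uni[150:200])
  res <- term_enrichment(uni[1:20], sets, uni)
  expect_equal(res$term[1], "hit")
  expect_equal(res$p[res$term == "hit"], 1 / choose(200, 20),
               tolerance = 1e-9)
  expect_equal(res$p[res$term == "disjoint"], 1)
  expect_true(all(res$q >= res$p))
  ## null calibration: p for a random set is (super-)uniform, as a discrete
  ## exact test must be: P(p <= a) <= a, and p is not degenerate
  ps <- vapply(1:200, function(s) {
    gs <- with_seed_local(s, sample(uni, 15))
    term_enrichment(gs, sets["other"], uni)$p
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.08)
  expect_lte(mean(ps <= 0.2), 0.25)
  expect_gte(mean(ps), 0.4)
  expect_error(term_enrichment("NOT_IN", sets, uni), "universe")
})

test_that("interaction density finds planted blocks and degenerates safely", {
  ## complete graph: density identically 1
  n <- 12
  full <- expand.grid(a = sprintf("P%02d", 1:n), b = sprintf("P%02d", 1:n))
  full <- full[as.character(full$a) < as.character(full$b), ]
  r <- interaction_density_rank(sprintf("P%02d", 1:n), full, n_perm = 100)
  expect_true(all(r$d == 1))
  ## edgeless network
  r0 <- interaction_density_rank(sprintf("P%02d", 1:n),
                                 data.frame(a = character(),
                                            b = character()),
                                 n_perm = 100)
  expect_true(all(r0$d == 0))
  expect_equal(r0$p, 1)
  expect_error(interaction_density_rank(sprintf("P%02d", 1:n), full,
                                        n_perm = 10), ">= 100")
})

test_that("headline proportions carry provenance and handle empties", {
  st <- headline_stats(list(benign = c(129098, 131882),
                            spis_per_query = c(2784, 727),
                            empty_case = c(0, 0)))
  expect_equal(st$value[st$stat == "benign"], 98)
  expect_equal(st$value[st$stat == "spis_per_query"], 3.8)
  expect_true(is.na(st$value[st$stat == "empty_case"]))
  ## derived from calls: zero SPI queries -> undefined, not zero
  calls <- data.frame(query = "A", target = "T01", confirmed = FALSE)
  st2 <- summary_stats(spi_calls = calls, n_total_combinations = 100)
  expect_true(is.na(st2$value[st2$stat == "spis_per_query"]))
  expect_equal(st2$value[st2$stat == "benign"], 100)
  ## rounding is half away from zero
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(75.516), 76)
})
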