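test_that("screen generator obeys its closed forms", {
  ## null screen, no gradient, vanishing noise: fusion == controls per strain
  scr <- quick_screen(n_queries = 96, noise_sigma = 1e-12, seed = 3)
  f <- tapply(scr$fusion$size, scr$fusion$strain, mean)
  ct <- tapply(scr$control_target$size, scr$control_target$strain, mean)
  expect_equal(f, ct, tolerance = 1e-9)

  ## one planted SPI, effect 0.5: fusion exactly half of control
  spi <- data.frame(query = "Q0007", target = "T01", effect = 0.5)
  spec <- screen_sim_spec(96, spi_set = spi, noise_sigma = 1e-12, seed = 4)
  scr2 <- simulate_screen(spec)
  f2 <- mean(scr2$fusion$size[scr2$fusion$strain == "Q0007"])
  c2 <- mean(scr2$control_gbp$size[scr2$control_gbp$strain == "Q0007"])
  expect_equal(f2 / c2, 0.5, tolerance = 1e-9)
  expect_equal(scr2$truth$effect, 0.5)

  ## linear gradient doubling left to right: column-size ratio ~ 2
  spec3 <- screen_sim_spec(384, gradient_model = c(intercept = 1, col = 1),
                           noise_sigma = 0.05, seed = 5)
  scr3 <- simulate_screen(spec3)
  fus <- scr3$fusion
  r <- mean(fus$size[fus$col == 47]) / mean(fus$size[fus$col == 0])
  expect_equal(r, 2, tolerance = 0.1)

  ## determinism and input validation
  expect_identical(simulate_screen(spec3)$fusion, scr3$fusion)
  expect_error(screen_sim_spec(10, spi_set = data.frame(
    query = "QXXXX", target = "T01", effect = 0.5)), "unknown query")
  expect_error(screen_sim_spec(10, spi_set = data.frame(
    query = "Q0001", target = "T01", effect = 1.5)), "0, 1")
  expect_error(screen_sim_spec(10, gradient_model = c(intercept = -1)),
               "positive")
})

test_that("retest plates have the published capacity and layout", {
  truth <- data.frame(query = "Q0001", target = "T01", effect = 0.5)
  cands <- sprintf("Q%04d", 1:80)
  rt <- simulate_retest_plate(cands, truth, seed = 2)
  expect_equal(rt$n_plates, 1L)
  expect_equal(nrow(rt$fusion), 1536L)            # 80 + 16 refs, 16 reps
  expect_equal(sum(rt$fusion$is_control) / 16L, 16L)
  ## planted effect carried by fusion only
  f <- mean(rt$fusion$size[rt$fusion$strain == "Q0001"])
  ct <- mean(rt$control_target$size[rt$control_target$strain == "Q0001"])
  expect_lt(f / ct, 0.65)
  f2 <- mean(rt$fusion$size[rt$fusion$strain == "Q0002"])
  c2 <- mean(rt$control_target$size[rt$control_target$strain == "Q0002"])
  expect_equal(f2 / c2, 1, tolerance = 0.35)
  ## overflow splits across plates; single candidate fits one plate
  rt2 <- simulate_retest_plate(sprintf("Q%04d", 1:100), truth, seed = 2)
  expect_equal(rt2$n_plates, 2L)
  rt3 <- simulate_retest_plate("Q0001", truth, seed = 2)
  expect_equal(rt3$n_plates, 1L)
  expect_error(simulate_retest_plate(character(), truth), "empty")
})

test_that("annotation/network generator plants what it claims", {
  ## multinomial compartments: uniform 4 compartments, n = 400
  devs <- vapply(1:200, function(s) {
    a <- simulate_annotations(400, compartments = c(a = .25, b = .25,
                                                    c = .25, d = .25),
                              seed = s)$annotations
    max(abs(table(a$compartment) - 100))
  }, numeric(1))
  ## binomial sd ~ sqrt(400*.25*.75) = 8.7; 4 cells, 200 seeds
  expect_lt(mean(devs), 3 * 8.7)
  expect_gt(mean(devs), 2)

  ## planted module edge density ~ p_in / p_out
  sim <- simulate_annotations(300, module = 50, p_in = 0.3, p_out = 0.01,
                              seed = 7)
  mod <- sim$annotations$protein[1:50]
  inside <- sim$network$a %in% mod & sim$network$b %in% mod
  d_in <- sum(inside) / choose(50, 2)
  d_out <- sum(!inside) / (choose(300, 2) - choose(50, 2))
  expect_equal(d_in, 0.3, tolerance = 0.25)
  expect_equal(d_in / d_out, 30, tolerance = 0.5)
  expect_true(all(sim$network$a != sim$network$b))

  ## enrichment factor 1 leaves compartments exchangeable across seeds
  base <- simulate_annotations(400, spi_queries = sprintf("P%04d", 1:50),
                               enriched_compartment = "nucleus",
                               enrichment = 1, seed = 11)
  plain <- simulate_annotations(400, seed = 11)
  expect_identical(base$annotations$compartment,
                   plain$annotations$compartment)
})

test_that("focus stacks conserve planted intensity", {
  ## conservation by construction at zero noise
  fs <- focus_sim_spec(c(13, 32, 32),
                       foci = data.frame(z = 7, y = 16, x = 16,
                                         intensity = 1e4, sigma_nm = 250),
                       background = 0)
  sim <- simulate_focus_stack(fs)
  expect_equal(sum(sim$stack), 1e4, tolerance = 1e-9)
  ## zero foci -> flat background
  fs0 <- focus_sim_spec(c(5, 8, 8), background = 3)
  expect_true(all(simulate_focus_stack(fs0)$stack == 3))
  ## two separated foci -> two truth records, no warning
  fs2 <- focus_sim_spec(c(13, 48, 48),
                        foci = data.frame(z = c(7, 7), y = c(12, 36),
                                          x = c(12, 36),
                                          intensity = c(1e4, 2e4),
                                          sigma_nm = 250),
                        background = 0)
  expect_silent(sim2 <- simulate_focus_stack(fs2))
  expect_equal(nrow(sim2$truth), 2L)
  expect_false(any(sim2$truth$overlap_warning))
  ## close pair warns and is recorded
  fs3 <- focus_sim_spec(c(13, 32, 32),
                        foci = data.frame(z = c(7, 7), y = c(16, 18),
                                          x = c(16, 16),
                                          intensity = c(1e4, 1e4),
                                          sigma_nm = 250),
                        background = 0)
  expect_warning(sim3 <- simulate_focus_stack(fs3), "3 sigma")
  expect_true(all(sim3$truth$overlap_warning))
  expect_error(focus_sim_spec(c(5, 8, 8),
                              foci = data.frame(z = 99, y = 1, x = 1,
                                                intensity = 1,
                                                sigma_nm = 100)),
               "inside")
})

test_that("rendered plates match the disk-area model", {
  lay <- plate_layout("A", n_rows = 2, n_cols = 2, replicate_block = 4)
  tab <- as.data.frame(lay)
  tab$size <- ifelse(tab$row == 0 & tab$col == 1, 0, 100)
  img <- render_plate_image(tab, pitch = 30, radius_scale = 0.1)
  ## zero-size colony leaves its (top-right) cell empty
  expect_equal(sum(img[1:30, 31:60] > 100), 0)
  expect_gt(sum(img[1:30, 1:30] > 100), 0)
  ## pixel-count oracle: radius 10 disk area within 5% of pi * 100
  tab$size <- ifelse(tab$row == 0 & tab$col == 0, 1e4, 0)
  img2 <- render_plate_image(tab, pitch = 30, radius_scale = 0.1)
  expect_equal(sum(img2 > 100), pi * 100, tolerance = 0.05)
  ## radius above half pitch is rejected
  expect_error(render_plate_image(tab, pitch = 15, radius_scale = 0.1),
               "half the grid pitch")
  ## full 1536 plate has the stated extent
  full <- as.data.frame(plate_layout(sprintf("S%03d", 1:384)))
  full$size <- 60
  img3 <- render_plate_image(full, pitch = 20)
  expect_equal(dim(img3), c(32 * 20, 48 * 20))
})
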