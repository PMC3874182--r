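test_that("noiseless binding trace ramps then plateaus at one filament length", {
  sim <- simulate_binding_trace(
    noise = noise_model(sigma = 0), nucleation_times = 150,
    filament = filament_spec(700), n_filaments_max = 1, seed = 2)
  tr <- sim$trace
  # plateau: Delta L = 700 x 0.12 = 84 nm above the naked-DNA baseline
  base56 <- force_extension(56, tr$construct_bp)
  late <- tr$time >= 180 & tr$time < 240
  expect_equal(unique(round(tr$extension[late] - base56, 9)), 84)
  expect_equal(sim$truth$pause_levels, 84)
  # growth phase has the configured slope
  mid <- tr$time > 152 & tr$time < 169
  slopes <- diff(tr$extension[mid]) / tr$dt
  expect_equal(unique(round(slopes, 6)), 4)
})

test_that("noiseless traces are piecewise linear with breakpoints matching ground truth", {
  for (seed in 1:5) {
    sim <- simulate_binding_trace(noise = noise_model(sigma = 0), seed = seed,
                                  filament = filament_spec(1000))
    tr <- sim$trace
    truth <- sim$truth
    # rebuild Delta L from the ground-truth knots and compare sample by sample
    kt <- c(tr$time[1], truth$breakpoints, max(tr$time) + tr$dt)
    dl <- cumsum(c(0, truth$segment_slopes * diff(kt)))
    dl_t <- stats::approx(kt, dl, xout = tr$time, rule = 2)$y
    baseline <- force_extension(tr$force, tr$construct_bp)
    expect_equal(tr$extension, baseline + dl_t, tolerance = 1e-8)
    # pause levels are exact integer multiples of the filament extension
    if (length(truth$pause_levels))
      expect_equal(truth$pause_levels %% (1000 * 0.12),
                   rep(0, length(truth$pause_levels)))
  }
})

test_that("3'3' and 5'5' pulling below threshold never extends", {
  for (mode in c("3p3p", "5p5p")) {
    sim <- simulate_binding_trace(
      protocol = standard_binding_protocol(test_force = 52),
      kinetics = binding_kinetics(mode = mode),
      noise = noise_model(sigma = 0), seed = 8)
    base <- force_extension(sim$trace$force, sim$trace$construct_bp)
    expect_equal(sim$trace$extension, base)
    expect_equal(length(sim$truth$pause_levels), 0)
  }
})

test_that("simulation is deterministic in the seed", {
  a <- simulate_binding_trace(seed = 42)
  b <- simulate_binding_trace(seed = 42)
  c <- simulate_binding_trace(seed = 43)
  expect_identical(a$trace$extension, b$trace$extension)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$trace$extension, c$trace$extension))
})

test_that("force release unbinds non-homologous but not homologous complexes", {
  # non-homologous: terminal Delta L returns to zero in the final 40 pN phase
  sim <- simulate_binding_trace(noise = noise_model(sigma = 0),
                                nucleation_times = 130, seed = 5)
  tr <- sim$trace
  end <- tr$time > max(tr$time) - 10
  expect_equal(tr$extension[end],
               force_extension(40, tr$construct_bp) + 0 * tr$time[end])
  # homologous: the gained extension persists after the force drops
  simh <- simulate_binding_trace(
    filament = filament_spec(700, homologous = TRUE,
                             target_strand = "complementary"),
    noise = noise_model(sigma = 0), nucleation_times = 130,
    n_filaments_max = 1, seed = 5)
  trh <- simh$trace
  endh <- trh$time > max(trh$time) - 10
  expect_equal(unique(round(trh$extension[endh] -
                              force_extension(40, trh$construct_bp), 6)), 84)
})

test_that("control traces stay at baseline with sd ~ sigma", {
  prot <- standard_binding_protocol(test_force = 56)
  tr0 <- simulate_control_trace(prot, noise_model(sigma = 0), seed = 1)
  ph_base <- force_extension(tr0$force, tr0$construct_bp)
  expect_equal(tr0$extension, ph_base)
  # seeded noisy control: sample sd over 20-120 s of the high-force phase
  trn <- simulate_control_trace(prot, noise_model(sigma = 10), seed = 3)
  idx <- trn$time >= 140 & trn$time <= 240
  expect_equal(sd(trn$extension[idx]), 10, tolerance = 0.1)
  # at 58 pN the control stays near the B-form length
  tr58 <- simulate_control_trace(standard_binding_protocol(test_force = 58),
                                 noise_model(sigma = 0), seed = 1)
  expect_lt(max(tr58$extension), 1.05 * 48502 * 0.34)
})

test_that("overstretch ramp scales the nominal transition force with the bead", {
  r1 <- simulate_overstretch_ramp(bead_scale = 1, noise = noise_model(sigma = 0))
  # memoryless model: reversing the ramp gives the same curve
  expect_equal(force_extension(r1$force, r1$construct_bp),
               r1$extension)
  r2 <- simulate_overstretch_ramp(bead_scale = 1.05,
                                  noise = noise_model(sigma = 0))
  # same true-force curve, nominal force axis divided by the bead scale
  expect_equal(r2$force * 1.05, r1$force, tolerance = 1e-9)
  expect_equal(r2$extension, r1$extension)
})

test_that("simulate_cohort expands, seeds and serialises reproducibly", {
  cfg <- list(list(type = "binding", mode = c("3p5p", "3p3p", "5p5p"),
                   test_force = c(52, 56), filament_nt = 700, n = 5))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  e1 <- simulate_cohort(cfg, seed = 9, out_dir = dir1,
                        noise = noise_model(sigma = 5))
  e2 <- simulate_cohort(cfg, seed = 9, out_dir = dir2,
                        noise = noise_model(sigma = 5))
  expect_length(e1, 30)
  expect_length(list.files(dir1, pattern = "\\.csv$"), 30)
  # byte-identical sidecars and traces on rerun with the same master seed
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_error(simulate_cohort(list(), seed = 1), "empty")
})
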