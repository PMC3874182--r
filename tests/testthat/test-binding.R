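test_that("delta_extension is zero for controls and exact for full binding", {
  # noiseless control
  ctl <- simulate_control_trace(standard_binding_protocol(56),
                                noise_model(sigma = 0), seed = 1)
  expect_equal(delta_extension(ctl)$delta_L, 0, tolerance = 1e-9)
  # one fully bound 700-nt filament: Delta L = 84 nm
  sim <- simulate_binding_trace(noise = noise_model(sigma = 0),
                                nucleation_times = 130, n_filaments_max = 1,
                                seed = 1)
  expect_equal(delta_extension(sim$trace)$delta_L, 84, tolerance = 1e-9)
  # window outside the high-force phase is an error
  expect_error(delta_extension(sim$trace, window = c(100, 130)),
               "outside the high-force phase")
})

test_that("noisy control cohorts have mean Delta L consistent with zero", {
  dl <- vapply(1:12, function(s)
    delta_extension(simulate_control_trace(
      standard_binding_protocol(56), noise_model(sigma = 10),
      seed = 100 + s))$delta_L, numeric(1))
  n_eff <- 75  # samples averaged per window
  expect_lt(abs(mean(dl)), 3 * 10 / sqrt(n_eff * length(dl) / 2))
})

test_that("detect_pauses finds plateaus and ignores pure ramps", {
  # plateau at 84 nm
  sim <- simulate_binding_trace(noise = noise_model(sigma = 0),
                                nucleation_times = 130, n_filaments_max = 1,
                                seed = 1)
  seg <- segment_trace(sim$trace)
  pl <- detect_pauses(seg, sim$trace)
  expect_equal(nrow(pl), 1)
  # the 0.5 s overlap lets a couple of growth samples into the plateau
  # segment, so level and slope are near-exact rather than exact
  expect_lt(abs(pl$level - 84), 0.1)
  expect_lt(abs(pl$slope), 0.01)
  # ramp-only trace: no pause
  ex <- simulate_exchange_trace(0.5, force_protocol(140, 25),
                                noise_model(sigma = 0), seed = 1)
  segr <- segment_trace(ex$trace)
  expect_equal(nrow(detect_pauses(segr, ex$trace,
                                  baseline = force_extension(25, 48502))), 0)
  # two sequential filaments: levels at 84 and 168
  sim2 <- simulate_binding_trace(noise = noise_model(sigma = 0),
                                 nucleation_times = c(125, 165),
                                 n_filaments_max = 2, seed = 1)
  pl2 <- detect_pauses(segment_trace(sim2$trace), sim2$trace)
  expect_equal(sort(round(pl2$level)), c(84, 168))
})

test_that("pause_histogram locates cohort peaks within a bin", {
  # single-level cohort
  one <- data.frame(level = rep(84, 10) + rnorm(10, 0, 1), duration = 30)
  h1 <- pause_histogram(one)
  expect_length(h1$peaks, 1)
  expect_lt(abs(h1$peaks - 84), 10)
  # three levels near {84, 168, 252}, sigma 5, n = 60
  set.seed(33)
  lv <- rep(c(84, 168, 252), each = 20) + rnorm(60, 0, 5)
  h3 <- pause_histogram(data.frame(level = lv, duration = 20))
  expect_length(h3$peaks, 3)
  expect_true(all(abs(sort(h3$peaks) - c(84, 168, 252)) <= 10))
  # oversized bins merge neighbouring peaks (documented failure mode)
  hwide <- pause_histogram(data.frame(level = lv, duration = 20),
                           bin_width = 120)
  expect_lt(length(hwide$peaks), 3)
})

test_that("ext_per_nt converts peak levels through integer multiples", {
  e1 <- ext_per_nt(84, 700)
  expect_equal(e1$value, 0.12)
  expect_equal(e1$assignment$k, 1)
  e2 <- ext_per_nt(c(84, 168), 700)
  expect_equal(e2$value, 0.12)
  expect_equal(e2$sd, 0)
  expect_equal(e2$assignment$k, c(1, 2))
  expect_error(ext_per_nt(numeric(0), 700), "no assignable peaks")
})

test_that("ext_per_nt recovery works across generating values", {
  for (g in c(0.08, 0.12, 0.17)) {
    cfg <- list(list(type = "binding", filament_nt = 700, test_force = 56,
                     n = 6))
    entries <- simulate_cohort(cfg, seed = round(1000 * g))
    # regenerate with the target geometry
    entries <- lapply(entries, function(e) {
      simulate_binding_trace(
        filament = filament_spec(700, ext_per_nt = g),
        noise = noise_model(sigma = 10), seed = e$seed)
    })
    pl <- do.call(rbind, lapply(entries, function(e)
      detect_pauses(segment_trace(e$trace), e$trace)))
    est <- ext_per_nt(pause_histogram(pl)$peaks, 700)
    expect_lt(abs(est$value - g), 0.01)
  }
})

test_that("coverage_fraction reproduces the incomplete-coverage arithmetic", {
  expect_equal(coverage_fraction(0.17)$fraction, 1)
  expect_equal(coverage_fraction(0.12)$fraction, 0.12 / 0.17, tolerance = 1e-12)
  expect_equal(round(100 * coverage_fraction(0.12)$fraction, 1), 70.6)
  expect_equal(coverage_fraction(0.085)$fraction, 0.5)
  # scale consistency
  expect_equal(coverage_fraction(0.24, reference_ext = 0.34)$fraction,
               coverage_fraction(0.12)$fraction)
  expect_error(coverage_fraction(-1), "positive")
  expect_error(coverage_fraction(0.1, reference_ext = 0), "positive")
})

test_that("cohort_summary groups by mode and force with count conservation", {
  summaries <- list()
  for (m in c("3p5p", "control")) for (f in c(52, 56)) for (r in 1:3)
    summaries[[length(summaries) + 1]] <-
      structure(list(delta_L = rnorm(1), force = f, mode = m),
                class = "extension_summary")
  tab <- cohort_summary(summaries, force_bins = c(50, 54, 58))
  expect_equal(sum(tab$n), length(summaries))
  expect_equal(nrow(tab), 4)
  # single-trace cells flag sd as NA
  tab1 <- cohort_summary(summaries[1], force_bins = c(50, 54))
  expect_true(is.na(tab1$sd_delta_L))
})
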