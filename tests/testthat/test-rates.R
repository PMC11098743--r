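# Rate estimation: initial slopes, windows, pools and turnover.

test_that("a perfect line returns its slope with zero standard error", {
  # 2 pmol/s over 1e6 cells -> 120 pmol/min per 1e6 cells
  tp <- c(0, 5, 10, 20)
  ion <- cbind(0, 0, 2 * tp)  # heavy channel M+2
  s <- isotopologue_series("Gly", c(C = 2, H = 5, N = 1, O = 2), tp, ion,
                           norvaline = rep(1, 4), n_cells = 1e6)
  s$units <- "pmol"
  r <- import_rate(s, window = c(0, 20))
  expect_equal(r$rate, 120)
  expect_equal(r$se, 0, tolerance = 1e-9)
  expect_equal(r$r_squared, 1)
})

test_that("the simulated labelling curve matches an ODE integration oracle", {
  skip_if_not_installed("deSolve")
  J <- 60; P <- 600
  tt <- tracer_truth(J_in = J, P = P, noise_cv = 0, amino_acid = "Gln",
                     fragment_formula = "C5H10N2O3")
  tp <- c(0, 5, 10, 20, 30, 40, 100, 250)
  s <- simulate_tracer(tt, tp, seed = 1)
  q <- absolute_quantify(
    internal_standard_correct(natural_abundance_correct(s)),
    fit_standard_curve(simulate_standards("Gln")))
  heavy <- q$ion_counts[, ncol(q$ion_counts)] / 0.64  # per 1e6 cells
  ode_out <- deSolve::ode(c(H = 0), tp / 60,
                          function(t, y, p) list(p$k * (p$P - y[1])),
                          list(k = J / P, P = P))
  expect_equal(unname(heavy), unname(ode_out[, "H"]), tolerance = 1e-6)
})

test_that("initial-slope regression recovers the import flux when kt is small", {
  # k * t_max = 0.1/min * (40/60) min ~ 0.067: slope within 5% of J_in
  tt <- tracer_truth(J_in = 60, P = 600, noise_cv = 0, amino_acid = "Val",
                     fragment_formula = "C5H11NO2")
  s <- simulate_tracer(tt, c(0, 5, 10, 20, 30, 40, 100, 250), seed = 1)
  q <- absolute_quantify(
    steady_state_tic_correct(internal_standard_correct(
      natural_abundance_correct(s))),
    fit_standard_curve(simulate_standards("Val")))
  r <- import_rate(q)  # Val default window 0-40 s
  expect_equal(r$window, c(0, 40))
  expect_lt(abs(r$rate - 60) / 60, 0.05)
})

test_that("the default window schedule is applied per amino acid", {
  w <- default_import_windows()
  expect_equal(unname(w["Phe"]), 10)
  expect_equal(unname(w["Leu"]), 20)
  expect_equal(unname(w["Gln"]), 100)
  tt <- tracer_truth(J_in = 300, P = 400, noise_cv = 0, amino_acid = "Phe",
                     fragment_formula = "C9H11NO2")
  s <- simulate_tracer(tt, c(0, 5, 10, 20, 30, 40, 100, 250), seed = 2)
  q <- absolute_quantify(
    internal_standard_correct(natural_abundance_correct(s)),
    fit_standard_curve(simulate_standards("Phe")))
  r <- import_rate(q)
  expect_equal(r$window, c(0, 10))
  expect_equal(r$n, 3)  # 0, 5, 10 s
})

test_that("constant and linearly declining medium give 0 and 1 pmol/min", {
  tp <- c(0, 10, 20, 30)  # minutes
  flat <- isotopologue_series("Ser", c(C = 3, H = 7, N = 1, O = 3), tp,
                              cbind(rep(500, 4), 0, 0, 0),
                              norvaline = rep(1, 4),
                              assay_kind = "consumption", n_cells = 1e6)
  expect_equal(consumption_rate(flat)$rate, 0)
  dec <- isotopologue_series("Ser", c(C = 3, H = 7, N = 1, O = 3), tp,
                             cbind(500 - tp, 0, 0, 0), norvaline = rep(1, 4),
                             assay_kind = "consumption", n_cells = 1e6)
  expect_equal(consumption_rate(dec)$rate, 1)
})

test_that("secreted amino acids yield negative consumption", {
  # export exceeding import: medium levels rise
  tt <- tracer_truth(J_in = 20, J_out = 80, P = 500, noise_cv = 0,
                     amino_acid = "Asn", fragment_formula = "C4H8N2O3")
  s <- simulate_tracer(tt, c(0, 60, 120, 180, 240),
                       assay_kind = "consumption", seed = 3)
  q <- absolute_quantify(
    volume_correct(internal_standard_correct(natural_abundance_correct(s))),
    fit_standard_curve(simulate_standards("Asn")))
  r <- consumption_rate(q)
  expect_equal(r$rate, -60, tolerance = 1e-6)
})

test_that("export assays recover the efflux from labelled medium build-up", {
  tt <- tracer_truth(J_in = 100, J_out = 40, P = 500, noise_cv = 0,
                     amino_acid = "Ala", fragment_formula = "C3H7NO2")
  s <- simulate_tracer(tt, c(0, 5, 10, 20, 30, 40, 100),
                       assay_kind = "export", seed = 4)
  q <- absolute_quantify(
    internal_standard_correct(natural_abundance_correct(s)),
    fit_standard_curve(simulate_standards("Ala")))
  r <- export_rate(q, window = c(0, 100))
  expect_equal(r$rate, 40, tolerance = 1e-6)
})

test_that("intracellular level is the mean total pool per 1e6 cells", {
  tp <- c(0, 1, 2)
  ion <- rbind(c(100, 0, 50), c(80, 0, 70), c(60, 0, 90))
  s <- isotopologue_series("Gly", c(C = 2, H = 5, N = 1, O = 2), tp, ion,
                           norvaline = rep(1, 3), n_cells = 1e6)
  expect_equal(intracellular_level(s), 150)
  # varying totals: plain arithmetic mean
  ion2 <- rbind(c(100, 0, 0), c(200, 0, 0), c(300, 0, 0))
  s2 <- isotopologue_series("Gly", c(C = 2, H = 5, N = 1, O = 2), tp, ion2,
                            norvaline = rep(1, 3), n_cells = 1e6)
  expect_equal(intracellular_level(s2), 200)
})

test_that("pool turnover is import over level and zero for zero import", {
  expect_equal(pool_turnover(100, 100), 1)
  expect_equal(pool_turnover(0, 50), 0)
  expect_error(pool_turnover(10, 0), class = "screenflux_invalid_parameter")
  # in noiseless steady-state simulation the identity k = J_in / P holds
  tt <- tracer_truth(J_in = 60, P = 600, noise_cv = 0, amino_acid = "Thr",
                     fragment_formula = "C4H9NO3")
  s <- simulate_tracer(tt, c(0, 1, 2, 3, 4, 5, 6), seed = 5)
  q <- absolute_quantify(
    internal_standard_correct(natural_abundance_correct(s)),
    fit_standard_curve(simulate_standards("Thr")))
  rate <- import_rate(q, window = c(0, 6))
  level <- intracellular_level(q)
  expect_equal(level, 600, tolerance = 1e-6)
  # k * t_max = 0.01: residual curvature bias is ~0.5%
  expect_equal(pool_turnover(rate, level), 0.1, tolerance = 0.01)
  # the identity among the package's own outputs is exact
  expect_identical(pool_turnover(rate, level) * level, rate$rate)
})

test_that("regressions demand at least three points in the window", {
  tp <- c(0, 5, 10, 20)
  s <- isotopologue_series("Gly", c(C = 2, H = 5, N = 1, O = 2), tp,
                           cbind(1, 0, 2 * tp), norvaline = rep(1, 4))
  expect_error(import_rate(s, window = c(0, 6)),
               class = "screenflux_insufficient_points")
})
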