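# Internal-standard, TIC, volume and absolute-quantification steps.

mk_series <- function(ion, norv = rep(100, nrow(ion)), kind = "import",
                      tp = seq_len(nrow(ion)) - 1, volumes = NULL) {
  isotopologue_series("Gly", c(C = 2, H = 5, N = 1, O = 2), tp, ion, norv,
                      assay_kind = kind, sampling_volumes = volumes)
}

test_that("constant norvaline leaves the data untouched", {
  ion <- matrix(1:6, 2, 3)
  s <- internal_standard_correct(mk_series(ion))
  expect_equal(unname(s$ion_counts), matrix(1:6, 2, 3))
})

test_that("norvaline factors are signal over mean", {
  # norvaline (100, 200): factors (2/3, 4/3)
  ion <- rbind(c(30, 0, 0), c(40, 0, 0))
  s <- internal_standard_correct(mk_series(ion, norv = c(100, 200)))
  expect_equal(unname(s$ion_counts[1, 1]), 30 / (2 / 3))
  expect_equal(unname(s$ion_counts[2, 1]), 40 / (4 / 3))
  expect_equal(var(s$norvaline), 0)
  expect_error(internal_standard_correct(mk_series(ion, norv = c(0, 100))),
               class = "screenflux_degenerate_standard")
})

test_that("TIC correction divides by the per-sample factor", {
  # constant TIC: identity under both variants
  flat <- rbind(c(50, 30, 20), c(50, 30, 20))
  expect_equal(steady_state_tic_correct(mk_series(flat))$ion_counts,
               mk_series(flat)$ion_counts)
  expect_equal(steady_state_tic_correct(mk_series(flat), "regression")$ion_counts,
               mk_series(flat)$ion_counts)
  # TIC (90, 110), mean 100: factors (0.9, 1.1)
  drift <- rbind(c(90, 0, 0), c(110, 0, 0))
  out <- steady_state_tic_correct(mk_series(drift))
  expect_equal(out$ion_counts[, 1], c(100, 100))
  expect_error(steady_state_tic_correct(mk_series(rbind(c(0, 0, 0), c(1, 0, 0)))),
               class = "screenflux_degenerate_sample")
})

test_that("linear TIC drift is removed exactly only by the regression variant", {
  tp <- c(0, 1, 2, 3)
  tic <- 100 + 10 * tp
  ion <- cbind(tic, 0, 0)
  s <- mk_series(ion, tp = tp)
  reg <- steady_state_tic_correct(s, "regression")
  expect_equal(unname(reg$ion_counts[, 1]), tic)  # points already on the line
  rtm <- steady_state_tic_correct(s, "ratio_to_mean")
  expect_equal(unname(rtm$ion_counts[, 1]), rep(mean(tic), 4))
  expect_false(isTRUE(all.equal(rtm$ion_counts[, 1], reg$ion_counts[, 1])))
})

test_that("correction order only matters when the internal standard drifts", {
  set.seed(12)
  ion <- matrix(runif(12, 50, 150), 4, 3)
  # constant norvaline: the internal-standard step is the identity, so
  # the two orders coincide exactly
  flat_norv <- rep(100, 4)
  a <- steady_state_tic_correct(internal_standard_correct(mk_series(ion, flat_norv)))
  b <- internal_standard_correct(steady_state_tic_correct(mk_series(ion, flat_norv)))
  expect_equal(a$ion_counts, b$ion_counts, tolerance = 1e-12)
  # drifting norvaline: both row-multiplicative corrections change the
  # other's factors, so the order is part of the method (fixed here as
  # internal standard first, then TIC)
  norv <- runif(4, 80, 120)
  a2 <- steady_state_tic_correct(internal_standard_correct(mk_series(ion, norv)))
  b2 <- internal_standard_correct(steady_state_tic_correct(mk_series(ion, norv)))
  expect_false(isTRUE(all.equal(a2$ion_counts, b2$ion_counts)))
})

test_that("volume correction reconstructs whole-well amounts", {
  # zero withdrawal: identity
  ion <- rbind(c(100, 0, 0), c(100, 0, 0))
  s0 <- mk_series(ion, kind = "consumption", volumes = c(0, 0))
  expect_equal(volume_correct(s0)$ion_counts, s0$ion_counts)
  # constant-concentration medium with 15 ul draws from 300 ul stays flat
  tp <- 0:3
  conc_signal <- rep(120, 4)
  s <- mk_series(cbind(conc_signal, 0, 0), kind = "consumption", tp = tp,
                 volumes = rep(15, 4))
  out <- volume_correct(s, initial_volume = 300, per_sample_volume = 15)
  expect_equal(unname(out$ion_counts[, 1]), rep(120, 4))
  # over-withdrawal is rejected
  s_bad <- mk_series(cbind(conc_signal, 0, 0), kind = "consumption", tp = tp,
                     volumes = rep(120, 4))
  expect_error(volume_correct(s_bad, initial_volume = 300),
               class = "screenflux_invalid_schedule")
})

test_that("volume-corrected declining medium recovers the true consumption", {
  # simulated net uptake 60 pmol/min by 0.64e6 cells, hourly draws
  tt <- tracer_truth(J_in = 100, J_out = 40, P = 500, noise_cv = 0,
                     amino_acid = "Gln", fragment_formula = "C5H10N2O3")
  s <- simulate_tracer(tt, c(0, 60, 120, 180, 240),
                       assay_kind = "consumption", seed = 1)
  q <- absolute_quantify(
    volume_correct(internal_standard_correct(natural_abundance_correct(s))),
    fit_standard_curve(simulate_standards("Gln")))
  r <- consumption_rate(q)
  expect_equal(r$rate, 60, tolerance = 1e-6)
})

test_that("standard curves convert ion counts to pmol with norvaline scaling", {
  curve <- fit_standard_curve(simulate_standards("Gly", pmol = c(0, 5, 10, 20),
                                                 response_factor = 50))
  expect_equal(curve$slope, 50)
  expect_equal(curve$intercept, 0, tolerance = 1e-9)
  # 500 counts at slope 50, intercept 0, norvaline ratio 1 -> 10 pmol
  ion <- rbind(c(500, 0, 0), c(500, 0, 0))
  q <- absolute_quantify(mk_series(ion, norv = c(1e5, 1e5)), curve)
  expect_equal(unname(q$ion_counts[, 1]), c(10, 10))
  expect_equal(q$units, "pmol")
  # doubling the sample norvaline halves the pmol
  q2 <- absolute_quantify(mk_series(ion, norv = c(2e5, 2e5)), curve)
  expect_equal(unname(q2$ion_counts[, 1]), c(5, 5))
  # a standard point maps back to its own pmol
  q3 <- absolute_quantify(mk_series(rbind(c(50 * 20, 0, 0), c(50 * 20, 0, 0)),
                                    norv = c(1e5, 1e5)), curve)
  expect_equal(unname(q3$ion_counts[, 1]), c(20, 20))
})

test_that("quantification validates its inputs", {
  curve <- fit_standard_curve(simulate_standards("Leu"))
  s <- mk_series(rbind(c(1, 0, 0), c(1, 0, 0)))
  expect_error(absolute_quantify(s, curve), class = "screenflux_lookup_error")
  expect_error(fit_standard_curve(data.frame(amino_acid = "X", pmol = 1,
                                             ion_counts = 1, norvaline = 1)),
               class = "screenflux_invalid_spec")
})
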