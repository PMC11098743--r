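# Isotopologue time series container, normalization steps and rate
# estimation for amino-acid transport assays.

#' Construct an isotopologue time series
#'
#' Per-timepoint isotopologue ion counts for one amino-acid fragment,
#' with the norvaline internal-standard channel alongside.
#'
#' @param amino_acid identifier, e.g. "Leu".
#' @param fragment_formula fragment formula (string such as
#'   "C11H26N1O2Si2" or a named atom-count vector).
#' @param timepoints numeric, strictly increasing; seconds for
#'   import/export assays, minutes for consumption assays.
#' @param ion_counts matrix timepoint x isotopologue (columns M0..Mn);
#'   n must equal the label-element atom count of the fragment.
#' @param norvaline internal-standard ion counts per timepoint.
#' @param assay_kind "import", "consumption" or "export".
#' @param time_unit "s" or "min"; defaults by assay kind.
#' @param sampling_volumes microlitres withdrawn at each timepoint
#'   (consumption assays).
#' @param n_cells effective cells in the assay (default 0.64e6: 0.8e6
#'   monolayer minus an estimated 20% loss during washes).
#' @return An `isotopologue_series`.
#' @export
isotopologue_series <- function(amino_acid, fragment_formula, timepoints,
                                ion_counts, norvaline,
                                assay_kind = c("import", "consumption", "export"),
                                time_unit = NULL, sampling_volumes = NULL,
                                n_cells = 0.64e6) {
  assay_kind <- match.arg(assay_kind)
  if (is.null(time_unit)) {
    time_unit <- if (assay_kind == "consumption") "min" else "s"
  }
  ion_counts <- as.matrix(ion_counts)
  if (any(diff(timepoints) <= 0) || any(timepoints < 0)) {
    sf_stop("timepoints must be non-negative and strictly increasing",
            "screenflux_invalid_parameter")
  }
  if (nrow(ion_counts) != length(timepoints) ||
      length(norvaline) != length(timepoints)) {
    sf_stop("ion_counts rows and norvaline must match timepoints",
            "screenflux_invalid_parameter")
  }
  if (any(ion_counts < 0)) {
    sf_stop("ion counts must be >= 0", "screenflux_invalid_parameter")
  }
  n_label <- unname(parse_formula(fragment_formula)["C"])
  if (!is.na(n_label) && ncol(ion_counts) != n_label + 1L) {
    sf_stop("isotopologue vector length must be label capacity + 1",
            "screenflux_invalid_parameter")
  }
  colnames(ion_counts) <- paste0("M", seq_len(ncol(ion_counts)) - 1L)
  structure(list(amino_acid = amino_acid,
                 fragment_formula = fragment_formula,
                 timepoints = timepoints, ion_counts = ion_counts,
                 norvaline = norvaline, assay_kind = assay_kind,
                 time_unit = time_unit, sampling_volumes = sampling_volumes,
                 n_cells = n_cells, units = "ion_counts"),
            class = "isotopologue_series")
}

#' @export
print.isotopologue_series <- function(x, ...) {
  cat(sprintf("isotopologue_series: %s (%s), %d timepoints (%s), M0..M%d [%s]\n",
              x$amino_acid, x$assay_kind, length(x$timepoints), x$time_unit,
              ncol(x$ion_counts) - 1L, x$units))
  invisible(x)
}

#' Internal-standard (norvaline) correction
#'
#' Divides each timepoint's ion counts by the ratio of its norvaline
#' signal to the mean norvaline signal over all timepoints; the
#' corrected norvaline channel is constant by construction.
#'
#' @param series an `isotopologue_series`.
#' @return corrected series.
#' @export
internal_standard_correct <- function(series) {
  stopifnot(inherits(series, "isotopologue_series"))
  if (any(series$norvaline <= 0)) {
    sf_stop("norvaline signal must be > 0 at every timepoint",
            "screenflux_degenerate_standard")
  }
  f <- series$norvaline / mean(series$norvaline)
  series$ion_counts <- series$ion_counts / f
  series$norvaline <- series$norvaline / f
  series
}

#' Steady-state total-ion-count correction
#'
#' Under steady state the total ion count (TIC, excluding the internal
#' standard) is constant over the assay. `ratio_to_mean` divides each
#' timepoint by TIC_t / mean(TIC) (import assays); `regression` divides
#' by TIC_t / fitted TIC(t) from a linear fit over the time course
#' (consumption assays, where withdrawal makes the raw TIC drift
#' linearly rather than randomly).
#'
#' @param series an `isotopologue_series`.
#' @param variant "ratio_to_mean" or "regression".
#' @return corrected series.
#' @export
steady_state_tic_correct <- function(series,
                                     variant = c("ratio_to_mean", "regression")) {
  stopifnot(inherits(series, "isotopologue_series"))
  variant <- match.arg(variant)
  tic <- rowSums(series$ion_counts)
  if (any(tic <= 0)) {
    sf_stop("total ion count must be > 0 at every timepoint",
            "screenflux_degenerate_sample")
  }
  target <- if (variant == "ratio_to_mean") {
    rep(mean(tic), length(tic))
  } else {
    fit <- ols_line(series$timepoints, tic)
    fit$intercept + fit$slope * series$timepoints
  }
  series$ion_counts <- series$ion_counts * (target / tic)
  series
}

#' Volume correction for consumption assays
#'
#' Medium sampling shrinks the well volume (e.g. 15 ul drawn from
#' 300 ul at each timepoint), so the measured concentration no longer
#' tracks the amount consumed. This correction converts
#' concentration-proportional signals to the whole-well equivalent:
#' signal times the remaining-volume fraction, plus the running tally of
#' analyte already withdrawn. On constant-concentration medium the
#' corrected trace is exactly flat, and its slope equals minus the
#' consumption rate.
#'
#' @param series a consumption-kind `isotopologue_series`.
#' @param initial_volume starting medium volume (ul, default 300).
#' @param per_sample_volume volume withdrawn at each timepoint (ul,
#'   default 15); overridden by the series' `sampling_volumes` if set.
#' @return corrected series.
#' @export
volume_correct <- function(series, initial_volume = 300,
                           per_sample_volume = 15) {
  stopifnot(inherits(series, "isotopologue_series"))
  k <- length(series$timepoints)
  draws <- series$sampling_volumes
  if (is.null(draws)) draws <- rep(per_sample_volume, k)
  if (length(draws) != k) {
    sf_stop("one sampling volume per timepoint required",
            "screenflux_invalid_schedule")
  }
  v_before <- initial_volume - c(0, cumsum(draws))[seq_len(k)]
  if (any(v_before <= 0) || any(draws > v_before)) {
    sf_stop("cumulative withdrawal exceeds the available volume",
            "screenflux_invalid_schedule")
  }
  counts <- series$ion_counts
  withdrawn <- apply(counts * (draws / initial_volume), 2,
                     function(col) c(0, cumsum(col))[seq_len(k)])
  series$ion_counts <- counts * (v_before / initial_volume) + withdrawn
  series$norvaline <- series$norvaline  # internal standard already spiked per sample
  series$volume_corrected <- TRUE
  series
}

#' Fit standard curves for absolute quantification
#'
#' Unweighted ordinary least squares of ion counts against pmol for
#' each amino acid in a dilution series, retaining the mean norvaline
#' signal of the standards.
#'
#' @param standards data.frame with columns `amino_acid`, `pmol`,
#'   `ion_counts`, `norvaline`; >= 3 dilution points per amino acid.
#' @return A `standard_curve` data.frame: `amino_acid`, `slope`,
#'   `intercept`, `norvaline_mean`, `n`, `r_squared`.
#' @export
fit_standard_curve <- function(standards) {
  need <- c("amino_acid", "pmol", "ion_counts", "norvaline")
  if (!all(need %in% names(standards))) {
    sf_stop(paste("standards need columns:", paste(need, collapse = ", ")),
            "screenflux_invalid_spec")
  }
  rows <- lapply(split(standards, standards$amino_acid), function(d) {
    if (nrow(d) < 3L) {
      sf_stop(sprintf("amino acid %s: need >= 3 dilution points",
                      d$amino_acid[1]), "screenflux_invalid_spec")
    }
    fit <- ols_line(d$pmol, d$ion_counts)
    if (fit$slope <= 0) {
      sf_stop(sprintf("amino acid %s: non-positive standard-curve slope",
                      d$amino_acid[1]), "screenflux_invalid_spec")
    }
    data.frame(amino_acid = d$amino_acid[1], slope = fit$slope,
               intercept = fit$intercept, norvaline_mean = mean(d$norvaline),
               n = fit$n, r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("standard_curve", "data.frame")
  out
}

#' Convert ion counts to pmol via a standard curve
#'
#' Total pmol per timepoint is `(TIC - intercept) / slope *
#' (norvaline_standard_mean / norvaline_sample_mean)`, distributed over
#' isotopologue channels in proportion to their ion counts (the curve is
#' linear, so channel fractions are preserved). Negative totals are
#' clipped to zero with a warning.
#'
#' @param series an `isotopologue_series` (ion-count units).
#' @param curve a `standard_curve` covering the series' amino acid.
#' @return the series with `ion_counts` in pmol and `units` = "pmol".
#' @export
absolute_quantify <- function(series, curve) {
  stopifnot(inherits(series, "isotopologue_series"),
            inherits(curve, "standard_curve"))
  row <- curve[curve$amino_acid == series$amino_acid, , drop = FALSE]
  if (nrow(row) != 1L) {
    sf_stop(sprintf("amino acid %s not in standard curve", series$amino_acid),
            "screenflux_lookup_error")
  }
  norv_ratio <- row$norvaline_mean / mean(series$norvaline)
  tic <- rowSums(series$ion_counts)
  total_pmol <- (tic - row$intercept) / row$slope * norv_ratio
  if (any(total_pmol < 0)) {
    warning(sprintf("%s: %d timepoint(s) below the curve intercept; clipped to 0",
                    series$amino_acid, sum(total_pmol < 0)))
    total_pmol <- pmax(total_pmol, 0)
  }
  frac <- series$ion_counts / ifelse(tic > 0, tic, 1)
  series$ion_counts <- frac * total_pmol
  series$units <- "pmol"
  series
}

#' Default per-amino-acid import regression windows (seconds)
#'
#' Initial-slope windows chosen so that labelling stays approximately
#' linear: 0-100 s for slowly exchanging pools (Asn, Asp, Gln, Glu,
#' Pro), 0-40 s for Arg, Gly, His, Ile, Lys, Ser, Thr, Val, 0-20 s for
#' Leu and Tyr, and 0-10 s for the fastest, Phe.
#'
#' @return named numeric vector: upper window bound per amino acid.
#' @export
default_import_windows <- function() {
  c(Asn = 100, Asp = 100, Gln = 100, Glu = 100, Pro = 100,
    Arg = 40, Gly = 40, His = 40, Ile = 40, Lys = 40, Ser = 40,
    Thr = 40, Val = 40,
    Leu = 20, Tyr = 20,
    Phe = 10)
}

# Shared slope machinery for the three rate estimators.
rate_from_slope <- function(series, values, window, n_cells, sign = 1) {
  t <- series$timepoints
  if (is.null(window)) window <- c(0, max(t))
  if (length(window) == 1L) window <- c(0, window)
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 3L) {
    sf_stop("fewer than 3 timepoints in the regression window",
            "screenflux_insufficient_points")
  }
  fit <- ols_line(t[keep], values[keep])
  per_min <- if (series$time_unit == "s") 60 else 1
  cells <- if (is.null(n_cells)) series$n_cells else n_cells
  scale <- sign * per_min / (cells / 1e6)
  structure(list(amino_acid = series$amino_acid,
                 rate = fit$slope * scale,
                 se = fit$se * abs(scale),
                 window = window, n = fit$n, r_squared = fit$r_squared,
                 units = "pmol/min per 1e6 cells"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.3g %s (window %g-%g, n=%d, R2=%.3f)\n",
              x$amino_acid, x$rate, x$se, x$units, x$window[1], x$window[2],
              x$n, x$r_squared))
  invisible(x)
}

# Heavy-labelled amount per timepoint. Medium amino acids are uniformly
# fully labelled, so after abundance correction the label lives in the
# M+n channel; intermediate channels are zero in expectation and only
# carry correction noise scaled by the (large) unlabelled pool. The
# fully-labelled channel is therefore the default readout; the channel
# sum is kept for partially-labelled designs.
heavy_amount <- function(series, heavy = c("fully_labelled", "all_labelled")) {
  heavy <- match.arg(heavy)
  n <- ncol(series$ion_counts)
  if (heavy == "fully_labelled") {
    series$ion_counts[, n]
  } else {
    rowSums(series$ion_counts[, -1, drop = FALSE])
  }
}

#' Import rate from the initial labelling slope
#'
#' Ordinary least squares of the heavy-labelled amount against time
#' within the per-amino-acid window. The slope is reported as pmol per
#' minute per 1e6 cells.
#'
#' @param series a corrected, pmol-quantified import
#'   `isotopologue_series`.
#' @param window regression window in seconds, `c(lo, hi)` or a single
#'   upper bound; defaults to the amino acid's entry in
#'   [default_import_windows()].
#' @param n_cells effective cell number; defaults to the series' value.
#' @param heavy "fully_labelled" (default; all-or-none labelling puts
#'   the tracer in the M+n channel after abundance correction) or
#'   "all_labelled" (sum of M+1..M+n, for partially-labelled designs).
#' @return A `rate_estimate` (rate, se, window, n, r_squared).
#' @export
import_rate <- function(series, window = NULL, n_cells = NULL,
                        heavy = c("fully_labelled", "all_labelled")) {
  stopifnot(inherits(series, "isotopologue_series"))
  if (is.null(window)) {
    w <- default_import_windows()[series$amino_acid]
    window <- if (is.na(w)) NULL else unname(w)
  }
  rate_from_slope(series, heavy_amount(series, match.arg(heavy)),
                  window, n_cells, sign = 1)
}

#' Consumption rate from the medium time course
#'
#' Slope of total (labelled + unlabelled) medium amino acid over time;
#' positive rates mean net consumption (decreasing medium levels),
#' negative rates mean net secretion.
#'
#' @param series a corrected consumption `isotopologue_series` (pmol).
#' @param window optional regression window (defaults to all points).
#' @param n_cells effective cell number.
#' @return A `rate_estimate`.
#' @export
consumption_rate <- function(series, window = NULL, n_cells = NULL) {
  stopifnot(inherits(series, "isotopologue_series"))
  total <- rowSums(series$ion_counts)
  rate_from_slope(series, total, window, n_cells, sign = -1)
}

#' Export rate from labelled amino acid released into the medium
#'
#' Slope of the heavy-labelled medium amount over time; positive rates
#' mean release.
#'
#' @inheritParams consumption_rate
#' @inheritParams import_rate
#' @return A `rate_estimate`.
#' @export
export_rate <- function(series, window = NULL, n_cells = NULL,
                        heavy = c("fully_labelled", "all_labelled")) {
  stopifnot(inherits(series, "isotopologue_series"))
  rate_from_slope(series, heavy_amount(series, match.arg(heavy)),
                  window, n_cells, sign = 1)
}

#' Intracellular amino acid level
#'
#' Mean over timepoints of the total (unlabelled + heavy-labelled)
#' amount, per 1e6 cells.
#'
#' @param series a pmol-quantified `isotopologue_series`.
#' @param n_cells effective cell number; defaults to the series' value.
#' @return level in pmol per 1e6 cells.
#' @export
intracellular_level <- function(series, n_cells = NULL) {
  stopifnot(inherits(series, "isotopologue_series"))
  cells <- if (is.null(n_cells)) series$n_cells else n_cells
  mean(rowSums(series$ion_counts)) / (cells / 1e6)
}

#' Pool turnover constant
#'
#' k_turn = import rate / intracellular level, in 1/min: the rate at
#' which the free intracellular pool is replaced by import.
#'
#' @param import a `rate_estimate` from [import_rate()].
#' @param level intracellular level (pmol per 1e6 cells).
#' @return k_turn in 1/min.
#' @export
pool_turnover <- function(import, level) {
  if (!is.numeric(level) || level <= 0) {
    sf_stop("intracellular level must be > 0", "screenflux_invalid_parameter")
  }
  rate <- if (inherits(import, "rate_estimate")) import$rate else import
  rate / level
}
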