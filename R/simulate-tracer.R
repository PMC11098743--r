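# Ground-truth tracer simulator: first-order label exchange, natural-
# abundance convolution, internal standard and multiplicative noise.

#' Define ground truth for a simulated tracer experiment
#'
#' Steady-state assumption: the intracellular pool P is constant over
#' the assay, so the heavy-labelled pool follows first-order exchange
#' H(t) = P (1 - exp(-k t)) with k = J_in / P.
#'
#' @param J_in import flux, pmol/min per 1e6 cells.
#' @param J_out export flux, pmol/min per 1e6 cells.
#' @param P intracellular pool, pmol per 1e6 cells.
#' @param fragment_formula measured fragment formula (string or named
#'   atom-count vector).
#' @param noise_cv multiplicative (lognormal) noise coefficient of
#'   variation (>= 0).
#' @param amino_acid identifier attached to emitted series.
#' @return A `tracer_truth` list.
#' @export
tracer_truth <- function(J_in, J_out = J_in / 2, P, fragment_formula = "C5H10NO2",
                         noise_cv = 0.05, amino_acid = "Leu") {
  assert_scalar_number(J_in, "J_in")
  assert_scalar_number(J_out, "J_out")
  assert_scalar_number(P, "P")
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0) {
    sf_stop("noise_cv must be >= 0", "screenflux_invalid_parameter")
  }
  structure(list(J_in = J_in, J_out = J_out, P = P,
                 fragment_formula = fragment_formula, noise_cv = noise_cv,
                 amino_acid = amino_acid),
            class = "tracer_truth")
}

# Lognormal multiplicative noise with unit mean and the given CV.
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an isotopologue time course with known ground truth
#'
#' Labelling is all-or-none per molecule (medium amino acids are
#' uniformly fully heavy-labelled). For an import assay the
#' intracellular heavy pool is H(t) = P (1 - exp(-k t)), k = J_in / P,
#' and the total pool stays at P. For a consumption assay the medium is
#' unlabelled and declines at the net rate J_in - J_out, with optional
#' per-timepoint withdrawal shrinking the well volume. For an export
#' assay the labelled amount released into the medium grows as J_out * t
#' over an unlabelled background. Emitted isotopologue vectors are the
#' labelled/unlabelled mixture convolved with natural abundance, scaled
#' to ion counts, with lognormal noise of the stated CV, plus a
#' norvaline internal-standard channel.
#'
#' @param truth a `tracer_truth`.
#' @param timepoints seconds (import/export) or minutes (consumption),
#'   non-negative increasing.
#' @param abundances natural-abundance map (see
#'   [default_isotope_abundances()]).
#' @param internal_standard_level norvaline ion counts (mean level).
#' @param seed integer seed.
#' @param assay_kind "import", "consumption" or "export".
#' @param response_factor ion counts per pmol (default 50).
#' @param n_cells effective cells in the assay (default 0.64e6).
#' @param medium_amount total medium amino acid, pmol (consumption /
#'   export background; default 20 * P).
#' @param initial_volume,per_sample_volume consumption-assay medium
#'   volume and per-timepoint withdrawal, ul.
#' @return An `isotopologue_series` (ion-count units) with the truth
#'   attached as attribute `truth`.
#' @export
simulate_tracer <- function(truth, timepoints,
                            abundances = default_isotope_abundances(),
                            internal_standard_level = 1e5, seed = 1L,
                            assay_kind = c("import", "consumption", "export"),
                            response_factor = 50, n_cells = 0.64e6,
                            medium_amount = NULL,
                            initial_volume = 300, per_sample_volume = 15) {
  stopifnot(inherits(truth, "tracer_truth"))
  assay_kind <- match.arg(assay_kind)
  if (any(timepoints < 0) || any(diff(timepoints) <= 0)) {
    sf_stop("timepoints must be non-negative and increasing",
            "screenflux_invalid_parameter")
  }
  A <- isotope_correction_matrix(truth$fragment_formula, abundances)
  n <- ncol(A) - 1L
  cells_frac <- n_cells / 1e6
  if (is.null(medium_amount)) {
    # growth media carry far more amino acid than cells turn over in an
    # assay: ~1e5 pmol in a 300 ul well is a few hundred micromolar
    medium_amount <- if (assay_kind == "import") 20 * truth$P * cells_frac else 1e5
  }

  k_min <- truth$J_in / truth$P          # 1/min
  tp <- timepoints
  nt <- length(tp)

  if (assay_kind == "import") {
    t_min <- tp / 60
    heavy <- truth$P * (1 - exp(-k_min * t_min)) * cells_frac
    light <- truth$P * cells_frac - heavy
    draws <- NULL
  } else if (assay_kind == "consumption") {
    # medium concentration declines under net uptake from a shrinking well
    net <- truth$J_in - truth$J_out      # pmol/min per 1e6 cells
    v <- rep(per_sample_volume, nt)
    v_before <- initial_volume - c(0, cumsum(v))[seq_len(nt)]
    if (any(v_before <= 0)) {
      sf_stop("withdrawal schedule exhausts the medium",
              "screenflux_invalid_schedule")
    }
    conc <- numeric(nt)                  # in pmol per initial-volume equivalent
    conc[1] <- medium_amount
    for (i in seq_len(nt - 1L)) {
      dt <- tp[i + 1L] - tp[i]           # minutes
      conc[i + 1L] <- conc[i] - net * cells_frac * dt *
        (initial_volume / (v_before[i] - v[i]))
    }
    if (any(conc < 0)) {
      sf_stop("consumption exhausts the medium amino acid pool",
              "screenflux_invalid_parameter")
    }
    light <- conc
    heavy <- rep(0, nt)
    draws <- v
  } else {                               # export
    t_min <- tp / 60
    heavy <- truth$J_out * t_min * cells_frac
    light <- rep(medium_amount, nt)
    draws <- NULL
  }

  with_seed(seed, {
    x <- cbind(light, matrix(0, nt, n - 1L), heavy)  # labelling distribution
    observed <- x %*% t(A)
    noise <- matrix(ln_noise(length(observed), truth$noise_cv), nt)
    ion <- observed * response_factor * noise
    norv <- internal_standard_level * ln_noise(nt, truth$noise_cv)
    series <- isotopologue_series(
      amino_acid = truth$amino_acid,
      fragment_formula = truth$fragment_formula,
      timepoints = tp, ion_counts = ion, norvaline = norv,
      assay_kind = assay_kind, sampling_volumes = draws, n_cells = n_cells
    )
    attr(series, "truth") <- truth
    series
  })
}

#' Simulate a standards dilution series matched to the tracer simulator
#'
#' @param amino_acid identifier.
#' @param pmol dilution points (default 0, 50, ..., 400 pmol).
#' @param response_factor ion counts per pmol (matches
#'   [simulate_tracer()]).
#' @param internal_standard_level norvaline ion counts.
#' @param noise_cv multiplicative noise CV (default 0: exact standards).
#' @param seed integer seed.
#' @return data.frame for [fit_standard_curve()].
#' @export
simulate_standards <- function(amino_acid, pmol = seq(0, 400, by = 50),
                               response_factor = 50,
                               internal_standard_level = 1e5,
                               noise_cv = 0, seed = 1L) {
  with_seed(seed, {
    data.frame(
      amino_acid = amino_acid,
      pmol = pmol,
      ion_counts = pmol * response_factor * ln_noise(length(pmol), noise_cv),
      norvaline = internal_standard_level * ln_noise(length(pmol), noise_cv),
      stringsAsFactors = FALSE
    )
  })
}
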