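# Competition, viability-titration and lipid-peroxidation calculations.

#' Simulate a qPCR growth-competition assay
#'
#' A test cell line is mixed 1:1 with its NTC control at T0; after
#' growth, genomic DNA is assayed in two qPCR reactions (test-sgRNA and
#' NTC primers) and the mixture composition read out as the Ct
#' difference. Assuming perfect doubling per cycle, the test:NTC
#' template ratio changes by `2^(effect * D_norm)` where `D_norm` is the
#' doubling difference between test medium and reference. Noiseless
#' output is exactly inverted by [competition_phenotype()].
#'
#' @param true_log2fc_per_doubling true per-doubling log2 fitness effect
#'   of the test line.
#' @param doublings_test,doublings_ref population doublings in the test
#'   condition and the vehicle reference.
#' @param ct_noise_sd per-reaction Ct noise, cycles (default 0).
#' @param base_ct Ct of a 50% template at T0 (arbitrary anchor).
#' @param condition condition label.
#' @param seed integer seed.
#' @return data.frame of competition records: `sample`, `condition`,
#'   `timepoint` ("T0"/"endpoint"), `ct_test`, `ct_ntc`,
#'   `doublings_test`, `doublings_ref`.
#' @export
simulate_competition <- function(true_log2fc_per_doubling, doublings_test,
                                 doublings_ref = 0, ct_noise_sd = 0,
                                 base_ct = 20, condition = "test",
                                 seed = 1L) {
  if (doublings_test < 0 || doublings_ref < 0) {
    sf_stop("doublings must be >= 0", "screenflux_invalid_parameter")
  }
  if (ct_noise_sd < 0) {
    sf_stop("ct_noise_sd must be >= 0", "screenflux_invalid_parameter")
  }
  d_norm <- doublings_test - doublings_ref
  with_seed(seed, {
    # T0: 50/50 mix, both primers read the same template abundance.
    # endpoint: test template gains effect * d_norm log2 units vs NTC.
    shift <- true_log2fc_per_doubling * d_norm
    ct <- c(
      t0_test = base_ct, t0_ntc = base_ct,
      end_test = base_ct - shift / 2, end_ntc = base_ct + shift / 2
    ) + stats::rnorm(4, sd = ct_noise_sd)
    data.frame(
      sample = c("mix", "mix"),
      condition = condition,
      timepoint = c("T0", "endpoint"),
      ct_test = c(ct[["t0_test"]], ct[["end_test"]]),
      ct_ntc = c(ct[["t0_ntc"]], ct[["end_ntc"]]),
      doublings_test = doublings_test,
      doublings_ref = doublings_ref,
      stringsAsFactors = FALSE
    )
  })
}

#' Growth phenotype from a qPCR competition assay
#'
#' Per condition: delta-Ct = Ct_test - Ct_ntc at T0 and endpoint;
#' delta-delta-Ct = endpoint minus T0; the phenotype is
#' `-ddCt / D_norm`, where `D_norm` is the doubling difference between
#' the test condition and the vehicle reference
#' (`normalization = "condition_vs_reference"`) or the total doublings
#' of the assay (`"per_doubling"`, complete-media assays). Higher Ct
#' means less template, so depletion of the test line gives a negative
#' phenotype, matching screen-score signs.
#'
#' @param records data.frame of competition records (see
#'   [simulate_competition()] for columns).
#' @param normalization "condition_vs_reference" or "per_doubling".
#' @return data.frame `condition`, `ddct`, `d_norm`, `phenotype`.
#' @export
competition_phenotype <- function(records,
                                  normalization = c("condition_vs_reference",
                                                    "per_doubling")) {
  normalization <- match.arg(normalization)
  rows <- lapply(split(records, records$condition), function(d) {
    t0 <- d[d$timepoint == "T0", , drop = FALSE]
    end <- d[d$timepoint == "endpoint", , drop = FALSE]
    if (nrow(t0) == 0L || nrow(end) == 0L) {
      sf_stop(sprintf("condition %s: missing %s record", d$condition[1],
                      if (nrow(t0) == 0L) "T0" else "endpoint"),
              "screenflux_unpaired_record")
    }
    dct_t0 <- mean(t0$ct_test - t0$ct_ntc)
    dct_end <- mean(end$ct_test - end$ct_ntc)
    ddct <- dct_end - dct_t0
    d_norm <- if (normalization == "condition_vs_reference") {
      mean(end$doublings_test) - mean(end$doublings_ref)
    } else {
      mean(end$doublings_test)
    }
    if (d_norm == 0) {
      sf_stop(sprintf("condition %s: zero doubling normalization",
                      d$condition[1]), "screenflux_invalid_parameter")
    }
    data.frame(condition = d$condition[1], ddct = ddct, d_norm = d_norm,
               phenotype = -ddct / d_norm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population doublings from a viability plate
#'
#' Per condition: replicate readings are averaged, divided by the T0
#' luminescence, internally normalized to the plate's complete-medium
#' control, and expressed on a log2 scale as population doublings.
#' Invariant to plate-wide multiplicative gain.
#'
#' @param plate data.frame with columns `condition`, `replicate`,
#'   `reading`, `is_t0` (logical). Additional layout columns (row, col)
#'   are ignored, so spatially randomized plates remap for free.
#' @param normalizer condition name of the plate-internal control, or
#'   NULL to skip internal normalization.
#' @return data.frame `condition`, `log2_doublings`.
#' @export
viability_log2fc <- function(plate, normalizer = NULL) {
  need <- c("condition", "replicate", "reading", "is_t0")
  if (!all(need %in% names(plate))) {
    sf_stop(paste("plate needs columns:", paste(need, collapse = ", ")),
            "screenflux_invalid_spec")
  }
  t0 <- mean(plate$reading[plate$is_t0])
  if (!is.finite(t0) || t0 <= 0) {
    sf_stop("T0 luminescence reference missing or zero",
            "screenflux_degenerate_reference")
  }
  grown <- plate[!plate$is_t0, , drop = FALSE]
  means <- tapply(grown$reading, grown$condition, mean)
  ratio <- means / t0
  if (!is.null(normalizer)) {
    if (!normalizer %in% names(ratio)) {
      sf_stop(sprintf("normalizer condition %s not on plate", normalizer),
              "screenflux_invalid_spec")
    }
    ratio <- ratio / ratio[[normalizer]]
  }
  data.frame(condition = names(ratio), log2_doublings = log2(as.numeric(ratio)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalized lipid peroxide level
#'
#' Ratio of oxidized to reduced lipophilic dye fluorescence, normalized
#' to a control condition's ratio (control scores 1 by construction).
#'
#' @param oxidized,reduced fluorescence intensities (reduced > 0).
#' @param control_ratio oxidized/reduced ratio of the control condition.
#' @return normalized peroxide level.
#' @export
lipid_peroxidation_ratio <- function(oxidized, reduced, control_ratio = 1) {
  if (any(reduced <= 0) || any(control_ratio <= 0)) {
    sf_stop("reduced signal and control ratio must be > 0",
            "screenflux_invalid_parameter")
  }
  (oxidized / reduced) / control_ratio
}
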