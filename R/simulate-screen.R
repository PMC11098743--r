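# Ground-truth screen simulator: lognormal library representation,
# per-gene fitness effects acting over population doublings, multinomial
# sequencing.

#' Define ground truth for a simulated screen
#'
#' @param manifest a `library_manifest`.
#' @param effects named numeric vector of per-gene fitness effects e_g
#'   (per-doubling log2 growth-rate difference; genes absent default to
#'   0). NTC sgRNAs always have effect exactly 0.
#' @param efficacy per-sgRNA efficacy multipliers in \[0, 1\], either a
#'   single value or a vector named by sgRNA id (default 1: full effect).
#' @param sigma_abund lognormal sigma of the initial library
#'   representation (default 0.5).
#' @param depth_per_sgrna sequencing depth per sample, expressed as mean
#'   reads per sgRNA (default 500).
#' @return A `screen_truth` list.
#' @export
screen_truth <- function(manifest, effects = numeric(0), efficacy = 1,
                         sigma_abund = 0.5, depth_per_sgrna = 500) {
  stopifnot(inherits(manifest, "library_manifest"))
  assert_scalar_number(sigma_abund, "sigma_abund", allow_zero = TRUE)
  assert_scalar_number(depth_per_sgrna, "depth_per_sgrna")
  e <- stats::setNames(rep(0, nrow(manifest)), manifest$sgrna_id)
  known <- intersect(names(effects), manifest$gene)
  for (g in known) e[manifest$gene == g] <- effects[[g]]
  e[manifest$is_ntc] <- 0
  eff <- if (length(efficacy) == 1L && is.null(names(efficacy))) {
    stats::setNames(rep(efficacy, nrow(manifest)), manifest$sgrna_id)
  } else {
    out <- stats::setNames(rep(1, nrow(manifest)), manifest$sgrna_id)
    out[names(efficacy)] <- efficacy
    out
  }
  if (any(eff < 0 | eff > 1)) {
    sf_stop("efficacy multipliers must lie in [0, 1]",
            "screenflux_invalid_parameter")
  }
  structure(list(effect = e, efficacy = eff, sigma_abund = sigma_abund,
                 depth_per_sgrna = depth_per_sgrna),
            class = "screen_truth")
}

#' Simulate a pooled screen with known ground truth
#'
#' Initial sgRNA abundances are lognormal; in a grown arm with D
#' population doublings, the abundance of sgRNA i targeting gene g is
#' proportional to `abund_T0 * 2^(D * (1 + efficacy_i * e_g))` (NTCs
#' expand as `2^D`). Read counts per sample are multinomial at the
#' stated depth, optionally overdispersed by a Dirichlet prefactor.
#'
#' @param manifest a `library_manifest`.
#' @param truth a `screen_truth`.
#' @param design data.frame with columns `sample_id`, `arm`,
#'   `replicate`, `tech_rep`, `doublings`; must contain a T0 row
#'   (doublings 0, arm "T0") and at least one grown arm.
#' @param seed integer seed; output is deterministic given the seed.
#' @param overdispersion Dirichlet concentration-scale knob; `Inf`
#'   (default) gives plain multinomial sampling, smaller values inflate
#'   count variance.
#' @param mode passed to [screen_experiment()].
#' @return A `screen_experiment`; the per-sgRNA truth is attached as
#'   attribute `truth`.
#' @export
simulate_screen <- function(manifest, truth, design, seed = 1L,
                            overdispersion = Inf,
                            mode = c("in_vitro", "in_vivo")) {
  mode <- match.arg(mode)
  stopifnot(inherits(manifest, "library_manifest"),
            inherits(truth, "screen_truth"))
  if (any(design$doublings < 0)) {
    sf_stop("negative population doublings in design",
            "screenflux_invalid_design")
  }
  if (!any(design$arm == "T0")) {
    sf_stop("design must name a T0 sample", "screenflux_invalid_design")
  }
  if (!any(design$doublings > 0)) {
    sf_stop("design must include a grown arm with doublings > 0",
            "screenflux_invalid_design")
  }
  n <- nrow(manifest)
  depth <- round(truth$depth_per_sgrna * n)
  with_seed(seed, {
    abund0 <- stats::rlnorm(n, meanlog = 0, sdlog = truth$sigma_abund)
    names(abund0) <- manifest$sgrna_id
    growth_rate <- 1 + truth$efficacy * truth$effect  # per doubling
    counts <- vapply(seq_len(nrow(design)), function(j) {
      d <- design$doublings[j]
      ab <- abund0 * 2^(d * growth_rate)
      p <- ab / sum(ab)
      if (is.finite(overdispersion)) {
        g <- stats::rgamma(n, shape = p * overdispersion, rate = 1)
        p <- g / sum(g)
      }
      stats::rmultinom(1, size = depth, prob = p)[, 1]
    }, numeric(n))
    rownames(counts) <- manifest$sgrna_id
    colnames(counts) <- design$sample_id
    expt <- screen_experiment(counts, design, mode = mode)
    attr(expt, "truth") <- truth
    expt
  })
}

#' A minimal two-arm screen design
#'
#' T0 plus one treated arm, each with `n_replicates` biological
#' replicates (single technical replicate).
#'
#' @param doublings population doublings of the treated arm.
#' @param n_replicates biological replicates (default 1).
#' @param arm label of the grown arm (default "treated").
#' @return design data.frame for [simulate_screen()].
#' @export
two_arm_design <- function(doublings, n_replicates = 1L, arm = "treated") {
  reps <- seq_len(n_replicates)
  data.frame(
    sample_id = c(paste0("T0_r", reps), paste0(arm, "_r", reps)),
    arm = rep(c("T0", arm), each = n_replicates),
    replicate = rep(reps, 2),
    tech_rep = 1L,
    doublings = rep(c(0, doublings), each = n_replicates),
    stringsAsFactors = FALSE
  )
}
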