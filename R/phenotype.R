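# Per-sgRNA phenotypes: count filtering, pseudocounts and rho calculation.

#' Filter low-count sgRNAs and add a pseudocount
#'
#' Depth-matches the two compared samples to a common total (the
#' geometric mean of their totals), flags sgRNAs whose depth-matched
#' count falls below `min_count` in both samples, and adds the
#' pseudocount to the retained counts. The in vitro default minimum is
#' 100 counts in at least one of the two conditions; in vivo screens
#' lower it to 25.
#'
#' @param expt a `screen_experiment`.
#' @param pair character(2): (treated/endpoint sample id, control sample id).
#' @param min_count minimum depth-matched count required in at least one
#'   of the two samples (boundary inclusive).
#' @param pseudocount value added to all retained counts to damp
#'   low-count noise (default 10).
#' @return data.frame `sgrna_id`, `treated`, `control` (depth-matched,
#'   pseudocounted), `pass`; excluded sgRNAs carry NA phenotype inputs.
#' @export
filter_and_pseudocount <- function(expt, pair, min_count = 100,
                                   pseudocount = 10) {
  stopifnot(inherits(expt, "screen_experiment"), length(pair) == 2L)
  if (min_count < 0) {
    sf_stop("`min_count` must be >= 0", "screenflux_invalid_parameter")
  }
  missing_s <- setdiff(pair, colnames(expt$counts))
  if (length(missing_s)) {
    sf_stop(paste("samples not in experiment:", paste(missing_s, collapse = ", ")),
            "screenflux_invalid_spec")
  }
  treated <- expt$counts[, pair[1]]
  control <- expt$counts[, pair[2]]
  t1 <- sum(treated); t2 <- sum(control)
  if (t1 == 0 || t2 == 0) {
    sf_stop("zero-total sample in pair", "screenflux_degenerate_sample")
  }
  common <- sqrt(t1 * t2)
  treated <- treated * common / t1
  control <- control * common / t2
  pass <- treated >= min_count | control >= min_count
  out <- data.frame(
    sgrna_id = rownames(expt$counts),
    treated = ifelse(pass, treated + pseudocount, NA_real_),
    control = ifelse(pass, control + pseudocount, NA_real_),
    pass = pass,
    stringsAsFactors = FALSE
  )
  attr(out, "pair") <- pair
  attr(out, "min_count") <- min_count
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-sgRNA rho phenotypes
#'
#' rho_i = [log2((c_i,treated + psi) / (c_i,control + psi)) - median of
#' the same quantity over NTC sgRNAs] / D, with D the number of
#' population doublings of the comparison. In vivo screens are scored
#' without doubling normalization (D fixed at 1). The NTC median of the
#' result is exactly zero by construction.
#'
#' @param scaffold output of [filter_and_pseudocount()].
#' @param ntc_ids character vector of NTC sgRNA ids (used for centering).
#' @param doublings population doublings D (> 0); ignored in in vivo mode.
#' @param mode "in_vitro" or "in_vivo".
#' @return data.frame `sgrna_id`, `rho`, `pass`.
#' @export
sgrna_phenotype <- function(scaffold, ntc_ids, doublings = NULL,
                            mode = c("in_vitro", "in_vivo")) {
  mode <- match.arg(mode)
  if (mode == "in_vitro") {
    if (is.null(doublings) || doublings <= 0) {
      sf_stop("in vitro scoring requires doublings > 0",
              "screenflux_invalid_design")
    }
    d <- doublings
  } else {
    d <- 1
  }
  lr <- log2(scaffold$treated / scaffold$control)
  is_ntc <- scaffold$sgrna_id %in% ntc_ids
  ntc_lr <- lr[is_ntc & scaffold$pass]
  if (!length(ntc_lr)) {
    sf_stop("no NTC sgRNAs retained; cannot center phenotypes",
            "screenflux_cannot_center")
  }
  rho <- (lr - stats::median(ntc_lr)) / d
  data.frame(sgrna_id = scaffold$sgrna_id, rho = rho,
             pass = scaffold$pass, stringsAsFactors = FALSE)
}
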