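# Natural-isotope abundance: forward convolution model and its inversion.

#' Default natural isotope abundances
#'
#' Per element, the fractional abundance of the M+0, M+1, ... mass
#' isotopes (terrestrial averages). Si is included because silylation
#' reagents used in GC-MS derivatization contribute Si atoms to the
#' measured fragment.
#'
#' @return named list element -> numeric abundance vector (sums to 1).
#' @export
default_isotope_abundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
    Si = c(0.92223, 0.04685, 0.03092)
  )
}

# Polynomial (distribution) product: mass-shift convolution.
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  }
  out
}

# n-fold self-convolution of a single-atom mass-shift distribution.
poly_power <- function(a, n) {
  out <- 1
  for (i in seq_len(n)) out <- poly_mult(out, a)
  out
}

#' Parse a molecular formula string into an element count map
#'
#' @param formula e.g. "C5H10N1O2" or "C11H26N1O2Si2".
#' @return named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) return(formula)  # already a count map
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(sub("^[A-Za-z]+", "", parts))
  ct[is.na(ct)] <- 1L
  stats::setNames(ct, el)
}

#' Forward natural-abundance convolution matrix
#'
#' Builds the matrix A such that `observed = A %*% x`, where `x` is the
#' underlying tracer-labelling distribution (x_j = amount with j tracer
#' atoms) and `observed` is the measured isotopologue vector M+0..M+n.
#' Column j convolves the natural isotope distributions of all atoms in
#' the fragment except the j tracer-labelled atoms of the label element
#' (assumed isotopically pure), then shifts by j. Rows beyond M+n are
#' truncated, matching the measured vector length of label capacity + 1.
#'
#' @param formula fragment formula (string or named atom-count vector).
#' @param abundances element -> isotope-fraction map; each must sum to 1.
#' @param label_element tracer-labelled element (default "C").
#' @return (n+1) x (n+1) matrix, n = number of label-element atoms.
#' @export
isotope_correction_matrix <- function(formula,
                                      abundances = default_isotope_abundances(),
                                      label_element = "C") {
  counts <- parse_formula(formula)
  for (el in names(counts)) {
    if (!el %in% names(abundances)) {
      sf_stop(sprintf("no natural abundances supplied for element %s", el),
              "screenflux_invalid_parameter")
    }
    s <- sum(abundances[[el]])
    if (abs(s - 1) > 1e-6) {
      sf_stop(sprintf("abundances for %s must sum to 1 (got %g)", el, s),
              "screenflux_invalid_parameter")
    }
  }
  n <- unname(counts[label_element])
  if (is.na(n) || n < 1) {
    sf_stop("fragment contains no atoms of the label element",
            "screenflux_invalid_parameter")
  }
  others <- counts[setdiff(names(counts), label_element)]
  base <- 1
  for (el in names(others)) {
    base <- poly_mult(base, poly_power(abundances[[el]], others[[el]]))
  }
  A <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    dist <- poly_mult(base, poly_power(abundances[[label_element]], n - j))
    shifted <- c(rep(0, j), dist)
    A[, j + 1L] <- shifted[seq_len(n + 1L)]
  }
  dimnames(A) <- list(paste0("M", 0:n), paste0("x", 0:n))
  A
}

#' Correct measured isotopologues for natural isotope abundance
#'
#' Solves `observed = A x` for the underlying labelling distribution x
#' by non-negative least squares (one solve per timepoint), where A is
#' the forward convolution matrix of the fragment formula. The
#' round-trip `correct(convolve(x))` recovers x to numerical precision.
#'
#' @param series an `isotopologue_series` (see [isotopologue_series()]).
#' @param abundances element -> isotope-fraction map.
#' @param label_element tracer-labelled element (default "C").
#' @return the series with corrected `ion_counts`.
#' @export
natural_abundance_correct <- function(series,
                                      abundances = default_isotope_abundances(),
                                      label_element = "C") {
  stopifnot(inherits(series, "isotopologue_series"))
  A <- isotope_correction_matrix(series$fragment_formula, abundances,
                                 label_element)
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    sf_stop(sprintf("correction matrix ill-conditioned for formula %s",
                    paste0(names(parse_formula(series$fragment_formula)),
                           parse_formula(series$fragment_formula),
                           collapse = "")),
            "screenflux_conditioning_error")
  }
  corrected <- t(apply(series$ion_counts, 1, function(obs) {
    # direct solve when already non-negative (exactly-consistent data);
    # non-negative least squares otherwise
    x <- solve(A, obs)
    if (all(x >= -1e-9 * max(abs(x), 1))) return(pmax(x, 0))
    pracma::lsqnonneg(A, obs)$x
  }))
  dimnames(corrected) <- dimnames(series$ion_counts)
  series$ion_counts <- corrected
  series$na_corrected <- TRUE
  series
}
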