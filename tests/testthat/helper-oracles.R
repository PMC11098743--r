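# Independent oracles and small fixtures used across the suite. These
# deliberately avoid the code paths they check.

# --- Mann-Whitney oracles ---------------------------------------------------

# Literal exhaustive enumeration: every assignment of pooled ranks to
# group x via combn. Feasible for small n + m only.
enum_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  sums <- colSums(matrix(combn(n + m, n), nrow = n))
  pl <- mean(sums <= w_obs)
  ph <- mean(sums >= w_obs)
  min(1, 2 * min(pl, ph))
}

# Generating-function count of k-subset rank sums: exact for any size,
# still an exhaustive count over all C(n+m, n) configurations.
ranksum_counts <- function(N, m) {
  maxs <- sum(seq(N - m + 1, N))
  ways <- matrix(0, m + 1, maxs + 1)
  ways[1, 1] <- 1
  for (i in seq_len(N)) {
    for (k in seq(min(m, i), 1)) {
      src <- seq_len(maxs + 1 - i)
      ways[k + 1, src + i] <- ways[k + 1, src + i] + ways[k, src]
    }
  }
  ways[m + 1, ]
}

gf_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  counts <- ranksum_counts(n + m, n)
  total <- sum(counts)
  sums <- seq_along(counts) - 1L
  pl <- sum(counts[sums <= w_obs]) / total
  ph <- sum(counts[sums >= w_obs]) / total
  min(1, 2 * min(pl, ph))
}

# --- top-k phenotype-score oracle -------------------------------------------

# Brute force over all k-subsets: the phenotype score must equal the
# signed mean of the subset maximizing the sum of absolute values.
brute_top_k_mean <- function(values, k) {
  subsets <- combn(length(values), k)
  sums <- apply(subsets, 2, function(ix) sum(abs(values[ix])))
  best <- subsets[, which.max(sums)]
  mean(values[best])
}

# --- isotope forward-model oracle -------------------------------------------

# Independent natural-abundance convolution via stats::convolve over the
# per-atom distributions, for a molecule with j labelled carbons.
convolve_forward <- function(formula, abundances, j, label = "C") {
  counts <- screenflux::parse_formula(formula)
  dist <- 1
  mult <- function(a, b) {
    if (length(a) == 1) return(a * b)
    if (length(b) == 1) return(b * a)
    stats::convolve(a, rev(b), type = "open")
  }
  for (el in names(counts)) {
    n_at <- counts[[el]] - if (el == label) j else 0L
    for (i in seq_len(n_at)) dist <- mult(dist, abundances[[el]])
  }
  c(rep(0, j), dist)
}

# --- fixtures ---------------------------------------------------------------

test_manifest <- function(n_genes = 4, n_ntc = 30, seed = 11,
                          two_tss_genes = 0) {
  build_manifest(c(SLC = n_genes), sgrnas_per_tss = 10,
                 two_tss_genes = two_tss_genes, n_ntc = n_ntc, seed = seed)
}

# A gene_score_table built by hand (for hit-calling tests).
scored_table <- function(genes, scores, pseudo_scores) {
  df <- data.frame(
    gene = c(genes, sprintf("pseudo_%02d", seq_along(pseudo_scores))),
    tss = "primary",
    phenotype_score = c(scores, pseudo_scores),
    p_value = 0.5,
    screen_score = c(scores, pseudo_scores),
    n_sgrnas = 10L,
    is_pseudogene = rep(c(FALSE, TRUE), c(length(genes), length(pseudo_scores))),
    class = "none",
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_score_table", "data.frame")
  df
}

# Molecular formulas used by the tracer recovery suites.
aa_formulas <- c(
  Asn = "C4H8N2O3", Asp = "C4H7NO4", Gln = "C5H10N2O3", Glu = "C5H9NO4",
  Pro = "C5H9NO2", Arg = "C6H14N4O2", Gly = "C2H5NO2", His = "C6H9N3O2",
  Ile = "C6H13NO2", Lys = "C6H14N2O2", Ser = "C3H7NO3", Thr = "C4H9NO3",
  Val = "C5H11NO2", Leu = "C6H13NO2", Tyr = "C9H11NO3", Phe = "C9H11NO2"
)

# The import-assay sampling schedule used throughout (seconds).
import_timepoints <- c(0, 5, 10, 20, 30, 40, 100, 250)
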