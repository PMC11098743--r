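# Gene-level scoring: top-7 phenotype score, Mann-Whitney p, screen score.

#' Two-sided Mann-Whitney p-value
#'
#' Exact null distribution when both groups have <= `exact_max` values
#' and there are no ties; otherwise the normal approximation with tie
#' and continuity corrections (via [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors.
#' @param exact_max largest group size for which the exact distribution
#'   is used (default 25).
#' @return two-sided p-value.
#' @export
mann_whitney_p <- function(x, y, exact_max = 25L) {
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- no_ties && length(x) <= exact_max && length(y) <= exact_max
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Score a single gene from its sgRNA rho phenotypes
#'
#' Two metrics per gene: (1) the signed mean of the `top_k` rho
#' phenotypes largest in absolute value ("phenotype score", PS), and
#' (2) the two-sided Mann-Whitney p-value of all retained rho phenotypes
#' against the NTC rho distribution. The single summary ("screen score")
#' is PS * -log10(max(p, p_floor)).
#'
#' @param rhos numeric vector of the gene's retained sgRNA rho values.
#' @param ntc_rhos numeric vector of NTC sgRNA rho values.
#' @param top_k number of strongest phenotypes averaged (default 7).
#' @param min_sgrnas minimum retained sgRNAs required to score the gene
#'   (default 5); below this the gene is reported unscored (NA), not an
#'   error.
#' @param p_floor p-values are floored here before -log10 (default 1e-16).
#' @return list(phenotype_score, p_value, screen_score, n_sgrnas).
#' @export
gene_score <- function(rhos, ntc_rhos, top_k = 7L, min_sgrnas = 5L,
                       p_floor = 1e-16) {
  rhos <- rhos[is.finite(rhos)]
  n <- length(rhos)
  if (n < min_sgrnas) {
    return(list(phenotype_score = NA_real_, p_value = NA_real_,
                screen_score = NA_real_, n_sgrnas = n))
  }
  k <- min(top_k, n)
  sel <- order(abs(rhos), decreasing = TRUE)[seq_len(k)]
  ps <- mean(rhos[sel])
  p <- mann_whitney_p(rhos, ntc_rhos)
  ss <- ps * -log10(max(p, p_floor))
  list(phenotype_score = ps, p_value = p, screen_score = ss, n_sgrnas = n)
}

#' Score a whole screen comparison at the gene level
#'
#' Runs the full per-comparison pipeline: count filtering and
#' pseudocount, per-sgRNA rho phenotypes, then gene-level scores for
#' every real gene and every pseudogene. Genes with two transcription
#' start sites are scored as independent 10-sgRNA units and reported as
#' the unit with the larger absolute screen score.
#'
#' @param expt a `screen_experiment` (technical replicates already
#'   averaged if applicable).
#' @param manifest a `library_manifest`.
#' @param pseudogenes a `pseudogene_set` (see [make_pseudogenes()]).
#' @param pair character(2): (treated sample id, control sample id).
#' @param doublings population doublings for this comparison (in vitro).
#' @param min_count,pseudocount,top_k,min_sgrnas,p_floor scoring
#'   parameters; see [filter_and_pseudocount()] and [gene_score()].
#' @return A `gene_score_table`: data.frame with columns `gene`, `tss`,
#'   `phenotype_score`, `p_value`, `screen_score`, `n_sgrnas`, `class`
#'   (hit class, "none" until [call_hits()]), `is_pseudogene`.
#' @export
score_screen <- function(expt, manifest, pseudogenes, pair,
                         doublings = NULL, min_count = 100,
                         pseudocount = 10, top_k = 7L, min_sgrnas = 5L,
                         p_floor = 1e-16) {
  stopifnot(inherits(manifest, "library_manifest"))
  unknown <- setdiff(manifest$sgrna_id, rownames(expt$counts))
  if (length(unknown)) {
    sf_stop(sprintf("%d manifest sgRNAs missing from counts", length(unknown)),
            "screenflux_invalid_spec")
  }
  scaffold <- filter_and_pseudocount(expt, pair, min_count, pseudocount)
  ntc_ids <- manifest$sgrna_id[manifest$is_ntc]
  pheno <- sgrna_phenotype(scaffold, ntc_ids, doublings, mode = expt$mode)
  rho <- stats::setNames(pheno$rho, pheno$sgrna_id)
  rho <- rho[pheno$pass]
  ntc_rhos <- rho[names(rho) %in% ntc_ids]
  ntc_rhos <- ntc_rhos[is.finite(ntc_rhos)]

  targets <- manifest[!manifest$is_ntc, , drop = FALSE]
  units <- split(targets$sgrna_id,
                 paste(targets$gene, targets$tss, sep = "\r"))
  unit_meta <- do.call(rbind, strsplit(names(units), "\r", fixed = TRUE))
  unit_rows <- lapply(seq_along(units), function(i) {
    s <- gene_score(rho[intersect(units[[i]], names(rho))], ntc_rhos,
                    top_k, min_sgrnas, p_floor)
    data.frame(gene = unit_meta[i, 1], tss = unit_meta[i, 2],
               phenotype_score = s$phenotype_score, p_value = s$p_value,
               screen_score = s$screen_score, n_sgrnas = s$n_sgrnas,
               stringsAsFactors = FALSE)
  })
  unit_tab <- do.call(rbind, unit_rows)
  # Two-TSS genes: keep the TSS unit with the larger |screen score|.
  pick <- unlist(lapply(split(seq_len(nrow(unit_tab)), unit_tab$gene), function(ix) {
    if (length(ix) == 1L) return(ix)
    ss <- abs(unit_tab$screen_score[ix])
    if (all(is.na(ss))) ix[1] else ix[which.max(replace(ss, is.na(ss), -Inf))]
  }))
  gene_tab <- unit_tab[sort(pick), , drop = FALSE]
  gene_tab$is_pseudogene <- FALSE

  # pseudogenes are scored against the NTC reference excluding their own
  # members: real-gene sgRNAs are never inside the reference, so the
  # leave-self-out reference is what makes the two nulls exchangeable
  pseudo_rows <- lapply(seq_len(nrow(pseudogenes)), function(i) {
    mem <- pseudogenes$member_sgrna_ids[[i]]
    s <- gene_score(rho[intersect(mem, names(rho))],
                    ntc_rhos[!names(ntc_rhos) %in% mem],
                    top_k, min_sgrnas, p_floor)
    data.frame(gene = pseudogenes$pseudogene_id[i], tss = "primary",
               phenotype_score = s$phenotype_score, p_value = s$p_value,
               screen_score = s$screen_score, n_sgrnas = s$n_sgrnas,
               is_pseudogene = TRUE, stringsAsFactors = FALSE)
  })
  out <- rbind(gene_tab, do.call(rbind, pseudo_rows))
  out$class <- "none"
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    pair = pair, doublings = doublings, mode = expt$mode,
    min_count = min_count, pseudocount = pseudocount, top_k = top_k,
    min_sgrnas = min_sgrnas, p_floor = p_floor
  )
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Average gene score tables across biological replicates
#'
#' Per-gene arithmetic mean of screen scores (and phenotype scores).
#' Per-replicate screen scores are retained in `rep_screen_scores`
#' columns so that significance thresholds can still be derived from
#' unaveraged pseudogene scores.
#'
#' @param tables list of `gene_score_table`s over the same gene universe.
#' @return A `gene_score_table` of averages.
#' @export
average_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ref <- tables[[1]]
  # gene universe must match; the winning TSS unit of a two-TSS gene may
  # legitimately differ between replicates
  for (t in tables[-1]) {
    if (!identical(ref$gene, t$gene)) {
      sf_stop("replicate tables cover different gene sets",
              "screenflux_alignment_error")
    }
  }
  ss <- vapply(tables, function(t) t$screen_score, numeric(nrow(ref)))
  ps <- vapply(tables, function(t) t$phenotype_score, numeric(nrow(ref)))
  ss <- matrix(ss, nrow = nrow(ref))
  ps <- matrix(ps, nrow = nrow(ref))
  out <- ref
  out$screen_score <- rowMeans(ss)
  out$phenotype_score <- rowMeans(ps)
  out$p_value <- NA_real_
  for (j in seq_along(tables)) out[[paste0("rep_screen_score_", j)]] <- ss[, j]
  attr(out, "n_replicates") <- length(tables)
  out
}

#' Write a gene score table to TSV
#'
#' Columns `gene,tss,phenotype_score,p_value,screen_score,n_sgrnas,class,is_pseudogene`.
#'
#' @param table a `gene_score_table`.
#' @param path output path.
#' @export
write_gene_scores <- function(table, path) {
  cols <- c("gene", "tss", "phenotype_score", "p_value", "screen_score",
            "n_sgrnas", "class", "is_pseudogene")
  utils::write.table(as.data.frame(table)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
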