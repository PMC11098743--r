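# Significance thresholds from the pseudogene null, hit calling,
# cross-condition utilities.

#' Derive significance thresholds from pseudogene screen scores
#'
#' The cut-offs are set by the highest- and lowest-scoring simulated
#' negative-control gene. For replicate-averaged tables that retain
#' per-replicate columns (see [average_replicates()]), the stringent
#' variant takes the extremes over the unaveraged per-replicate
#' pseudogene scores; pooling over several condition tables implements
#' the "highest-scoring negative control in any condition" rule.
#'
#' @param tables a `gene_score_table` or list of them.
#' @param per_replicate use per-replicate pseudogene scores when present
#'   (default TRUE).
#' @return list(upper, lower): enrichment and depletion cut-offs.
#' @export
pseudogene_thresholds <- function(tables, per_replicate = TRUE) {
  if (inherits(tables, "gene_score_table")) tables <- list(tables)
  scores <- unlist(lapply(tables, function(t) {
    ps <- t[t$is_pseudogene, , drop = FALSE]
    repcols <- grep("^rep_screen_score_", names(ps), value = TRUE)
    if (per_replicate && length(repcols)) {
      unlist(ps[repcols], use.names = FALSE)
    } else {
      ps$screen_score
    }
  }))
  scores <- scores[is.finite(scores)]
  if (!length(scores)) {
    sf_stop("no pseudogene scores available for thresholding",
            "screenflux_cannot_threshold")
  }
  list(upper = max(scores), lower = min(scores))
}

#' Call hits against pseudogene-derived thresholds
#'
#' Genes with screen score above `thresholds$upper` are classed
#' "enriched", below `thresholds$lower` "depleted", otherwise "none".
#' If an untreated-arm table is supplied, significant hits whose
#' untreated per-replicate score falls below `untreated_floor` are
#' reclassified to "excluded" (pan-resistance guard: a general slowdown
#' in proliferation inflates apparent resistance across conditions)
#' unless they are very strong resistant (score > `resistant_override`)
#' or hypersensitive (score < `hypersensitive_override`) in the scored
#' condition.
#'
#' @param table a `gene_score_table` (real genes and pseudogenes).
#' @param thresholds list(upper, lower) from [pseudogene_thresholds()];
#'   defaults to thresholds derived from `table` itself.
#' @param untreated optional `gene_score_table` for the untreated
#'   control arm of the screen.
#' @param untreated_floor per-replicate untreated score below which a
#'   hit is excluded (default -0.12).
#' @param resistant_override condition score above which the exclusion
#'   is waived (default 1.5).
#' @param hypersensitive_override condition score below which the
#'   exclusion is waived (default -1.5).
#' @return the table with its `class` column filled in and the
#'   thresholds attached as attribute `thresholds`.
#' @export
call_hits <- function(table, thresholds = NULL, untreated = NULL,
                      untreated_floor = -0.12, resistant_override = 1.5,
                      hypersensitive_override = -1.5) {
  stopifnot(inherits(table, "gene_score_table"))
  if (!any(table$is_pseudogene)) {
    sf_stop("table carries no pseudogenes; cannot derive thresholds",
            "screenflux_cannot_threshold")
  }
  if (is.null(thresholds)) thresholds <- pseudogene_thresholds(table)
  ss <- table$screen_score
  cls <- ifelse(is.na(ss), "unscored",
         ifelse(ss > thresholds$upper, "enriched",
         ifelse(ss < thresholds$lower, "depleted", "none")))

  if (!is.null(untreated)) {
    u <- untreated[!untreated$is_pseudogene, , drop = FALSE]
    repcols <- grep("^rep_screen_score_", names(u), value = TRUE)
    umin <- if (length(repcols)) {
      apply(as.matrix(u[repcols]), 1, min, na.rm = TRUE)
    } else {
      u$screen_score
    }
    umin <- stats::setNames(umin, u$gene)
    hit <- !table$is_pseudogene & cls %in% c("enriched", "depleted")
    flagged <- hit & (umin[table$gene] < untreated_floor) %in% TRUE
    waived <- ss > resistant_override | ss < hypersensitive_override
    cls[flagged & !waived] <- "excluded"
  }
  table$class <- cls
  attr(table, "thresholds") <- thresholds
  table
}

#' Quality-control in vivo (tumour) replicates by NTC dispersion
#'
#' Per tumour sample, the noise metric is the number of NTC sgRNAs whose
#' count is not within 1 log2 of the sample's median NTC count. The
#' `n_exclude` noisiest samples are dropped; survivors are paired by
#' noise-metric rank (1 with 2, 3 with 4, ...) and counts averaged after
#' matching totals.
#'
#' @param expt a `screen_experiment` whose tumour samples are columns.
#' @param manifest a `library_manifest` (identifies NTC sgRNAs).
#' @param n_exclude how many samples to drop (default 2).
#' @param log2_band half-width of the acceptance band around the median
#'   NTC count, in log2 units (default 1).
#' @return list(expt = paired-and-averaged `screen_experiment`,
#'   noise_metric = named integer vector, excluded = sample ids).
#' @export
invivo_replicate_qc <- function(expt, manifest, n_exclude = 2L,
                                log2_band = 1) {
  stopifnot(inherits(expt, "screen_experiment"))
  if (ncol(expt$counts) < n_exclude + 2L) {
    sf_stop("need at least n_exclude + 2 tumour samples",
            "screenflux_insufficient_replicates")
  }
  ntc <- expt$counts[manifest$sgrna_id[manifest$is_ntc], , drop = FALSE]
  metric <- apply(ntc, 2, function(v) {
    med <- stats::median(v)
    sum(abs(log2(v / med)) > log2_band)
  })
  ord <- order(metric)  # quietest first; ties keep column order
  keep <- ord[seq_len(length(ord) - n_exclude)]
  excluded <- colnames(expt$counts)[ord[seq(length(ord) - n_exclude + 1L,
                                            length(ord))]]
  if (length(keep) %% 2L != 0L) {
    sf_stop("surviving tumour samples cannot be paired (odd count)",
            "screenflux_insufficient_replicates")
  }
  kept_counts <- expt$counts[, keep, drop = FALSE]
  totals <- colSums(kept_counts)
  scaled <- sweep(kept_counts, 2, mean(totals) / totals, "*")
  pair_ix <- split(seq_along(keep), ceiling(seq_along(keep) / 2))
  merged <- vapply(pair_ix, function(ix) rowMeans(scaled[, ix, drop = FALSE]),
                   numeric(nrow(scaled)))
  colnames(merged) <- unname(vapply(pair_ix, function(ix) {
    paste(colnames(scaled)[ix], collapse = "+")
  }, character(1)))
  samples <- data.frame(
    sample_id = colnames(merged), arm = "tumour",
    replicate = seq_len(ncol(merged)), tech_rep = 1L, doublings = 0,
    stringsAsFactors = FALSE
  )
  list(expt = screen_experiment(merged, samples, mode = "in_vivo"),
       noise_metric = metric, excluded = excluded)
}

#' Normalize growth scores to the most depleted gene
#'
#' Divides all (real-gene) screen scores by the absolute value of the
#' most negative one, so the most depleted gene scores exactly -1; used
#' to compare in vivo screens with in vitro conditions.
#'
#' @param table a `gene_score_table`.
#' @return the rescaled table (no-op with a warning if no score is
#'   negative).
#' @export
normalize_to_most_depleted <- function(table) {
  ss <- table$screen_score[!table$is_pseudogene]
  mn <- suppressWarnings(min(ss, na.rm = TRUE))
  if (!is.finite(mn) || mn >= 0) {
    warning("no negative screen score; table left unchanged")
    return(table)
  }
  scale_cols <- c("screen_score",
                  grep("^rep_screen_score_", names(table), value = TRUE))
  for (cc in scale_cols) table[[cc]] <- table[[cc]] / abs(mn)
  table
}

#' Pairwise Pearson correlation of gene scores across conditions
#'
#' Restricts to genes significant (classed "enriched" or "depleted") in
#' at least one condition, optionally applies the magnitude display
#' filter (drop genes that never score below `mag_lower` nor above
#' `mag_upper`), then computes Pearson r and two-sided p for every
#' condition pair via [stats::cor.test()].
#'
#' @param tables named list of `gene_score_table`s (one per condition),
#'   hit classes already assigned by [call_hits()].
#' @param magnitude_filter apply the display-magnitude filter (default
#'   FALSE).
#' @param mag_lower,mag_upper magnitude filter bounds (defaults -0.20
#'   and 0.10).
#' @return list(r, p): condition x condition matrices, plus `genes`, the
#'   gene set used.
#' @export
condition_correlation <- function(tables, magnitude_filter = FALSE,
                                  mag_lower = -0.20, mag_upper = 0.10) {
  if (length(tables) < 2L) {
    sf_stop("need >= 2 condition tables", "screenflux_invalid_spec")
  }
  mats <- lapply(tables, function(t) {
    t <- t[!t$is_pseudogene, , drop = FALSE]
    stats::setNames(t$screen_score, t$gene)
  })
  genes <- Reduce(intersect, lapply(mats, names))
  sig <- Reduce(`|`, lapply(tables, function(t) {
    t <- t[!t$is_pseudogene, , drop = FALSE]
    stats::setNames(t$class %in% c("enriched", "depleted"), t$gene)[genes]
  }))
  genes <- genes[sig]
  if (magnitude_filter && length(genes)) {
    m <- vapply(mats, function(v) v[genes], numeric(length(genes)))
    m <- matrix(m, nrow = length(genes))
    keep <- apply(m, 1, function(r) any(r < mag_lower | r > mag_upper))
    genes <- genes[keep]
  }
  if (length(genes) < 3L) {
    sf_stop("fewer than 3 genes after filtering; correlation undefined",
            "screenflux_undefined_correlation")
  }
  k <- length(tables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(tables), names(tables)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      ct <- stats::cor.test(mats[[i]][genes], mats[[j]][genes],
                            method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, genes = genes)
}
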