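# sgRNA library manifest and the simulated-negative-control (pseudogene) null.

NTC_SENTINEL <- "NTC"

#' Default transporter library composition
#'
#' Gene counts by class for the transporter CRISPRi/a libraries: 413 SLC
#' genes, 28 atypical SLCs and 48 ABC transporters (489 target genes in
#' total), with 37 genes carrying two annotated transcription start
#' sites and 730 non-targeting control (NTC) sgRNAs.
#'
#' @return named list with `composition` (named integer vector of gene
#'   counts per class), `sgrnas_per_tss`, `two_tss_genes` and `n_ntc`.
#' @export
#' @examples
#' spec <- transporter_library_spec()
#' sum(spec$composition)  # 489 target genes
transporter_library_spec <- function() {
  list(
    composition = c(SLC = 413L, atypical_SLC = 28L, ABC = 48L),
    sgrnas_per_tss = 10L,
    two_tss_genes = 37L,
    n_ntc = 730L
  )
}

#' Build an sgRNA library manifest
#'
#' Constructs a manifest of sgRNA entries for a pooled CRISPRi/a library:
#' `sgrnas_per_tss` guides per transcription start site (TSS) for every
#' target gene, a stated number of genes carrying a second TSS (and hence
#' twice the guides), and a pool of non-targeting control (NTC) sgRNAs.
#' Synthetic protospacers (unique 19-20 nt A/C/G/T strings) are drawn from
#' the seeded RNG; real guide sequences are not needed for any downstream
#' computation.
#'
#' @param composition named vector/list mapping gene class (e.g. "SLC",
#'   "ABC") to the number of target genes in that class.
#' @param sgrnas_per_tss guides per TSS (default 10).
#' @param two_tss_genes how many genes carry two TSSs (default 0); these
#'   receive a "secondary" TSS block of another `sgrnas_per_tss` guides.
#' @param n_ntc number of non-targeting control sgRNAs.
#' @param seed integer seed controlling protospacer generation and the
#'   assignment of two-TSS status.
#' @return A `library_manifest`: a data.frame with columns `sgrna_id`,
#'   `gene`, `tss`, `protospacer`, `is_ntc`, `class`, plus a
#'   `composition` attribute.
#' @export
#' @examples
#' m <- build_manifest(c(SLC = 2), sgrnas_per_tss = 10, n_ntc = 20, seed = 1)
#' nrow(m)  # 2 * 10 + 20
build_manifest <- function(composition, sgrnas_per_tss = 10L,
                           two_tss_genes = 0L, n_ntc = 0L, seed = 1L) {
  composition <- unlist(composition)
  if (length(composition) == 0L || is.null(names(composition)) ||
      any(!nzchar(names(composition)))) {
    sf_stop("`composition` must be a named class -> gene-count map",
            "screenflux_invalid_spec")
  }
  if (any(composition <= 0) || any(composition != round(composition))) {
    sf_stop("all composition counts must be positive integers",
            "screenflux_invalid_spec")
  }
  assert_scalar_number(sgrnas_per_tss, "sgrnas_per_tss")
  assert_scalar_number(two_tss_genes, "two_tss_genes", allow_zero = TRUE)
  assert_scalar_number(n_ntc, "n_ntc", allow_zero = TRUE)
  n_genes <- sum(composition)
  if (two_tss_genes > n_genes) {
    sf_stop("`two_tss_genes` cannot exceed the total number of genes",
            "screenflux_invalid_spec")
  }

  classes <- rep(names(composition), composition)
  genes <- sprintf("%s%03d", classes, unlist(lapply(composition, seq_len)))

  with_seed(seed, {
    two_tss <- if (two_tss_genes > 0) sort(sample.int(n_genes, two_tss_genes)) else integer(0)
    tss_per_gene <- ifelse(seq_len(n_genes) %in% two_tss, 2L, 1L)

    gene_col <- rep(genes, tss_per_gene * sgrnas_per_tss)
    class_col <- rep(classes, tss_per_gene * sgrnas_per_tss)
    tss_col <- unlist(lapply(tss_per_gene, function(k) {
      rep(c("primary", "secondary")[seq_len(k)], each = sgrnas_per_tss)
    }))
    idx_col <- unlist(lapply(tss_per_gene, function(k) rep(seq_len(sgrnas_per_tss), k)))

    n_target <- length(gene_col)
    n_total <- n_target + n_ntc
    protospacers <- random_protospacers(n_total)

    entries <- data.frame(
      sgrna_id = c(
        sprintf("%s_%s_sg%02d", gene_col, substr(tss_col, 1, 1), idx_col),
        if (n_ntc > 0) sprintf("NTC_sg%04d", seq_len(n_ntc)) else character(0)
      ),
      gene = c(gene_col, rep(NTC_SENTINEL, n_ntc)),
      tss = c(tss_col, rep("primary", n_ntc)),
      protospacer = protospacers,
      is_ntc = c(rep(FALSE, n_target), rep(TRUE, n_ntc)),
      class = c(class_col, rep(NTC_SENTINEL, n_ntc)),
      stringsAsFactors = FALSE
    )
    stopifnot(!anyDuplicated(entries$sgrna_id))
    attr(entries, "composition") <- c(
      as.list(composition),
      list(n_genes = n_genes, two_tss_genes = as.integer(two_tss_genes),
           n_ntc = as.integer(n_ntc),
           sgrnas_per_tss = as.integer(sgrnas_per_tss))
    )
    class(entries) <- c("library_manifest", "data.frame")
    entries
  })
}

# Unique random 19-20 nt protospacers; resamples clashes.
random_protospacers <- function(n) {
  if (n == 0L) return(character(0))
  draw <- function(k) {
    lens <- sample(c(19L, 20L), k, replace = TRUE)
    vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  out
}

#' @export
print.library_manifest <- function(x, ...) {
  comp <- attr(x, "composition")
  cat(sprintf(
    "library_manifest: %d entries, %d target genes (%d with 2 TSSs), %d NTC sgRNAs\n",
    nrow(x), comp$n_genes, comp$two_tss_genes, comp$n_ntc))
  invisible(x)
}

#' Group NTC sgRNAs into simulated negative-control pseudogenes
#'
#' Builds pseudogenes by randomly grouping `size` NTC sgRNAs per
#' pseudogene from the manifest's NTC pool. Sampling is without
#' replacement within a pseudogene (members are distinct) and with
#' replacement across pseudogenes, since the NTC pool is typically too
#' small to supply disjoint groups for every real gene. Scored like real
#' genes, these calibrate the technical-noise null.
#'
#' @param manifest a `library_manifest`.
#' @param n_pseudogenes number of pseudogenes (conventionally the number
#'   of real genes scored).
#' @param size members per pseudogene (default 10).
#' @param seed integer seed; assignments are a deterministic function of
#'   (manifest, n, size, seed).
#' @return data.frame `pseudogene_id`, `member_sgrna_ids` (list column),
#'   with attribute `seed`.
#' @export
make_pseudogenes <- function(manifest, n_pseudogenes, size = 10L, seed = 1L) {
  stopifnot(inherits(manifest, "library_manifest"))
  assert_scalar_number(n_pseudogenes, "n_pseudogenes")
  assert_scalar_number(size, "size")
  ntc_ids <- manifest$sgrna_id[manifest$is_ntc]
  if (length(ntc_ids) < size) {
    sf_stop(sprintf("manifest has %d NTC sgRNAs; %d needed per pseudogene",
                    length(ntc_ids), size),
            "screenflux_insufficient_ntc")
  }
  with_seed(seed, {
    members <- lapply(seq_len(n_pseudogenes), function(i) {
      sort(sample(ntc_ids, size, replace = FALSE))
    })
    out <- data.frame(
      pseudogene_id = sprintf("pseudo_%04d", seq_len(n_pseudogenes)),
      stringsAsFactors = FALSE
    )
    out$member_sgrna_ids <- members
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("pseudogene_set", "data.frame")
    out
  })
}

#' Write / read a library manifest as CSV
#'
#' Columns: `sgrna_id,gene,tss,protospacer,is_ntc` (plus `class`).
#'
#' @param manifest a `library_manifest`.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "library_manifest"))
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sgrna_id", "gene", "tss", "protospacer", "is_ntc")
  if (!all(need %in% names(df))) {
    sf_stop(paste("manifest CSV must contain columns:",
                  paste(need, collapse = ", ")),
            "screenflux_invalid_spec")
  }
  df$is_ntc <- as.logical(df$is_ntc)
  if (!all(df$is_ntc == (df$gene == NTC_SENTINEL))) {
    sf_stop("`is_ntc` must match the NTC sentinel gene name",
            "screenflux_invalid_spec")
  }
  if (anyDuplicated(df$sgrna_id)) {
    sf_stop("duplicate sgrna_id in manifest", "screenflux_invalid_spec")
  }
  if (!"class" %in% names(df)) df$class <- ifelse(df$is_ntc, NTC_SENTINEL, "gene")
  genes <- unique(df$gene[!df$is_ntc])
  attr(df, "composition") <- list(
    n_genes = length(genes),
    two_tss_genes = sum(tapply(df$tss[!df$is_ntc], df$gene[!df$is_ntc],
                               function(t) any(t == "secondary"))),
    n_ntc = sum(df$is_ntc),
    sgrnas_per_tss = if (any(!df$is_ntc))
      max(table(paste(df$gene, df$tss)[!df$is_ntc])) else NA_integer_
  )
  class(df) <- c("library_manifest", "data.frame")
  df
}

#' Write / read pseudogene assignments as CSV
#'
#' Columns: `pseudogene_id,member_sgrna_ids` with members joined by ";".
#'
#' @param pseudogenes a `pseudogene_set`.
#' @param path file path.
#' @export
write_pseudogenes <- function(pseudogenes, path) {
  df <- data.frame(
    pseudogene_id = pseudogenes$pseudogene_id,
    member_sgrna_ids = vapply(pseudogenes$member_sgrna_ids,
                              paste, character(1), collapse = ";")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pseudogenes
#' @export
read_pseudogenes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(pseudogene_id = df$pseudogene_id, stringsAsFactors = FALSE)
  out$member_sgrna_ids <- strsplit(df$member_sgrna_ids, ";", fixed = TRUE)
  class(out) <- c("pseudogene_set", "data.frame")
  out
}
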