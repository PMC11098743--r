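# The screen experiment container: sgRNA x sample counts plus sample sheet.

#' Construct a screen experiment
#'
#' Couples an sgRNA x sample count matrix with its sample metadata.
#'
#' @param counts numeric matrix, rows named by sgRNA id, columns by
#'   sample id; non-negative.
#' @param samples data.frame with columns `sample_id`, `arm` (e.g. "T0",
#'   "untreated", "treated", "tumour"), `replicate`, `tech_rep`,
#'   `doublings` (population doublings relative to T0), and optionally
#'   `mode` ("in_vitro" or "in_vivo").
#' @param mode screen mode; in vivo screens are scored without
#'   normalization to population doublings.
#' @return A `screen_experiment` (list with `counts` and `samples`).
#' @export
screen_experiment <- function(counts, samples, mode = c("in_vitro", "in_vivo")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    sf_stop("`counts` must have sgRNA rownames and sample colnames",
            "screenflux_invalid_spec")
  }
  if (any(counts < 0)) {
    sf_stop("counts must be non-negative", "screenflux_invalid_spec")
  }
  need <- c("sample_id", "arm", "replicate", "tech_rep", "doublings")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    sf_stop(paste("sample sheet missing columns:",
                  paste(missing_cols, collapse = ", ")),
            "screenflux_invalid_spec")
  }
  if (!setequal(samples$sample_id, colnames(counts))) {
    sf_stop("sample sheet ids must match count matrix columns",
            "screenflux_invalid_spec")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (any(samples$doublings < 0)) {
    sf_stop("population doublings must be >= 0", "screenflux_invalid_design")
  }
  structure(list(counts = counts, samples = samples, mode = mode),
            class = "screen_experiment")
}

#' @export
print.screen_experiment <- function(x, ...) {
  cat(sprintf("screen_experiment (%s): %d sgRNAs x %d samples [%s]\n",
              x$mode, nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$arm), collapse = ", ")))
  invisible(x)
}

#' Read counts and sample sheet from disk
#'
#' Counts TSV: first column `sgrna_id`, remaining columns one per sample
#' (integer counts). Sample sheet CSV: columns
#' `sample_id,arm,replicate,tech_rep,doublings` and optional `mode`.
#'
#' @param counts_path path to the counts TSV.
#' @param samples_path path to the sample sheet CSV.
#' @param mode screen mode override; defaults to the sheet's `mode`
#'   column (or "in_vitro").
#' @return A `screen_experiment`.
#' @export
read_screen_experiment <- function(counts_path, samples_path, mode = NULL) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sgrna_id") {
    sf_stop("counts TSV must start with an `sgrna_id` column",
            "screenflux_invalid_spec")
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$sgrna_id
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  if (is.null(mode)) {
    mode <- if ("mode" %in% names(samples)) samples$mode[1] else "in_vitro"
  }
  screen_experiment(counts, samples, mode = mode)
}

#' Write a screen experiment's counts (TSV) and sample sheet (CSV)
#'
#' @param expt a `screen_experiment`.
#' @param counts_path,samples_path output paths.
#' @export
write_screen_experiment <- function(expt, counts_path, samples_path) {
  df <- data.frame(sgrna_id = rownames(expt$counts), expt$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  s <- expt$samples
  s$mode <- expt$mode
  utils::write.csv(s, samples_path, row.names = FALSE, quote = FALSE)
  invisible(expt)
}

#' Average technical replicates after depth normalization
#'
#' Within each (arm, replicate) group, counts are normalized to reads
#' per million and the technical replicates averaged. Groups with a
#' single technical replicate pass through (depth-normalized) unchanged.
#'
#' @param expt a `screen_experiment`.
#' @return A `screen_experiment` with one column per (arm, replicate),
#'   counts in reads-per-million units.
#' @export
average_technical_replicates <- function(expt) {
  stopifnot(inherits(expt, "screen_experiment"))
  totals <- colSums(expt$counts)
  if (any(totals == 0)) {
    sf_stop("sample with zero total reads", "screenflux_degenerate_sample")
  }
  rpm <- sweep(expt$counts, 2, totals / 1e6, "/")
  key <- paste(expt$samples$arm, expt$samples$replicate, sep = "||")
  groups <- split(seq_len(ncol(rpm)), key)
  merged <- vapply(groups, function(ix) rowMeans(rpm[, ix, drop = FALSE]),
                   numeric(nrow(rpm)))
  first <- vapply(groups, `[`, integer(1), 1L)
  samples <- expt$samples[first, , drop = FALSE]
  samples$tech_rep <- 1L
  samples$sample_id <- paste(samples$arm, samples$replicate, sep = "_rep")
  colnames(merged) <- samples$sample_id
  screen_experiment(merged, samples, mode = expt$mode)
}
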