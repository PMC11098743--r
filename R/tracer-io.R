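# Plain-text interchange for isotopologue series and standards.

#' Write / read an isotopologue series as TSV
#'
#' Columns: `amino_acid, fragment_formula, timepoint, M0..Mn, norvaline`
#' (plus `sampling_volume` when the series carries a withdrawal
#' schedule). One file per assay; assay kind, time unit and cell number
#' ride along in `#key: value` header comments.
#'
#' @param series an `isotopologue_series`.
#' @param path file path.
#' @export
write_isotopologue_series <- function(series, path) {
  stopifnot(inherits(series, "isotopologue_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#assay_kind: %s", series$assay_kind), con)
  writeLines(sprintf("#time_unit: %s", series$time_unit), con)
  writeLines(sprintf("#n_cells: %g", series$n_cells), con)
  writeLines(sprintf("#units: %s", series$units), con)
  df <- data.frame(
    amino_acid = series$amino_acid,
    fragment_formula = if (is.character(series$fragment_formula)) {
      series$fragment_formula
    } else {
      paste0(names(series$fragment_formula), series$fragment_formula,
             collapse = "")
    },
    timepoint = series$timepoints,
    series$ion_counts,
    norvaline = series$norvaline,
    check.names = FALSE
  )
  if (!is.null(series$sampling_volumes)) {
    df$sampling_volume <- series$sampling_volumes
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isotopologue_series
#' @export
read_isotopologue_series <- function(path) {
  header <- readLines(path, n = 10L)
  meta_lines <- grep("^#", header, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^#", "", l)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mcols <- grep("^M[0-9]+$", names(df), value = TRUE)
  series <- isotopologue_series(
    amino_acid = df$amino_acid[1],
    fragment_formula = df$fragment_formula[1],
    timepoints = df$timepoint,
    ion_counts = as.matrix(df[mcols]),
    norvaline = df$norvaline,
    assay_kind = meta$assay_kind %||% "import",
    time_unit = meta$time_unit,
    sampling_volumes = df$sampling_volume,
    n_cells = as.numeric(meta$n_cells %||% 0.64e6)
  )
  series$units <- meta$units %||% "ion_counts"
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a standards table as CSV
#'
#' Columns: `amino_acid, pmol, ion_counts, norvaline`.
#'
#' @param standards standards data.frame.
#' @param path file path.
#' @export
write_standards <- function(standards, path) {
  utils::write.csv(standards, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_standards
#' @export
read_standards <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
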