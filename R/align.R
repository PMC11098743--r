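# Exact-match protospacer counting from FASTQ reads.

#' Count sgRNAs from FASTQ reads or load a counts table
#'
#' For FASTQ input (gzip accepted), the protospacer is taken at a fixed
#' offset/length within each read and matched exactly against the
#' manifest's protospacers; reads matching no protospacer are tallied
#' and the alignment rate reported. For TSV input the table is loaded
#' as-is (see [read_screen_experiment()] for the paired-sample-sheet
#' variant).
#'
#' @param path FASTQ file (".fastq"/".fq", optionally ".gz") or counts
#'   TSV.
#' @param manifest a `library_manifest`.
#' @param sample_id name for the resulting count column (FASTQ input).
#' @param offset 0-based position of the protospacer within the read.
#' @param length protospacer length to extract; defaults to matching
#'   each manifest protospacer against a prefix of the extracted window
#'   of the longest protospacer length.
#' @return list(counts = named integer vector over manifest sgRNAs,
#'   n_reads, n_aligned, alignment_rate) for FASTQ input; a
#'   `screen_experiment`-style count matrix for TSV input.
#' @export
align_or_load_counts <- function(path, manifest, sample_id = "sample",
                                 offset = 0L, length = NULL) {
  stopifnot(inherits(manifest, "library_manifest"))
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    raw_lines <- readLines(con)
    close(con)
    raw_lines <- raw_lines[seq_len(max(which(nzchar(raw_lines)), 0L))]
    if (length(raw_lines) %% 4L != 0L) {
      sf_stop(sprintf("malformed FASTQ: truncated record %d",
                      length(raw_lines) %/% 4L + 1L),
              "screenflux_parse_error")
    }
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
      error = function(e) {
        sf_stop(paste("malformed FASTQ:", conditionMessage(e)),
                "screenflux_parse_error")
      })
    protos <- manifest$protospacer
    lens <- sort(unique(nchar(protos)), decreasing = TRUE)
    if (is.null(length)) length <- max(lens)
    window <- substr(reads, offset + 1L, offset + length)
    # exact-match policy: try each protospacer length, longest first
    hit <- rep(NA_integer_, base::length(reads))
    for (l in lens) {
      idx <- which(is.na(hit))
      if (!base::length(idx)) break
      m <- match(substr(window[idx], 1L, l), protos)
      m[!is.na(m)][nchar(protos[m[!is.na(m)]]) != l] <- NA_integer_
      hit[idx] <- m
    }
    counts <- tabulate(hit, nbins = nrow(manifest))
    names(counts) <- manifest$sgrna_id
    n_aligned <- sum(!is.na(hit))
    list(counts = counts, n_reads = base::length(reads),
         n_aligned = n_aligned,
         alignment_rate = n_aligned / base::length(reads),
         sample_id = sample_id)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
    counts
  }
}
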