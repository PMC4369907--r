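#' Fragment-count matrix with sample metadata
#'
#' Light container for an integer matrix of fragment counts (transcripts in
#' rows, samples in columns) plus the per-transcript lengths and per-sample
#' design metadata needed for FPKM normalization and per-line testing.
#'
#' Sample codes follow the 12-sample design of the experiment: `SC`/`ST` are
#' control/treatment of the heat-sensitive line (HS), `TC`/`TT` are
#' control/treatment of the heat-tolerant line (HT), each with numbered
#' biological replicates (e.g. `SC1`, `SC2`, `SC3`).
#'
#' @param counts Numeric matrix, transcripts x samples, non-negative counts.
#'   Row names are transcript ids, column names are sample codes.
#' @param lengths Integer vector of transcript lengths in bp, one per row.
#' @param samples Optional data.frame with columns `sample_id`, `line`
#'   (`"HS"`/`"HT"`), `condition` (`"control"`/`"treatment"`), `replicate`.
#'   If omitted it is derived from the column-name codes.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `lengths` and `samples`.
#' @export
count_matrix <- function(counts, lengths, samples = NULL) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must be a matrix with transcript row names and sample column names")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (length(lengths) != nrow(counts)) {
    stop("'lengths' must have one entry per transcript")
  }
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (is.null(samples)) samples <- parse_sample_codes(colnames(counts))
  if (!identical(samples$sample_id, colnames(counts))) {
    stop("sample metadata does not match count matrix columns")
  }
  structure(
    list(counts = counts, lengths = stats::setNames(lengths, rownames(counts)),
         samples = samples),
    class = "count_matrix"
  )
}

# Decode SC/ST/TC/TT + replicate-number sample codes into design metadata.
parse_sample_codes <- function(codes) {
  prefix <- substr(codes, 1, 2)
  ok <- prefix %in% c("SC", "ST", "TC", "TT")
  if (!all(ok)) {
    stop("unrecognized sample code(s): ", paste(codes[!ok], collapse = ", "))
  }
  data.frame(
    sample_id = codes,
    line = ifelse(substr(codes, 1, 1) == "S", "HS", "HT"),
    condition = ifelse(substr(codes, 2, 2) == "C", "control", "treatment"),
    replicate = as.integer(substr(codes, 3, nchar(codes))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x", ncol(x$counts), "samples\n")
  cat("samples:", paste(x$samples$sample_id, collapse = " "), "\n")
  cat("library sizes:", paste(format(colSums(x$counts), big.mark = ","), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The on-disk layout is one row per transcript with columns `transcript_id`,
#' `length_bp`, then one column per sample.
#'
#' @param x A [count_matrix()].
#' @param path File path of the TSV.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns a
#'   [count_matrix()].
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(
    transcript_id = rownames(x$counts),
    length_bp = as.integer(x$lengths),
    x$counts,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("transcript_id", "length_bp")
  if (!all(needed %in% names(df))) {
    stop("counts TSV must have 'transcript_id' and 'length_bp' columns")
  }
  sample_cols <- setdiff(names(df), needed)
  m <- as.matrix(df[sample_cols])
  rownames(m) <- df$transcript_id
  count_matrix(m, df$length_bp)
}
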