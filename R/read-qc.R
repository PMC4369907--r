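#' Read-filtering thresholds
#'
#' Encodes the filtering rules applied to raw reads before assembly: reads
#' are discarded when the fraction of `N` calls exceeds `max_n_fraction`
#' (strictly over), or when the fraction of bases with Phred quality below
#' `q_cutoff` exceeds `max_lowq_fraction` (strictly over). An optional
#' adapter sequence is trimmed first (exact substring match, trimmed from
#' the first occurrence to the read end); reads left empty are discarded as
#' `adapter_empty`.
#'
#' @param max_n_fraction Maximum tolerated `N` fraction (default 0.05).
#' @param q_cutoff Phred score below which a base counts as low quality
#'   (default 20).
#' @param max_lowq_fraction Maximum tolerated low-quality-base fraction
#'   (default 0.20).
#' @param adapter Optional adapter sequence to trim; `NULL` to skip.
#' @param phred_offset Quality encoding offset; 33 for Phred+33 (CASAVA >=
#'   1.8), 64 for legacy Phred+64.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_n_fraction = 0.05, q_cutoff = 20,
                          max_lowq_fraction = 0.20, adapter = NULL,
                          phred_offset = 33L) {
  if (max_n_fraction < 0 || max_n_fraction > 1 ||
      max_lowq_fraction < 0 || max_lowq_fraction > 1) {
    stop("fraction thresholds must be in [0, 1]")
  }
  if (q_cutoff < 0) stop("'q_cutoff' must be >= 0")
  if (!phred_offset %in% c(33L, 64L)) stop("'phred_offset' must be 33 or 64")
  structure(
    list(max_n_fraction = max_n_fraction, q_cutoff = q_cutoff,
         max_lowq_fraction = max_lowq_fraction, adapter = adapter,
         phred_offset = as.integer(phred_offset)),
    class = "qc_thresholds"
  )
}

#' Decode a quality character to its Phred score
#'
#' @param ch Character vector of single quality characters.
#' @param offset Encoding offset (33 for Phred+33).
#' @return Integer Phred score(s): `ascii(ch) - offset`.
#' @examples
#' q_from_char("!") # 0
#' q_from_char("I") # 40
#' @export
q_from_char <- function(ch, offset = 33L) {
  codes <- vapply(ch, function(x) {
    if (nchar(x) != 1L) stop("'ch' must contain single characters")
    utf8ToInt(x)
  }, integer(1), USE.NAMES = FALSE)
  if (any(codes < 33L)) stop("quality characters must be printable ASCII >= '!'")
  codes - as.integer(offset)
}

#' Decode a whole quality string to Phred scores
#'
#' @param quality Quality string (one read).
#' @param offset Encoding offset.
#' @return Integer vector of per-base Phred scores.
#' @export
phred_scores <- function(quality, offset = 33L) {
  codes <- utf8ToInt(quality)
  if (any(codes < 33L)) stop("quality characters must be printable ASCII >= '!'")
  codes - as.integer(offset)
}

#' Filter a single read
#'
#' Applies the filtering rules in fixed order: adapter trim, empty-read
#' check, `N`-fraction rule, low-quality-fraction rule. Both fraction rules
#' are strict inequalities ("over 5%", "more than 20%"), so a 100-bp read
#' with exactly 5 `N`s is kept.
#'
#' @param sequence Read sequence over `A`/`C`/`G`/`T`/`N`.
#' @param quality Quality string of equal length.
#' @param thresholds A [qc_thresholds()].
#' @return List with `keep` (logical), `reason` (`NA` if kept, else one of
#'   `"adapter_empty"`, `"n_fraction"`, `"lowq_fraction"`), and the possibly
#'   trimmed `sequence`/`quality`.
#' @export
filter_read <- function(sequence, quality, thresholds = qc_thresholds()) {
  res <- filter_reads(
    data.frame(sequence = sequence, quality = quality, stringsAsFactors = FALSE),
    thresholds
  )
  list(keep = res$keep, reason = res$reason,
       sequence = res$sequence, quality = res$quality)
}

#' Filter many reads at once
#'
#' Vectorized form of [filter_read()]; operates on a data.frame of reads as
#' produced by [simulate_reads()] or [read_fastq()].
#'
#' @param reads data.frame with `sequence` and `quality` columns.
#' @param thresholds A [qc_thresholds()].
#' @return The input with `sequence`/`quality` possibly trimmed and added
#'   columns `keep` and `reason`.
#' @export
filter_reads <- function(reads, thresholds = qc_thresholds()) {
  t <- thresholds
  seqs <- reads$sequence
  quals <- reads$quality
  if (any(nchar(seqs) != nchar(quals))) {
    stop("sequence/quality length mismatch")
  }
  if (!is.null(t$adapter) && nzchar(t$adapter)) {
    pos <- regexpr(t$adapter, seqs, fixed = TRUE)
    hit <- pos > 0L
    seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
    quals[hit] <- substr(quals[hit], 1L, pos[hit] - 1L)
  }
  len <- nchar(seqs)
  n_count <- len - nchar(gsub("N", "", seqs, fixed = TRUE))
  lowq_count <- vapply(quals, function(q) {
    codes <- utf8ToInt(q)
    if (any(codes < 33L)) stop("quality characters must be printable ASCII >= '!'")
    sum(codes - t$phred_offset < t$q_cutoff)
  }, integer(1), USE.NAMES = FALSE)

  reason <- rep(NA_character_, length(seqs))
  reason[len > 0 & lowq_count / pmax(len, 1L) > t$max_lowq_fraction] <- "lowq_fraction"
  reason[len > 0 & n_count / pmax(len, 1L) > t$max_n_fraction] <- "n_fraction"
  reason[len == 0L] <- "adapter_empty"

  reads$sequence <- seqs
  reads$quality <- quals
  reads$keep <- is.na(reason)
  reads$reason <- reason
  reads
}

#' Pair filtering policy: keep a pair only if both mates pass
#'
#' @param r1,r2 Lists (or one-row data.frames) with `sequence`, `quality`
#'   and optionally `read_id`; mates must share the read-id stem.
#' @param thresholds A [qc_thresholds()].
#' @return `TRUE` to keep the pair, `FALSE` to discard it.
#' @export
filter_pair <- function(r1, r2, thresholds = qc_thresholds()) {
  if (!is.null(r1$read_id) && !is.null(r2$read_id) &&
      sub("/[12]$", "", r1$read_id) != sub("/[12]$", "", r2$read_id)) {
    stop("mate read ids do not match")
  }
  filter_read(r1$sequence, r1$quality, thresholds)$keep &&
    filter_read(r2$sequence, r2$quality, thresholds)$keep
}

#' Per-sample QC summary
#'
#' Tallies keep/discard decisions into the per-sample layout of a sequencing
#' summary table: raw reads, high-quality reads, HQ percentage (2 dp,
#' half-away-from-zero), and discard counts per reason.
#'
#' @param x Either the data.frame returned by [filter_reads()], or a named
#'   integer vector of pre-computed tallies over
#'   `c(kept, adapter_empty, n_fraction, lowq_fraction)` (absent reasons
#'   default to zero).
#' @param sample_id Sample label for the summary row.
#' @return One-row data.frame: `sample_id`, `raw_reads`,
#'   `high_quality_reads`, `hq_percent`, `adapter_empty`, `n_fraction`,
#'   `lowq_fraction`.
#' @export
qc_summarize <- function(x, sample_id = "sample") {
  reasons <- c("adapter_empty", "n_fraction", "lowq_fraction")
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop("no reads to summarize")
    tallies <- c(kept = sum(x$keep),
                 vapply(reasons, function(r) sum(!is.na(x$reason) & x$reason == r),
                        numeric(1)))
  } else {
    if (is.null(names(x)) || !"kept" %in% names(x)) {
      stop("tallies must be named and include 'kept'")
    }
    tallies <- stats::setNames(rep(0, 4), c("kept", reasons))
    tallies[names(x)] <- x
    if (sum(tallies) == 0) stop("no reads to summarize")
  }
  raw <- sum(tallies)
  data.frame(
    sample_id = sample_id,
    raw_reads = raw,
    high_quality_reads = unname(tallies[["kept"]]),
    hq_percent = round_half_up(100 * tallies[["kept"]] / raw, 2),
    adapter_empty = unname(tallies[["adapter_empty"]]),
    n_fraction = unname(tallies[["n_fraction"]]),
    lowq_fraction = unname(tallies[["lowq_fraction"]]),
    stringsAsFactors = FALSE
  )
}

#' Read / write 4-line FASTQ
#'
#' Thin wrappers over Biostrings' quality-aware FASTQ support, converting to
#' and from the plain data.frame representation used by the filtering
#' functions.
#'
#' @param path FASTQ file path (optionally gzipped on read).
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @return `read_fastq` returns a data.frame (`read_id`, `sequence`,
#'   `quality`); `write_fastq` returns `path` invisibly.
#' @export
read_fastq <- function(path) {
  # the loader warns when dropping the (empty) metadata columns it attaches
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$read_id
  # the constructor warns about dropping (empty) metadata columns
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    s, Biostrings::PhredQuality(reads$quality)
  ))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
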