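# Descriptive statistics in the layout of per-sample sequencing summary
# tables: read/mapping aggregation, assembly statistics with N50, and the
# genomic-region breakdown of mapped positions.

#' N50 of a set of transcript lengths
#'
#' The largest length `L` such that transcripts of length >= `L` together
#' contain at least half of all assembled bases. Computed by sorting in
#' decreasing order and accumulating.
#'
#' @param lengths Positive lengths in bp, non-empty.
#' @return The N50 in bp.
#' @examples
#' n50(c(5, 4, 3, 2, 1)) # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("'lengths' must be non-empty")
  if (any(lengths <= 0)) stop("'lengths' must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))   # numeric accumulator: no integer overflow
  s[which(cs >= cs[length(cs)] / 2)[1]]
}

#' Known/novel split of assembled transcripts
#'
#' Counts and 2-dp percentages of annotated ("known") versus unannotated
#' ("novel") transcripts from a total and a known count. Used by
#' [assembly_summary()] and directly applicable to printed per-sample
#' assembly rows.
#'
#' @param n_total Total assembled transcripts.
#' @param known_count How many matched annotated genes.
#' @return One-row data.frame: `known_count`, `known_percent`,
#'   `novel_count`, `novel_percent`.
#' @export
known_novel_split <- function(n_total, known_count) {
  novel_count <- n_total - known_count
  data.frame(
    known_count = known_count,
    known_percent = round_half_up(100 * known_count / n_total, 2),
    novel_count = novel_count,
    novel_percent = round_half_up(100 * novel_count / n_total, 2)
  )
}

#' Assembly summary for one sample
#'
#' Transcript count, mean length (1 dp), N50, and the known/novel split with
#' 2-dp percentages and distinct gene counts per class.
#'
#' @param lengths Transcript lengths in bp.
#' @param known Logical (or 0/1) flag per transcript: matches an annotated
#'   gene.
#' @param gene_ids Gene id per transcript (for distinct-gene counts).
#' @param sample_id Label for the summary row.
#' @return One-row data.frame: `sample_id`, `n_transcripts`, `average_size`,
#'   `n50`, `known_count`, `known_percent`, `known_genes`, `novel_count`,
#'   `novel_percent`, `novel_genes`.
#' @export
assembly_summary <- function(lengths, known, gene_ids, sample_id = "sample") {
  n <- length(lengths)
  if (length(known) != n || length(gene_ids) != n) {
    stop("'lengths', 'known' and 'gene_ids' must be aligned vectors")
  }
  known <- as.logical(known)
  split <- known_novel_split(n, sum(known))
  data.frame(
    sample_id = sample_id,
    n_transcripts = n,
    average_size = round_half_up(mean(lengths), 1),
    n50 = n50(lengths),
    split[c("known_count", "known_percent")],
    known_genes = length(unique(gene_ids[known])),
    split[c("novel_count", "novel_percent")],
    novel_genes = length(unique(gene_ids[!known])),
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-sample read statistics into a totals row
#'
#' Sums raw, high-quality and mapped read counts over samples and recomputes
#' the percentages from the summed numerators and denominators (not by
#' averaging per-sample percentages): HQ% against raw reads, mapped% against
#' high-quality reads, both at 2 dp.
#'
#' @param stats data.frame with columns `raw_reads`, `hq_reads`,
#'   `mapped_reads` (one row per sample).
#' @return One-row data.frame: `sample_id = "Total"`, summed counts, and
#'   `hq_percent`, `mapped_percent`.
#' @export
aggregate_read_stats <- function(stats) {
  needed <- c("raw_reads", "hq_reads", "mapped_reads")
  if (nrow(stats) < 1L || !all(needed %in% names(stats))) {
    stop("'stats' needs >= 1 row and columns raw_reads, hq_reads, mapped_reads")
  }
  raw <- sum(as.numeric(stats$raw_reads))
  hq <- sum(as.numeric(stats$hq_reads))
  mapped <- sum(as.numeric(stats$mapped_reads))
  data.frame(
    sample_id = "Total",
    raw_reads = raw,
    hq_reads = hq,
    hq_percent = round_half_up(100 * hq / raw, 2),
    mapped_reads = mapped,
    mapped_percent = round_half_up(100 * mapped / hq, 2),
    stringsAsFactors = FALSE
  )
}

#' Tally mapped positions by genomic region
#'
#' @param x Either a character vector with one region label per mapped
#'   position, or a named numeric vector of pre-tallied counts. Valid
#'   regions: `exon`, `intron`, `intergenic`, `spliced`.
#' @param sample_id Label for the row.
#' @return One-row data.frame with `total_positions`, then count and 2-dp
#'   percent columns per region (`exon`, `exon_percent`, ...).
#' @export
region_tally <- function(x, sample_id = "sample") {
  regions <- c("exon", "intron", "intergenic", "spliced")
  if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(x) %in% regions)) {
      stop("pre-tallied counts must be named over: ", paste(regions, collapse = ", "))
    }
    counts <- stats::setNames(rep(0, 4), regions)
    counts[names(x)] <- x
  } else {
    if (length(x) == 0L) stop("no mapped positions to tally")
    if (!all(x %in% regions)) {
      stop("unknown region label(s): ", paste(unique(setdiff(x, regions)), collapse = ", "))
    }
    counts <- as.vector(table(factor(x, levels = regions)))
    names(counts) <- regions
  }
  total <- sum(counts)
  out <- data.frame(sample_id = sample_id, total_positions = total,
                    stringsAsFactors = FALSE)
  for (r in regions) {
    out[[r]] <- unname(counts[[r]])
    out[[paste0(r, "_percent")]] <- round_half_up(100 * counts[[r]] / total, 2)
  }
  out
}
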