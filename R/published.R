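# Loaders for the published per-sample summary tables of the rice high
# night temperature RNA-seq study (heat-tolerant line XN0437T vs
# heat-sensitive line XN0437S; 2 lines x treatment/control x 3 biological
# replicates). These printed per-sample rows are inputs to the aggregation
# functions; the totals and percentages they imply are recomputed, never
# stored.

published_table <- function(name) {
  path <- system.file("extdata", name, package = "riceHNT", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published per-sample summary tables
#'
#' Per-sample rows as printed in the study's summary tables:
#' \describe{
#'   \item{`hnt_read_stats()`}{raw, high-quality and genome-mapped read
#'     counts with percentages, per sample;}
#'   \item{`hnt_region_stats()`}{mapped positions split across exonic,
#'     intronic, intergenic and spliced regions;}
#'   \item{`hnt_assembly_stats()`}{assembled transcript counts, average
#'     size, N50, and the known/novel split with distinct gene counts;}
#'   \item{`hnt_deg_counts()`}{differentially expressed transcript counts
#'     per line and direction (`set` `"deg_hs"`/`"deg_ht"`), the cross-line
#'     overlap classes of all DEGs (`"deg_overlap"`), and the pattern
#'     classes of the 35 selected high night temperature response
#'     transcripts (`"htrt"`).}
#' }
#'
#' @return A data.frame (layout described above).
#' @name published_tables
NULL

#' @rdname published_tables
#' @export
hnt_read_stats <- function() published_table("read_stats.tsv")

#' @rdname published_tables
#' @export
hnt_region_stats <- function() published_table("region_stats.tsv")

#' @rdname published_tables
#' @export
hnt_assembly_stats <- function() published_table("assembly_stats.tsv")

#' @rdname published_tables
#' @export
hnt_deg_counts <- function() published_table("deg_class_counts.tsv")
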