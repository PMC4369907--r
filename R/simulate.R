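#' Configuration for the synthetic two-line expression experiment
#'
#' Defines the study conditions emulated by [simulate_experiment()]: a
#' 2-line x 2-condition design with biological replicates, negative-binomial
#' fragment counts, and planted cross-line effect classes.
#'
#' The four transcript classes are:
#' \describe{
#'   \item{null}{no planted effect in either line;}
#'   \item{concordant_equal}{same direction and equal |log2FC| in both lines
#'     (responds to the stress, but identically in the two lines);}
#'   \item{concordant_divergent}{same direction, clearly different |log2FC|
#'     (a tolerance-associated magnitude difference);}
#'   \item{discordant}{opposite directions in the two lines.}
#' }
#'
#' Class counts are allocated deterministically: each non-null class gets
#' `floor(proportion * n_transcripts)` transcripts and the remainder goes to
#' the null class.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param n_reps Biological replicates per line x condition cell (>= 2).
#' @param class_proportions Named fractions over the four classes; must sum
#'   to 1.
#' @param base_mean Mean fragment count per transcript under control.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param effect_log2 Named list giving the planted |log2 fold change| per
#'   non-null class as `c(hs = ..., ht = ...)` for the heat-sensitive and
#'   heat-tolerant lines.
#' @param transcript_length_range Two-element bp interval for transcript
#'   lengths (sampled uniformly).
#' @param seed Integer seed; one seed feeds fixed per-stream sub-seeds so the
#'   generated lengths, signs and counts are each independently reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000,
                       n_reps = 3,
                       class_proportions = c(null = 0.85,
                                             concordant_equal = 0.05,
                                             concordant_divergent = 0.05,
                                             discordant = 0.05),
                       base_mean = 500,
                       dispersion = 0.05,
                       effect_log2 = list(
                         concordant_equal = c(hs = 1.5, ht = 1.5),
                         concordant_divergent = c(hs = 1.0, ht = 3.2),
                         discordant = c(hs = 1.8, ht = 2.4)
                       ),
                       transcript_length_range = c(500L, 3000L),
                       seed = 1L) {
  classes <- c("null", "concordant_equal", "concordant_divergent", "discordant")
  stop_if_not_scalar_number(n_transcripts, "n_transcripts")
  stop_if_not_scalar_number(dispersion, "dispersion")
  if (n_reps < 2) stop("'n_reps' must be >= 2")
  if (!all(classes %in% names(class_proportions))) {
    stop("'class_proportions' must be named over: ", paste(classes, collapse = ", "))
  }
  class_proportions <- class_proportions[classes]
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9) {
    stop("'class_proportions' must be non-negative and sum to 1")
  }
  if (dispersion <= 0) stop("'dispersion' must be > 0")
  if (base_mean <= 0) stop("'base_mean' must be > 0")
  for (cl in setdiff(classes, "null")) {
    e <- effect_log2[[cl]]
    if (is.null(e) || !all(c("hs", "ht") %in% names(e)) || any(e < 0)) {
      stop("'effect_log2$", cl, "' must supply non-negative c(hs=, ht=) magnitudes")
    }
  }
  if (length(transcript_length_range) != 2 || any(transcript_length_range < 1) ||
      transcript_length_range[1] > transcript_length_range[2]) {
    stop("'transcript_length_range' must be an increasing positive bp interval")
  }
  structure(
    list(n_transcripts = as.integer(n_transcripts), n_reps = as.integer(n_reps),
         class_proportions = class_proportions, base_mean = base_mean,
         dispersion = dispersion, effect_log2 = effect_log2,
         transcript_length_range = as.integer(transcript_length_range),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate the two-line count experiment with planted ground truth
#'
#' Draws negative-binomial fragment counts for the 4 x `n_reps` sample design
#' (`SC*`, `ST*`, `TC*`, `TT*`). Treatment means are the control mean shifted
#' by the planted signed log2 effect of the transcript's class in that line;
#' each non-null transcript gets a random regulation sign (shared between
#' lines for concordant classes, flipped between lines for discordant ones).
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{a [count_matrix()];}
#'     \item{truth}{a data.frame (`transcript_id`, `class`,
#'       `planted_log2_HS`, `planted_log2_HT`, `true_rfc`) where `true_rfc`
#'       is the RFC implied by the planted magnitudes (`NA` for null).}
#'   }
#' @seealso [sim_config()], [compute_fpkm()], [select_htrts()]
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  n <- config$n_transcripts
  props <- config$class_proportions
  n_ce <- floor(props[["concordant_equal"]] * n)
  n_cd <- floor(props[["concordant_divergent"]] * n)
  n_disc <- floor(props[["discordant"]] * n)
  n_null <- n - n_ce - n_cd - n_disc
  class <- rep(c("null", "concordant_equal", "concordant_divergent", "discordant"),
               times = c(n_null, n_ce, n_cd, n_disc))
  ids <- sprintf("T%05d", seq_len(n))

  set.seed(stream_seed(config$seed, "lengths"))
  lr <- config$transcript_length_range
  lengths <- sample(seq(lr[1], lr[2]), n, replace = TRUE)

  set.seed(stream_seed(config$seed, "signs"))
  sgn <- sample(c(-1, 1), n, replace = TRUE)

  mag_hs <- mag_ht <- numeric(n)
  for (cl in c("concordant_equal", "concordant_divergent", "discordant")) {
    idx <- class == cl
    mag_hs[idx] <- config$effect_log2[[cl]][["hs"]]
    mag_ht[idx] <- config$effect_log2[[cl]][["ht"]]
  }
  planted_hs <- ifelse(class == "discordant", -sgn, sgn) * mag_hs
  planted_ht <- sgn * mag_ht
  planted_hs[class == "null"] <- 0
  planted_ht[class == "null"] <- 0

  true_rfc <- rep(NA_real_, n)
  nonnull <- class != "null"
  if (any(nonnull)) {
    true_rfc[nonnull] <- rfc_value(planted_hs[nonnull], planted_ht[nonnull],
                                   concordant = class[nonnull] != "discordant")$rfc
  }
  truth <- data.frame(
    transcript_id = ids, class = class,
    planted_log2_HS = planted_hs, planted_log2_HT = planted_ht,
    true_rfc = true_rfc, stringsAsFactors = FALSE
  )

  codes <- as.vector(vapply(c("SC", "ST", "TC", "TT"),
                            function(p) paste0(p, seq_len(config$n_reps)),
                            character(config$n_reps)))
  samples <- parse_sample_codes(codes)

  set.seed(stream_seed(config$seed, "counts"))
  counts <- matrix(0, nrow = n, ncol = length(codes),
                   dimnames = list(ids, codes))
  size <- 1 / config$dispersion
  for (j in seq_along(codes)) {
    planted <- if (samples$line[j] == "HS") planted_hs else planted_ht
    mu <- config$base_mean *
      2^(planted * (samples$condition[j] == "treatment"))
    counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
  }
  storage.mode(counts) <- if (max(counts) < .Machine$integer.max) "integer" else "double"

  list(counts = count_matrix(counts, lengths, samples), truth = truth)
}

#' Simulate paired-end reads with per-read QC ground truth
#'
#' Generates `n_pairs` mate pairs of fixed length. Each base is `N` with
#' probability `n_base_rate`; each base's Phred quality is drawn from a
#' low-quality band (Q 2-19) with probability `lowq_rate` and a high-quality
#' band (Q 30-40) otherwise, emulating the bimodal quality profile of
#' Illumina base calls. The `should_pass` label is computed here by applying
#' the filtering rules directly to the generated base/quality arrays, so it
#' is an oracle independent of [filter_read()]'s string parsing.
#'
#' @param n_pairs Number of read pairs.
#' @param read_len Read length in bp (default 101, HiSeq 2000 2x101 bp).
#' @param n_base_rate Per-base probability of an `N` call.
#' @param lowq_rate Per-base probability of a low-quality call.
#' @param seed Integer seed.
#' @param thresholds [qc_thresholds()] used for the truth labels.
#' @return data.frame with columns `read_id`, `mate` (1/2), `sequence`,
#'   `quality` (Phred+33), `should_pass`; rows ordered pair by pair.
#' @export
simulate_reads <- function(n_pairs, read_len = 101, n_base_rate = 0,
                           lowq_rate = 0, seed = 1,
                           thresholds = qc_thresholds()) {
  if (n_pairs < 1 || read_len < 1) stop("'n_pairs' and 'read_len' must be >= 1")
  if (n_base_rate < 0 || n_base_rate > 1 || lowq_rate < 0 || lowq_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  n_reads <- 2L * as.integer(n_pairs)
  total <- n_reads * as.integer(read_len)

  set.seed(stream_seed(seed, "read_bases"))
  base <- matrix(sample(c("A", "C", "G", "T"), total, replace = TRUE), nrow = n_reads)
  is_n <- matrix(stats::runif(total) < n_base_rate, nrow = n_reads)
  base[is_n] <- "N"

  set.seed(stream_seed(seed, "read_quality"))
  is_low <- matrix(stats::runif(total) < lowq_rate, nrow = n_reads)
  q <- matrix(0L, nrow = n_reads, ncol = read_len)
  q[is_low] <- sample(2:19, sum(is_low), replace = TRUE)
  q[!is_low] <- sample(30:40, sum(!is_low), replace = TRUE)

  # truth labels straight from the generated arrays (strict > rules)
  n_frac <- rowSums(is_n) / read_len
  lowq_frac <- rowSums(q < thresholds$q_cutoff) / read_len
  should_pass <- n_frac <= thresholds$max_n_fraction &
    lowq_frac <= thresholds$max_lowq_fraction

  qchars <- vapply(0:93, function(i) rawToChar(as.raw(i + 33L)), character(1))
  sequence <- do.call(paste0, as.data.frame(base, stringsAsFactors = FALSE))
  quality <- do.call(paste0, as.data.frame(matrix(qchars[q + 1L], nrow = n_reads),
                                           stringsAsFactors = FALSE))
  data.frame(
    read_id = sprintf("read_%06d", rep(seq_len(n_pairs), each = 2L)),
    mate = rep(1:2, n_pairs),
    sequence = sequence, quality = quality, should_pass = should_pass,
    stringsAsFactors = FALSE
  )
}

#' Simulate qPCR Ct values from planted expression effects
#'
#' Emulates the validation assay: for each gene the target Ct under
#' treatment is shifted by minus the planted log2 effect relative to control
#' (ideal amplification efficiency of 2, i.e. one cycle per doubling of
#' template), while the reference gene (ACT1-like) Ct is constant up to
#' Gaussian technical noise.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param line Which line's planted effect drives the shift (`"HS"`/`"HT"`).
#' @param genes Subset of transcript ids to assay (default: all).
#' @param base_ct Target-gene Ct under control, in cycles.
#' @param ref_ct Reference-gene Ct, in cycles.
#' @param noise_sd SD of Gaussian technical noise in cycles (>= 0).
#' @param n_tech Technical replicates per gene x condition.
#' @param seed Integer seed.
#' @return data.frame with columns `gene`, `condition`, `replicate`,
#'   `target_ct`, `reference_ct`.
#' @seealso [qpcr_relative_expression()]
#' @export
simulate_ct <- function(truth, line = c("HS", "HT"), genes = NULL,
                        base_ct = 25, ref_ct = 18, noise_sd = 0.15,
                        n_tech = 3, seed = 1) {
  line <- match.arg(line)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(genes)) genes <- truth$transcript_id
  planted_col <- if (line == "HS") "planted_log2_HS" else "planted_log2_HT"
  planted <- truth[[planted_col]][match(genes, truth$transcript_id)]
  if (anyNA(planted)) stop("some 'genes' are absent from the truth table")

  grid <- expand.grid(
    replicate = seq_len(n_tech), condition = c("control", "treatment"),
    gene = genes, stringsAsFactors = FALSE
  )[, c("gene", "condition", "replicate")]
  shift <- ifelse(grid$condition == "treatment",
                  -planted[match(grid$gene, genes)], 0)
  set.seed(stream_seed(seed, "ct"))
  grid$target_ct <- base_ct + shift + stats::rnorm(nrow(grid), 0, noise_sd)
  grid$reference_ct <- ref_ct + stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}
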