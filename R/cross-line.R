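# Cross-line pattern classification and Relative Fold Change selection: the
# statistic that contrasts how strongly the heat-tolerant (HT) and
# heat-sensitive (HS) lines respond to the same night-temperature stress.

#' The nine cross-line expression pattern classes
#'
#' @return Character vector of the pattern levels in canonical order.
#' @export
pattern_levels <- function() {
  c("up_both", "down_both", "upT_downS", "downT_upS",
    "HS_only_up", "HS_only_down", "HT_only_up", "HT_only_down", "neither")
}

#' Classify a transcript's cross-line expression pattern
#'
#' Deterministic 3x3 mapping of per-line regulation directions to nine
#' classes. Argument order is fixed as (HS, HT): `classify_pattern("up",
#' "down")` is `downT_upS` (down in the tolerant line, up in the sensitive
#' line).
#'
#' @param dir_hs,dir_ht Regulation direction in the heat-sensitive and
#'   heat-tolerant lines; each `"up"`, `"down"` or `"none"`. Vectorized.
#' @return Character vector of pattern labels (see [pattern_levels()]).
#' @export
classify_pattern <- function(dir_hs, dir_ht) {
  valid <- c("up", "down", "none")
  if (!all(dir_hs %in% valid) || !all(dir_ht %in% valid)) {
    stop("directions must be 'up', 'down' or 'none'")
  }
  map <- c(
    "up.up" = "up_both", "down.down" = "down_both",
    "down.up" = "upT_downS", "up.down" = "downT_upS",
    "up.none" = "HS_only_up", "down.none" = "HS_only_down",
    "none.up" = "HT_only_up", "none.down" = "HT_only_down",
    "none.none" = "neither"
  )
  unname(map[paste(dir_hs, dir_ht, sep = ".")])
}

#' Relative Fold Change between the two lines' log2 responses
#'
#' Three-case statistic over the per-line log2 fold changes, computed on
#' magnitudes `a = |ht_log2|`, `b = |hs_log2|`:
#' \describe{
#'   \item{Formula A}{concordant and `a > b`: `RFC = (a - b) / b`;}
#'   \item{Formula B}{concordant and `a < b`: `RFC = (b - a) / a`
#'     (equal magnitudes give RFC 0, labelled B by convention);}
#'   \item{Formula C}{discordant: `RFC = (a + b) / 2`.}
#' }
#' Operating on magnitudes keeps the three cases mutually consistent: a
#' discordant (+3, -2) pair scores (3 + 2) / 2 = 2.5 rather than a signed
#' mean of 0.5 that could never clear the selection threshold.
#'
#' @param hs_log2,ht_log2 Signed log2 fold changes in the HS and HT lines.
#'   Vectorized.
#' @param concordant Logical; `TRUE` when the transcript is regulated in the
#'   same direction in both lines.
#' @return data.frame with columns `formula` (`"A"`/`"B"`/`"C"`) and `rfc`
#'   (non-negative).
#' @export
rfc_value <- function(hs_log2, ht_log2, concordant) {
  n <- max(length(hs_log2), length(ht_log2), length(concordant))
  a <- rep_len(abs(ht_log2), n)
  b <- rep_len(abs(hs_log2), n)
  concordant <- rep_len(as.logical(concordant), n)
  if (any(concordant & (a == 0 | b == 0))) {
    stop("concordant transcripts require non-zero log2 fold changes in both lines")
  }
  formula <- ifelse(!concordant, "C", ifelse(a > b, "A", "B"))
  rfc <- numeric(n)
  rfc[formula == "A"] <- ((a - b) / b)[formula == "A"]
  rfc[formula == "B"] <- ((b - a) / a)[formula == "B"]
  rfc[formula == "C"] <- ((a + b) / 2)[formula == "C"]
  data.frame(formula = formula, rfc = rfc, stringsAsFactors = FALSE)
}

#' Select high night temperature response transcripts (HTRTs) by RFC
#'
#' Pairs the two lines' differential-expression results, classifies each
#' transcript's cross-line pattern, computes the Relative Fold Change for
#' the candidate set, and flags transcripts with `rfc >= threshold`
#' (inclusive) as selected.
#'
#' The default candidate set is the intersection of the two lines'
#' significant transcripts, matching how the cross-line overlap classes are
#' defined on transcripts regulated in both lines; `candidates = "union"`
#' admits transcripts significant in at least one line, using the sign of
#' each line's log2 fold change to decide concordance.
#'
#' @param de_hs,de_ht [de_test()] results for the HS and HT lines.
#' @param threshold RFC selection threshold (default 2.0, inclusive).
#' @param candidates `"intersection"` (default) or `"union"`.
#' @return data.frame sorted by `transcript_id`, one row per candidate:
#'   `transcript_id`, `hs_log2`, `ht_log2`, `pattern`, `formula`, `rfc`,
#'   `selected`.
#' @export
select_htrts <- function(de_hs, de_ht, threshold = 2.0,
                         candidates = c("intersection", "union")) {
  candidates <- match.arg(candidates)
  m <- merge(de_hs, de_ht, by = "transcript_id", suffixes = c("_hs", "_ht"))
  cand <- if (candidates == "intersection") {
    m$significant_hs & m$significant_ht
  } else {
    m$significant_hs | m$significant_ht
  }
  m <- m[cand, , drop = FALSE]
  m <- m[order(m$transcript_id), , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(transcript_id = character(), hs_log2 = numeric(),
                      ht_log2 = numeric(), pattern = character(),
                      formula = character(), rfc = numeric(),
                      selected = logical(), stringsAsFactors = FALSE))
  }
  if (any(m$log2fc_hs == 0 | m$log2fc_ht == 0)) {
    stop("candidate transcript(s) with zero log2 fold change cannot be scored")
  }
  pattern <- classify_pattern(m$direction_hs, m$direction_ht)
  concordant <- sign(m$log2fc_hs) == sign(m$log2fc_ht)
  v <- rfc_value(m$log2fc_hs, m$log2fc_ht, concordant)
  data.frame(
    transcript_id = m$transcript_id,
    hs_log2 = m$log2fc_hs, ht_log2 = m$log2fc_ht,
    pattern = pattern, formula = v$formula, rfc = v$rfc,
    selected = v$rfc >= threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tally cross-line pattern classes
#'
#' @param patterns Character/factor vector of pattern labels, or a
#'   data.frame with a `pattern` column (e.g. [select_htrts()] output).
#' @return Named integer vector over all nine [pattern_levels()], zero for
#'   absent classes; sums to the number of input records.
#' @export
tally_patterns <- function(patterns) {
  if (is.data.frame(patterns)) patterns <- patterns$pattern
  lv <- pattern_levels()
  if (!all(patterns %in% lv)) {
    stop("unknown pattern label(s): ",
         paste(unique(setdiff(patterns, lv)), collapse = ", "))
  }
  tab <- table(factor(patterns, levels = lv))
  stats::setNames(as.integer(tab), lv)
}
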