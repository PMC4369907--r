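#' FPKM normalization of a fragment-count matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM[t, s] = counts[t, s] * 1e9 / (length[t] * library_size[s])`, where
#' the library size of a sample is its total fragment count.
#'
#' @param counts A [count_matrix()], or a plain counts matrix if `lengths`
#'   is supplied.
#' @param lengths Transcript lengths in bp (ignored when `counts` is a
#'   [count_matrix()]).
#' @return An object of class `fpkm_matrix`: list with `values` (matrix),
#'   `library_sizes`, `lengths` and `samples` (design metadata, if known).
#' @export
compute_fpkm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    m <- counts$counts
    lengths <- counts$lengths
    samples <- counts$samples
  } else {
    m <- counts
    samples <- NULL
    if (is.null(lengths)) stop("'lengths' required when 'counts' is a plain matrix")
  }
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop("degenerate sample(s) with zero library size: ",
         paste(colnames(m)[lib <= 0], collapse = ", "))
  }
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  values <- m * 1e9 / outer(as.numeric(lengths), as.numeric(lib))
  dimnames(values) <- dimnames(m)
  structure(
    list(values = values, library_sizes = lib,
         lengths = stats::setNames(as.numeric(lengths), rownames(m)),
         samples = samples),
    class = "fpkm_matrix"
  )
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat("fpkm_matrix:", nrow(x$values), "transcripts x", ncol(x$values), "samples\n")
  invisible(x)
}

#' Signed log2 fold change of two expression means
#'
#' @param mean_treat,mean_ctl Mean expression (e.g. FPKM) under treatment
#'   and control.
#' @param pseudocount Added to both means before the ratio; must be > 0
#'   unless both means are positive.
#' @return `log2((mean_treat + pseudocount) / (mean_ctl + pseudocount))`.
#' @export
log2_fold_change <- function(mean_treat, mean_ctl, pseudocount = 1) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  if (pseudocount == 0 && any(mean_treat + mean_ctl == 0)) {
    stop("undefined ratio: both means zero with zero pseudocount")
  }
  log2((mean_treat + pseudocount) / (mean_ctl + pseudocount))
}

#' Per-line differential-expression test at fixed thresholds
#'
#' For one line, compares treatment vs control replicates transcript by
#' transcript: the reported log2 fold change is taken on replicate-mean FPKM
#' (plus pseudocount), and the p-value comes from a two-sample t-test on
#' `log2(FPKM + pseudocount)` across replicates. A transcript is flagged
#' significant when `p_value <= alpha` and `|log2fc| >= lfc_min`; no
#' multiple-testing correction is applied, mirroring the original selection
#' rule.
#'
#' The default is the pooled-variance (Student) t-test: with small equal
#' replicate groups it holds the nominal type-I rate on log-transformed
#' negative-binomial counts, where the Welch test is noticeably conservative
#' (see the methods vignette). Set `var_equal = FALSE` for Welch.
#'
#' @param fpkm An [compute_fpkm()] result whose samples carry line/condition
#'   metadata.
#' @param line `"HS"` (heat-sensitive) or `"HT"` (heat-tolerant).
#' @param alpha P-value threshold (default 0.05).
#' @param lfc_min Minimum |log2 fold change| (default 1.0).
#' @param pseudocount FPKM pseudocount (default 1).
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @return data.frame with one row per transcript: `transcript_id`, `line`,
#'   `log2fc`, `p_value`, `significant`, `direction`
#'   (`"up"`/`"down"`/`"none"`; `"none"` iff not significant).
#' @export
de_test <- function(fpkm, line = c("HS", "HT"), alpha = 0.05, lfc_min = 1.0,
                    pseudocount = 1, var_equal = TRUE) {
  line <- match.arg(line)
  if (!inherits(fpkm, "fpkm_matrix") || is.null(fpkm$samples)) {
    stop("'fpkm' must be an fpkm_matrix with sample metadata")
  }
  s <- fpkm$samples
  tcols <- which(s$line == line & s$condition == "treatment")
  ccols <- which(s$line == line & s$condition == "control")
  if (length(tcols) < 2 || length(ccols) < 2) {
    stop("need >= 2 treatment and >= 2 control replicates for line ", line)
  }
  v <- fpkm$values
  lfc <- log2_fold_change(rowMeans(v[, tcols, drop = FALSE]),
                          rowMeans(v[, ccols, drop = FALSE]),
                          pseudocount)
  logv <- log2(v + pseudocount)
  pvals <- vapply(seq_len(nrow(v)), function(i) {
    x <- logv[i, tcols]
    y <- logv[i, ccols]
    tryCatch(
      stats::t.test(x, y, var.equal = var_equal)$p.value,
      error = function(e) {
        # exactly constant data: no evidence against equality unless the
        # group means differ, in which case the difference is deterministic
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      }
    )
  }, numeric(1))
  significant <- pvals <= alpha & abs(lfc) >= lfc_min & lfc != 0
  data.frame(
    transcript_id = rownames(v),
    line = line,
    log2fc = lfc,
    p_value = pvals,
    significant = significant,
    direction = ifelse(!significant, "none", ifelse(lfc > 0, "up", "down")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
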