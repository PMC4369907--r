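# qPCR validation (2^-ddCt relative expression), RNA-seq concordance, and
# the grain-plumpness phenotype score.

#' Delta-delta-Ct of a target gene against a reference gene
#'
#' `ddCt = (Ct_target,treat - Ct_ref,treat) - (Ct_target,ctl - Ct_ref,ctl)`.
#' Ct values should already be means over technical replicates.
#'
#' @param ct_target_treat,ct_ref_treat Target/reference Ct under treatment,
#'   in cycles.
#' @param ct_target_ctl,ct_ref_ctl Target/reference Ct under control.
#' @return ddCt in cycles (vectorized).
#' @export
delta_delta_ct <- function(ct_target_treat, ct_ref_treat,
                           ct_target_ctl, ct_ref_ctl) {
  (ct_target_treat - ct_ref_treat) - (ct_target_ctl - ct_ref_ctl)
}

#' Relative quantity from a ddCt
#'
#' Assumes ideal amplification efficiency (template doubles each cycle):
#' `RQ = 2^(-ddCt)`.
#'
#' @param ddct ddCt in cycles.
#' @return Fold ratio of treatment to control expression.
#' @export
relative_quantity <- function(ddct) {
  2^(-ddct)
}

#' Relative expression per gene from a long Ct table
#'
#' Averages technical replicates on the Ct scale per gene x condition, then
#' applies [delta_delta_ct()] and [relative_quantity()].
#'
#' @param ct data.frame as from [simulate_ct()]: columns `gene`,
#'   `condition` (`"control"`/`"treatment"`), `replicate`, `target_ct`,
#'   `reference_ct`.
#' @return data.frame with one row per gene: `gene`, `ddct`, `rq`,
#'   `log2_rq`.
#' @export
qpcr_relative_expression <- function(ct) {
  needed <- c("gene", "condition", "target_ct", "reference_ct")
  if (!all(needed %in% names(ct))) {
    stop("'ct' must have columns: ", paste(needed, collapse = ", "))
  }
  agg <- stats::aggregate(ct[c("target_ct", "reference_ct")],
                          by = ct[c("gene", "condition")], FUN = mean)
  trt <- agg[agg$condition == "treatment", ]
  ctl <- agg[agg$condition == "control", ]
  i <- match(trt$gene, ctl$gene)
  if (anyNA(i)) stop("every gene needs both treatment and control Ct values")
  ddct <- delta_delta_ct(trt$target_ct, trt$reference_ct,
                         ctl$target_ct[i], ctl$reference_ct[i])
  out <- data.frame(gene = trt$gene, ddct = ddct,
                    rq = relative_quantity(ddct),
                    stringsAsFactors = FALSE)
  out$log2_rq <- log2(out$rq)
  out[order(out$gene), , drop = FALSE]
}

#' Direction concordance between qPCR and RNA-seq calls
#'
#' Fraction of shared genes whose qPCR log2 relative quantity and RNA-seq
#' log2 fold change agree in sign, with magnitudes below `tol` treated as
#' "no change" on either side.
#'
#' @param rq Named vector of qPCR relative quantities (fold ratios) per
#'   gene.
#' @param log2fc Named vector of RNA-seq log2 fold changes per gene.
#' @param tol Dead zone in log2 units (default 0.1).
#' @return Fraction in \[0, 1\].
#' @export
direction_concordance <- function(rq, log2fc, tol = 0.1) {
  shared <- intersect(names(rq), names(log2fc))
  if (length(shared) == 0L) stop("no shared genes between qPCR and RNA-seq")
  if (any(rq[shared] <= 0)) stop("relative quantities must be positive")
  zsign <- function(x) ifelse(abs(x) < tol, 0, sign(x))
  mean(zsign(log2(rq[shared])) == zsign(log2fc[shared]))
}

#' Grain plumpness score
#'
#' `GP (%) = 100 * GWt / GWc`, where GWt and GWc are 1000-grain weights
#' from the high-night-temperature treatment and the control.
#'
#' @param gwt Treatment 1000-grain weight in grams.
#' @param gwc Control 1000-grain weight in grams; must be > 0.
#' @return GP as a percentage (vectorized).
#' @export
grain_plumpness <- function(gwt, gwc) {
  if (any(gwc <= 0)) stop("'gwc' must be > 0")
  100 * gwt / gwc
}
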