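# Shared fixtures and independent oracles for the test suite.

# Build a count_matrix whose library sizes are identical across samples by
# appending a filler transcript; FPKM of the non-filler transcripts is then
# proportional to their counts, which makes expected values hand-computable.
make_counts_equal_lib <- function(mat, lengths, lib_size = NULL) {
  if (is.null(lib_size)) lib_size <- max(colSums(mat)) + 1000
  filler <- lib_size - colSums(mat)
  stopifnot(all(filler >= 0))
  m <- rbind(mat, filler = filler)
  rownames(m) <- c(rownames(mat), "Tfiller")
  count_matrix(m, c(lengths, 1000L))
}

# 12-sample count matrix from per-cell replicate means (HS ctl/trt, HT
# ctl/trt), constant counts (zero within-group variance unless jitter given).
make_design_counts <- function(hs_ctl, hs_trt, ht_ctl, ht_trt, lengths,
                               jitter = NULL, lib_size = NULL) {
  build <- function(v, k) if (is.null(jitter)) v else v + jitter[[k]]
  mat <- cbind(
    SC1 = build(hs_ctl, 1), SC2 = build(hs_ctl, 2), SC3 = build(hs_ctl, 3),
    ST1 = build(hs_trt, 1), ST2 = build(hs_trt, 2), ST3 = build(hs_trt, 3),
    TC1 = build(ht_ctl, 1), TC2 = build(ht_ctl, 2), TC3 = build(ht_ctl, 3),
    TT1 = build(ht_trt, 1), TT2 = build(ht_trt, 2), TT3 = build(ht_trt, 3)
  )
  rownames(mat) <- sprintf("T%03d", seq_along(hs_ctl))
  make_counts_equal_lib(mat, lengths, lib_size)
}

# Independent scalar brute-force of the three-case Relative Fold Change,
# written directly from the case text rather than via rfc_value()'s
# vectorized dispatch.
brute_rfc <- function(hs_log2, ht_log2, concordant) {
  a <- abs(ht_log2)
  b <- abs(hs_log2)
  if (!concordant) {
    list(formula = "C", rfc = (a + b) / 2)
  } else if (a > b) {
    list(formula = "A", rfc = (a - b) / b)
  } else {
    list(formula = "B", rfc = (b - a) / a)
  }
}

# Brute-force N50: largest candidate length L whose >=L transcripts hold at
# least half of all bases (O(n^2) definition check).
brute_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= half) return(L)
  }
  stop("unreachable")
}

# Low-noise simulation config: planted effects dominate counting noise and
# the planted mass is too small for FPKM composition bias to matter.
low_noise_config <- function(seed, n_transcripts = 1000, base_mean = 5e4,
                             dispersion = 1e-6) {
  sim_config(
    n_transcripts = n_transcripts,
    class_proportions = c(null = 0.985, concordant_equal = 0.005,
                          concordant_divergent = 0.005, discordant = 0.005),
    base_mean = base_mean, dispersion = dispersion, seed = seed
  )
}
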