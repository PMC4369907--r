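#!/usr/bin/env Rscript
# Compare the two lines' responses: classify cross-line expression patterns,
# compute the Relative Fold Change, and select HTRTs at RFC >= 2; then score
# the selection against the planted truth.

suppressPackageStartupMessages(library(riceHNT))

out <- "results"
de_hs <- read.delim(file.path(out, "de_HS.tsv"))
de_ht <- read.delim(file.path(out, "de_HT.tsv"))
truth <- read.delim(file.path(out, "truth.tsv"))

rfc <- select_htrts(de_hs, de_ht, threshold = 2.0, candidates = "union")
rfc$hs_log2 <- round_half_up(rfc$hs_log2, 4)
rfc$ht_log2 <- round_half_up(rfc$ht_log2, 4)
rfc$rfc <- round_half_up(rfc$rfc, 4)
write.table(rfc, file.path(out, "rfc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tal <- tally_patterns(rfc[rfc$selected, ])
write.table(data.frame(pattern = names(tal), count = tal),
            file.path(out, "htrt_tally.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("candidates:", nrow(rfc), " selected HTRTs:", sum(rfc$selected), "\n")
print(tal[tal > 0])

planted <- truth$transcript_id[!is.na(truth$true_rfc) & truth$true_rfc >= 2]
got <- rfc$transcript_id[rfc$selected]
cat(sprintf("recovery: %.1f%% of %d planted; %d false selections\n",
            100 * mean(planted %in% got), length(planted),
            sum(!got %in% planted)))
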