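#!/usr/bin/env Rscript
# FPKM-normalize the simulated counts and call per-line differentially
# expressed transcripts at the study thresholds (p <= 0.05, |log2FC| >= 1).

suppressPackageStartupMessages(library(riceHNT))

out <- "results"
cm <- read_counts(file.path(out, "counts.tsv"))
fp <- compute_fpkm(cm)

fpkm_df <- data.frame(transcript_id = rownames(fp$values), fp$values,
                      check.names = FALSE)
write.table(fpkm_df, file.path(out, "fpkm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (ln in c("HS", "HT")) {
  de <- de_test(fp, ln)
  de$log2fc <- round_half_up(de$log2fc, 4)
  write.table(de, file.path(out, paste0("de_", ln, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d significant (%d up, %d down) of %d transcripts\n",
              ln, sum(de$significant), sum(de$direction == "up"),
              sum(de$direction == "down"), nrow(de)))
}
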