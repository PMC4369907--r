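#!/usr/bin/env Rscript
# Generate the synthetic experiment that stands in for the sequenced grain
# samples: a 2-line x treatment/control x 3-replicate count matrix with
# planted cross-line effect classes, paired-end reads for the QC stage, and
# Ct tables for the qPCR validation stage.

suppressPackageStartupMessages(library(riceHNT))

out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(seed = 20150123)
sim <- simulate_experiment(cfg)

write_counts(sim$counts, file.path(out, "counts.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("simulated", nrow(sim$counts$counts), "transcripts x",
    ncol(sim$counts$counts), "samples\n")
print(table(sim$truth$class))
cat("planted HTRTs (true RFC >= 2):",
    sum(!is.na(sim$truth$true_rfc) & sim$truth$true_rfc >= 2), "\n")

# a small paired-end read set exercising the QC rules
rd <- simulate_reads(5000, read_len = 101, n_base_rate = 0.03,
                     lowq_rate = 0.15, seed = 20150123)
rd$read_id <- paste0(rd$read_id, "/", rd$mate)
write_fastq(rd[rd$mate == 1, ], file.path(out, "reads_R1.fastq"))
write_fastq(rd[rd$mate == 2, ], file.path(out, "reads_R2.fastq"))
write.table(rd[c("read_id", "should_pass")],
            file.path(out, "reads_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(rd), "reads;", sum(rd$should_pass), "should pass QC\n")

# zero-noise and noisy Ct tables for 12 assayed genes per line
genes <- sim$truth$transcript_id[sim$truth$class != "null"][1:12]
for (ln in c("HS", "HT")) {
  ct <- simulate_ct(sim$truth, ln, genes = genes, noise_sd = 0.15,
                    seed = 20150123)
  write.table(ct, file.path(out, paste0("ct_", ln, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote Ct tables for", length(genes), "genes x 2 lines\n")
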