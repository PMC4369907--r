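#!/usr/bin/env Rscript
# Filter the simulated paired-end reads with the study's rules (N fraction
# over 5%, or more than 20% of bases below Q20) and tabulate the per-sample
# QC summary; check the decisions against the simulator's truth labels.

suppressPackageStartupMessages(library(riceHNT))

out <- "results"
r1 <- read_fastq(file.path(out, "reads_R1.fastq"))
r2 <- read_fastq(file.path(out, "reads_R2.fastq"))
truth <- read.delim(file.path(out, "reads_truth.tsv"))

dec1 <- filter_reads(r1)
dec2 <- filter_reads(r2)
dec <- rbind(dec1, dec2)
truth <- truth[match(dec$read_id, truth$read_id), ]
cat("per-read agreement with simulator truth:",
    mean(dec$keep == truth$should_pass), "\n")

kept_pairs <- dec1$keep & dec2$keep
cat("pairs kept (both mates pass):", sum(kept_pairs), "of", nrow(dec1), "\n")

qc <- qc_summarize(dec, "simulated")
write.table(qc, file.path(out, "qc_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(qc)
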