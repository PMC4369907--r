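#!/usr/bin/env Rscript
# Re-derive every total and percentage of the study's printed summary tables
# from the per-sample rows: read/mapping totals, genomic-region breakdown,
# assembly known/novel splits, and the DEG/HTRT tallies.

suppressPackageStartupMessages(library(riceHNT))

out <- "results"

stats <- hnt_read_stats()
tot <- aggregate_read_stats(stats)
write.table(rbind(cbind(stats[1], stats[-1]),
                  data.frame(sample_id = tot$sample_id, raw_reads = tot$raw_reads,
                             hq_reads = tot$hq_reads, hq_percent = tot$hq_percent,
                             mapped_reads = tot$mapped_reads,
                             mapped_percent = tot$mapped_percent)),
            file.path(out, "read_stats_with_total.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("reads: %s raw, %s HQ (%.2f%%), %s mapped (%.2f%% of HQ)\n",
            format(tot$raw_reads, big.mark = ","),
            format(tot$hq_reads, big.mark = ","), tot$hq_percent,
            format(tot$mapped_reads, big.mark = ","), tot$mapped_percent))

reg <- hnt_region_stats()
rtot <- region_tally(c(exon = sum(reg$exon), intron = sum(reg$intron),
                       intergenic = sum(reg$intergenic),
                       spliced = sum(reg$spliced)), "Total")
write.table(rtot, file.path(out, "region_totals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("regions: exon %.2f%%, intron %.2f%%, intergenic %.2f%%, spliced %.2f%%\n",
            rtot$exon_percent, rtot$intron_percent, rtot$intergenic_percent,
            rtot$spliced_percent))

asm <- hnt_assembly_stats()
splits <- do.call(rbind, lapply(seq_len(nrow(asm)), function(i) {
  cbind(sample_id = asm$sample_id[i],
        known_novel_split(asm$n_transcripts[i], asm$known_count[i]))
}))
write.table(splits, file.path(out, "assembly_splits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("known-transcript fraction ranges",
    sprintf("%.2f%%-%.2f%%", min(splits$known_percent), max(splits$known_percent)),
    "across the 12 samples\n")

deg <- hnt_deg_counts()
cat("DEGs: heat-sensitive", sum(deg$count[deg$set == "deg_hs"]),
    "| heat-tolerant", sum(deg$count[deg$set == "deg_ht"]), "\n")
htrt <- deg[deg$set == "htrt", ]
tal <- tally_patterns(rep(htrt$class, htrt$count))
cat("HTRTs:", sum(tal), "(", paste(names(tal[tal > 0]), tal[tal > 0],
                                   collapse = ", "), ")\n")
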