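test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_transcripts = 200, seed = 7)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  d <- simulate_experiment(sim_config(n_transcripts = 200, seed = 8))
  expect_false(identical(a$counts$counts, d$counts$counts))
})

test_that("an all-null configuration plants no effects", {
  cfg <- sim_config(
    n_transcripts = 100,
    class_proportions = c(null = 1, concordant_equal = 0,
                          concordant_divergent = 0, discordant = 0),
    seed = 3
  )
  tr <- simulate_experiment(cfg)$truth
  expect_true(all(tr$class == "null"))
  expect_true(all(tr$planted_log2_HS == 0))
  expect_true(all(tr$planted_log2_HT == 0))
  expect_true(all(is.na(tr$true_rfc)))
})

test_that("class counts follow floor allocation with remainder to null", {
  cfg <- sim_config(
    n_transcripts = 103,
    class_proportions = c(null = 0.5, concordant_equal = 0.2,
                          concordant_divergent = 0.2, discordant = 0.1),
    seed = 1
  )
  tr <- simulate_experiment(cfg)$truth
  tab <- table(tr$class)
  expect_equal(unname(tab[["concordant_equal"]]), floor(0.2 * 103))
  expect_equal(unname(tab[["concordant_divergent"]]), floor(0.2 * 103))
  expect_equal(unname(tab[["discordant"]]), floor(0.1 * 103))
  expect_equal(unname(tab[["null"]]), 103 - 20 - 20 - 10)
  expect_equal(sum(tab), 103)
})

test_that("truth table covers every transcript once and encodes class structure", {
  sim <- simulate_experiment(sim_config(n_transcripts = 400, seed = 5))
  tr <- sim$truth
  expect_identical(tr$transcript_id, rownames(sim$counts$counts))
  expect_false(any(duplicated(tr$transcript_id)))
  conc <- tr$class %in% c("concordant_equal", "concordant_divergent")
  expect_true(all(sign(tr$planted_log2_HS[conc]) == sign(tr$planted_log2_HT[conc])))
  disc <- tr$class == "discordant"
  expect_true(all(sign(tr$planted_log2_HS[disc]) == -sign(tr$planted_log2_HT[disc])))
  expect_true(all(tr$true_rfc[tr$class == "concordant_equal"] == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(class_proportions = c(null = 0.5, concordant_equal = 0.2,
                                                concordant_divergent = 0.2,
                                                discordant = 0.2)), "sum to 1")
  expect_error(sim_config(n_reps = 1), "n_reps")
})

test_that("count-scale fold changes converge to the planted effect at low dispersion", {
  # Monte-Carlo check: 50 replicates per cell, near-zero dispersion, planted
  # |log2FC| = 2 on the concordant-equal class
  cfg <- sim_config(
    n_transcripts = 200, n_reps = 50,
    class_proportions = c(null = 0.9, concordant_equal = 0.1,
                          concordant_divergent = 0, discordant = 0),
    effect_log2 = list(concordant_equal = c(hs = 2, ht = 2),
                       concordant_divergent = c(hs = 1, ht = 3.2),
                       discordant = c(hs = 1.8, ht = 2.4)),
    dispersion = 1e-4, seed = 11
  )
  sim <- simulate_experiment(cfg)
  s <- sim$counts$samples
  trt <- rowMeans(sim$counts$counts[, s$line == "HS" & s$condition == "treatment"])
  ctl <- rowMeans(sim$counts$counts[, s$line == "HS" & s$condition == "control"])
  planted <- sim$truth$class == "concordant_equal"
  emp <- log2(trt[planted] / ctl[planted])
  expect_true(all(abs(abs(emp) - 2) < 0.1))
  expect_equal(sign(emp), sign(sim$truth$planted_log2_HS[planted]),
               ignore_attr = TRUE)
})

test_that("FPKM fold changes recover planted effects of several sizes", {
  # low planted mass + deep counts so composition bias and counting noise
  # are negligible; all three default effect classes checked at once
  sim <- simulate_experiment(low_noise_config(seed = 13, base_mean = 2e4,
                                              dispersion = 1e-4))
  fp <- compute_fpkm(sim$counts)
  tr <- sim$truth
  for (ln in c("HS", "HT")) {
    de <- de_test(fp, ln, pseudocount = 1e-6)
    planted <- tr[[paste0("planted_log2_", ln)]]
    idx <- tr$class != "null"
    expect_true(all(abs(de$log2fc[idx] - planted[idx]) < 0.1))
  }
})

test_that("clean reads all pass and all-N reads all fail", {
  clean <- simulate_reads(50, n_base_rate = 0, lowq_rate = 0, seed = 1)
  expect_true(all(clean$should_pass))
  expect_false(any(grepl("N", clean$sequence, fixed = TRUE)))
  allN <- simulate_reads(50, n_base_rate = 1, lowq_rate = 0, seed = 1)
  expect_false(any(allN$should_pass))
})

test_that("fraction of reads failing the N rule matches the binomial tail", {
  # with per-base N probability 0.05 on 101-bp reads, a read fails the
  # strict 5% rule iff it has >= 6 Ns: P = P(Binom(101, 0.05) >= 6)
  rd <- simulate_reads(1000, read_len = 101, n_base_rate = 0.05,
                       lowq_rate = 0, seed = 42)
  p_fail <- 1 - pbinom(5, 101, 0.05)
  obs <- mean(!rd$should_pass)
  se <- sqrt(p_fail * (1 - p_fail) / nrow(rd))
  expect_lt(abs(obs - p_fail), 3.5 * se)
})

test_that("read records are well formed", {
  rd <- simulate_reads(20, read_len = 75, n_base_rate = 0.1, lowq_rate = 0.3,
                       seed = 9)
  expect_equal(nrow(rd), 40)
  expect_true(all(nchar(rd$sequence) == 75))
  expect_true(all(nchar(rd$quality) == 75))
  expect_equal(rd$mate, rep(1:2, 20))
  expect_equal(rd$read_id[1], rd$read_id[2])
  expect_true(all(strsplit(paste(rd$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T", "N")))
})

test_that("zero-noise Ct values are exact and replicate-identical", {
  sim <- simulate_experiment(sim_config(n_transcripts = 50, seed = 2))
  tr <- sim$truth
  ct <- simulate_ct(tr, "HS", noise_sd = 0, seed = 4)
  # identical technical replicates within gene x condition
  spread <- tapply(ct$target_ct, paste(ct$gene, ct$condition), function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # null gene: no shift between conditions
  null_gene <- tr$transcript_id[tr$class == "null"][1]
  x <- ct[ct$gene == null_gene, ]
  expect_equal(diff(range(x$target_ct)), 0)
  # planted +2 gene gives RQ 4 downstream
  tr2 <- tr
  tr2$planted_log2_HS[1] <- 2
  ct2 <- simulate_ct(tr2, "HS", genes = tr2$transcript_id[1], noise_sd = 0, seed = 1)
  rq <- qpcr_relative_expression(ct2)
  expect_equal(rq$rq, 4)
})
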