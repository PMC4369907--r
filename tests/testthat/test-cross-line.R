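test_that("the 3x3 direction grid maps onto the nine pattern classes", {
  expect_equal(classify_pattern("up", "up"), "up_both")
  expect_equal(classify_pattern("down", "down"), "down_both")
  # argument order is (HS, HT): HS up with HT down is downT_upS
  expect_equal(classify_pattern("up", "down"), "downT_upS")
  expect_equal(classify_pattern("down", "up"), "upT_downS")
  expect_equal(classify_pattern("none", "none"), "neither")
  grid <- expand.grid(hs = c("up", "down", "none"), ht = c("up", "down", "none"),
                      stringsAsFactors = FALSE)
  got <- classify_pattern(grid$hs, grid$ht)
  expect_setequal(got, pattern_levels())   # partition: all nine, each once
  expect_false(any(duplicated(got)))
  expect_error(classify_pattern("sideways", "up"), "directions")
})

test_that("RFC follows the three-case formulas on magnitudes", {
  # concordant, HT magnitude higher -> formula A
  r <- rfc_value(1.0, 3.0, concordant = TRUE)
  expect_equal(r$formula, "A")
  expect_equal(r$rfc, 2.0)
  # equal magnitudes -> RFC 0, labelled B
  r <- rfc_value(1.5, 1.5, concordant = TRUE)
  expect_equal(r$formula, "B")
  expect_equal(r$rfc, 0)
  # concordant, HS higher -> formula B
  r <- rfc_value(-3.0, -1.0, concordant = TRUE)
  expect_equal(r$formula, "B")
  expect_equal(r$rfc, 2.0)
  # discordant -> formula C on magnitudes
  r <- rfc_value(2.4, -1.8, concordant = FALSE)
  expect_equal(r$formula, "C")
  expect_equal(r$rfc, 2.1)
  expect_error(rfc_value(0, 2, concordant = TRUE), "non-zero")
})

test_that("rfc_value agrees with the brute-force case analysis on a grid", {
  mags <- seq(1, 6, by = 0.05)
  grid <- expand.grid(b = mags, a = mags)
  for (conc in c(TRUE, FALSE)) {
    got <- rfc_value(grid$b, grid$a, concordant = conc)
    exp_rfc <- mapply(function(hs, ht) brute_rfc(hs, ht, conc)$rfc, grid$b, grid$a)
    exp_for <- mapply(function(hs, ht) brute_rfc(hs, ht, conc)$formula, grid$b, grid$a)
    expect_equal(got$rfc, unname(exp_rfc))
    expect_equal(got$formula, unname(exp_for))
  }
})

test_that("concordant selection at RFC >= 2 is exactly the 3x magnitude rule", {
  # integer-unit magnitudes (0.05 log2 units each) keep a - b and 3 * b exact
  # in double arithmetic, so the boundary a == 3b is decided identically on
  # both sides; the RFC formulas A/B are scale-invariant, so the identity on
  # units is the identity on log2 values
  mags <- 20:120
  grid <- expand.grid(b = mags, a = mags)
  rfc <- rfc_value(grid$b, grid$a, concordant = TRUE)$rfc
  expect_identical(rfc >= 2,
                   pmax(grid$a, grid$b) >= 3 * pmin(grid$a, grid$b))
})

test_that("HTRT selection handles edge cases and the inclusive threshold", {
  de_row <- function(id, line, lfc, sig) {
    data.frame(transcript_id = id, line = line, log2fc = lfc,
               p_value = ifelse(sig, 0.001, 0.8), significant = sig,
               direction = ifelse(!sig, "none", ifelse(lfc > 0, "up", "down")),
               stringsAsFactors = FALSE)
  }
  # nothing significant in both lines -> empty output
  hs <- de_row(c("T1", "T2"), "HS", c(2, 1.2), c(TRUE, FALSE))
  ht <- de_row(c("T1", "T2"), "HT", c(2, 1.5), c(FALSE, TRUE))
  out <- select_htrts(hs, ht)
  expect_equal(nrow(out), 0)
  # rfc exactly 2.0 is selected (inclusive >=)
  hs <- de_row("T1", "HS", 1, TRUE)
  ht <- de_row("T1", "HT", 3, TRUE)
  out <- select_htrts(hs, ht)
  expect_equal(out$rfc, 2.0)
  expect_true(out$selected)
  expect_equal(out$pattern, "up_both")
  expect_equal(out$formula, "A")
  # union admits transcripts significant in one line only
  hs <- de_row("T1", "HS", 0.4, FALSE)
  ht <- de_row("T1", "HT", 3, TRUE)
  expect_equal(nrow(select_htrts(hs, ht)), 0)
  out <- select_htrts(hs, ht, candidates = "union")
  expect_equal(nrow(out), 1)
  expect_equal(out$formula, "A")
  expect_equal(out$rfc, (3 - 0.4) / 0.4)
})

test_that("raising the threshold never grows the selected set", {
  set.seed(8)
  n <- 200
  hs <- data.frame(
    transcript_id = sprintf("T%03d", 1:n), line = "HS",
    log2fc = runif(n, -4, 4), p_value = runif(n, 0, 0.04),
    significant = TRUE, stringsAsFactors = FALSE
  )
  hs$direction <- ifelse(hs$log2fc > 0, "up", "down")
  ht <- hs
  ht$line <- "HT"
  ht$log2fc <- runif(n, -4, 4)
  ht$direction <- ifelse(ht$log2fc > 0, "up", "down")
  sizes <- vapply(seq(0, 4, by = 0.5), function(th) {
    sum(select_htrts(hs, ht, threshold = th)$selected)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("a low-noise experiment recovers exactly the planted HTRT set", {
  sim <- simulate_experiment(low_noise_config(seed = 27))
  fp <- compute_fpkm(sim$counts)
  # union candidates: the planted |log2FC| = 1.0 of the concordant-divergent
  # class sits on the per-line DEG gate, so intersection would censor it
  sel <- select_htrts(de_test(fp, "HS"), de_test(fp, "HT"),
                      candidates = "union")
  planted <- sim$truth$transcript_id[!is.na(sim$truth$true_rfc) &
                                       sim$truth$true_rfc >= 2]
  expect_setequal(sel$transcript_id[sel$selected], planted)
  # spot-check each selected rfc against the brute-force case analysis
  for (i in seq_len(nrow(sel))) {
    conc <- sign(sel$hs_log2[i]) == sign(sel$ht_log2[i])
    expect_equal(sel$rfc[i], brute_rfc(sel$hs_log2[i], sel$ht_log2[i], conc)$rfc)
  }
  # output is sorted for reproducible diffs
  expect_identical(sel$transcript_id, sort(sel$transcript_id))
})

test_that("pattern tallies count every record exactly once", {
  pats <- rep(c("down_both", "up_both", "upT_downS", "downT_upS"),
              times = c(4, 19, 4, 8))
  tal <- tally_patterns(pats)
  expect_equal(sum(tal), 35)
  expect_equal(unname(tal[c("down_both", "up_both", "upT_downS", "downT_upS")]),
               c(4, 19, 4, 8))
  expect_equal(sum(tal[setdiff(names(tal), c("down_both", "up_both",
                                             "upT_downS", "downT_upS"))]), 0)
  # empty input -> all-zero tally over all nine classes
  empty <- tally_patterns(character())
  expect_equal(sum(empty), 0)
  expect_equal(names(empty), pattern_levels())
  # permutation invariance
  set.seed(1)
  expect_identical(tally_patterns(sample(pats)), tal)
  expect_error(tally_patterns("diagonal"), "unknown pattern")
})
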