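# Transcript-level binding quantification: boundary rules, pseudocounted
# RPM arithmetic, top-N selection, fold changes and the Welch test.

test_that("crosslink-base assignment honours the 5'-region boundary", {
  b <- manual_bundle()            # utr5 50, cds 240 -> 5' region 50 + 150
  ## 5' base in the 5'UTR (position 3), at CDS offset 149 (200th nt,
  ## inside), at CDS offset 150 (201st nt, outside: half-open boundary),
  ## and in the 3'UTR
  al <- manual_alignments(c(3, 200, 201, 350), width = 20)
  bt <- count_transcript_binding(al, b, "c1")
  expect_equal(bt$total_count, 4)
  expect_equal(bt$fivep_count, 2)

  ## reads outside any transcript are uncounted but stay in the library
  al2 <- rbind(al, data.frame(read_id = "out", chrom = "chr1",
                              strand = "+", start = 10, end = 29,
                              multimapped = FALSE))
  bt2 <- count_transcript_binding(al2, b, "c1")
  expect_equal(bt2$total_count, 4)
  libs <- attr(bt2, "libraries")
  expect_equal(libs$mapped, 5)
  expect_equal(libs$assigned, 4)

  ## antisense alignments are not counted (sense-only rule)
  anti <- manual_alignments(3, width = 20, strand = "-")
  expect_equal(count_transcript_binding(anti, b, "c2")$total_count, 0)

  expect_error(count_transcript_binding(al, b, "c1", table = bt),
               "already present")
})

test_that("minus-strand crosslink base is the alignment end", {
  b <- manual_bundle()
  b$transcripts$strand <- "-"
  ## transcript position p on '-' maps to genomic base end - p + 1;
  ## 5' region is positions 1..200
  al <- data.frame(read_id = c("in5", "beyond"), chrom = "chr1",
                   strand = "-",
                   start = c(500 - 199 - 19, 500 - 200 - 19),
                   end = c(500 - 199, 500 - 200),
                   multimapped = FALSE, stringsAsFactors = FALSE)
  bt <- count_transcript_binding(al, b, "c1")
  expect_equal(bt$total_count, 2)
  expect_equal(bt$fivep_count, 1)
})

test_that("counts equal the brute-force interval oracle on simulated data", {
  b <- tiny_bundle(n_study = 6)
  tr <- make_binding_truth(b, factor_profile = list(
    fivep_share = 0.9, pervasive_transcript_fraction = 0.3),
    background_share = 0.5, seed = 3)
  cfg <- sim_config(n_reads = 3000)
  sim <- simulate_crac_reads(tr, b, "mock", cfg, seed = 9)
  pp <- preprocess_reads(sim$reads, cfg$barcode_table, cfg$adapter)
  al <- align_reads(pp$samples$mock, b, seed = 2)$alignments
  bt <- count_transcript_binding(al, b, "mock")
  want <- bf_count_binding(al, b$transcripts)
  expect_equal(bt$total_count, unname(want$total[bt$transcript]))
  expect_equal(bt$fivep_count, unname(want$fivep[bt$transcript]))
  ## conservation: totals never exceed mapped reads
  expect_lte(sum(bt$total_count), nrow(al))
})

test_that("pseudocounted RPM arithmetic matches the definition", {
  b <- manual_bundle()
  al <- manual_alignments(rep(3, 7), width = 20)
  bt <- count_transcript_binding(al, b, "c1")
  attr(bt, "libraries")$mapped <- 1000   # library of 1,000 mapped reads
  nb <- normalize_binding(bt, pseudocount = 3)
  expect_equal(nb$total_rpm, (7 + 3) * 1e6 / 1000)

  ## zero-count transcript floors at pseudocount x 1e6 / library
  bt0 <- count_transcript_binding(al[0, ], b, "z")
  attr(bt0, "libraries")$mapped <- 1000
  nb0 <- normalize_binding(bt0)
  expect_equal(nb0$total_rpm, 3e6 / 1000)

  attr(bt, "libraries")$mapped <- 0
  expect_error(normalize_binding(bt), "zero library")
})

test_that("top-transcript selection ranks by mean reference RPM", {
  tab <- data.frame(
    transcript = c("A", "B", "A", "B"),
    condition = c("control", "control", "mock", "mock"),
    total_count = 0, fivep_count = 0,
    total_rpm = c(10, 5, 0, 9), fivep_rpm = 0)
  attr(tab, "libraries") <- data.frame(condition = c("control", "mock"),
                                       mapped = 1, assigned = 1)
  class(tab) <- c("binding_table", "data.frame")
  expect_equal(select_top_transcripts(tab, n = 1), "B")   # means 5 vs 7
  expect_equal(select_top_transcripts(tab, n = 10), c("B", "A"))

  ## random tables agree with an independent sort oracle
  set.seed(12)
  ids <- sprintf("T%03d", 1:40)
  rt <- data.frame(transcript = rep(ids, 2),
                   condition = rep(c("control", "mock"), each = 40),
                   total_count = 0, fivep_count = 0,
                   total_rpm = round(runif(80, 0, 20)), fivep_rpm = 0)
  attr(rt, "libraries") <- data.frame(condition = c("control", "mock"),
                                      mapped = 1, assigned = 1)
  class(rt) <- c("binding_table", "data.frame")
  got <- select_top_transcripts(rt, n = 15)
  m <- (rt$total_rpm[1:40] + rt$total_rpm[41:80]) / 2
  want <- ids[order(-m, ids)][1:15]
  expect_equal(got, want)
})

test_that("fold changes behave in identity and doubling limits", {
  b <- manual_bundle()
  al1 <- manual_alignments(rep(3, 500), width = 20)
  al2 <- manual_alignments(rep(3, 1000), width = 20)
  bt <- count_transcript_binding(al1, b, "ref")
  bt <- count_transcript_binding(al2, b, "str", table = bt)
  libs <- attr(bt, "libraries")
  libs$mapped <- c(2000, 2000)   # equal library sizes
  attr(bt, "libraries") <- libs
  nb <- normalize_binding(bt)
  fc <- fold_changes(nb, "str", "ref", metric = "total")
  expect_equal(fc$log2fc, log2(1003 / 503))
  expect_lt(abs(fc$log2fc - 1), 0.02)
  fc0 <- fold_changes(nb, "ref", "ref", metric = "total")
  expect_equal(fc0$log2fc, 0)
  expect_error(fold_changes(nb, "nope", "ref"), "missing")
})

test_that("the Welch test separates planted shifts and handles degeneracy", {
  expect_equal(compare_distributions(c(1, 1, 1), c(1, 1, 1)),
               list(statistic = 0, p_value = 1))
  set.seed(8)
  x <- rnorm(2000, 0, 1)
  y <- rnorm(2000, -2, 1)
  r <- compare_distributions(y, x)
  expect_lt(r$p_value, 1e-15)
  ## order flips the sign of t, not the p value
  r2 <- compare_distributions(x, y)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  ## cross-check against stats::t.test directly
  tt <- t.test(y, x)
  expect_equal(r$statistic, unname(tt$statistic))
  expect_error(compare_distributions(1, c(1, 2)), "two values")
})
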