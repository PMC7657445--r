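# Preprocessing: demultiplexing, trimming, duplicate collapsing, entropy
# filtering, and their composition.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGGC"

test_that("demultiplexing assigns on the exact barcode field", {
  reads <- data.frame(
    id = c("a", "b", "c"),
    sequence = c(paste0("NNN", "GTGAGC", "ACGTACGTACGT"),
                 paste0("AAA", "TTTTTT", "ACGTACGTACGT"),
                 paste0("GCA", "TAGCAT", "TTTTGGGGCCCC")),
    qualities = strrep("I", 21),
    stringsAsFactors = FALSE)
  dm <- demultiplex(reads, c(s1 = "GTGAGC", s2 = "TAGCAT"), umi_length = 3)
  expect_equal(dm$samples$s1$id, "a")
  expect_equal(dm$samples$s1$umi, "NNN")
  expect_equal(dm$samples$s1$sequence, "ACGTACGTACGT")
  expect_equal(dm$samples$s2$id, "c")
  expect_equal(dm$unassigned$id, "b")
  expect_error(demultiplex(reads, c(x = "AAAAAA", y = "AAAAAA")),
               "duplicate")
})

test_that("demultiplexed per-sample counts match the simulation truth", {
  b <- tiny_bundle(n_study = 4)
  tr <- make_binding_truth(b, stress_model = data.frame(
    condition = "glucose", fivep_retention = 0.1, pervasive_retention = 1),
    seed = 1)
  cfg <- sim_config(n_reads = 400)
  pool <- list()
  for (cond in c("control", "mock", "glucose")) {
    s <- simulate_crac_reads(tr, b, cond, cfg,
                             seed = match(cond, c("control", "mock",
                                                  "glucose")))
    pool[[cond]] <- s$reads
  }
  mixed <- do.call(rbind, pool)
  dm <- demultiplex(mixed, cfg$barcode_table, cfg$umi_length)
  for (cond in names(pool))
    expect_equal(nrow(dm$samples[[cond]]), 400)
  expect_equal(nrow(dm$unassigned), 0)
})

test_that("adapter trimming follows the overlap and leftmost-cut rules", {
  insert <- "ACGTACGTACGTACGTACGTACGTACGTAC"   # 30 nt
  filler <- "GTCAG"
  read <- data.frame(id = "r", sequence = paste0(insert, ADAPTER, filler),
                     qualities = strrep("I", 30 + 22 + 5),
                     stringsAsFactors = FALSE)
  tr <- trim_reads(read, ADAPTER)
  expect_equal(tr$reads$sequence, insert)

  ## 3-nt terminal overlap is below min_overlap = 4: no trim
  read3 <- data.frame(id = "r", sequence = paste0(insert, "TGG"),
                      qualities = strrep("I", 33), stringsAsFactors = FALSE)
  expect_equal(trim_reads(read3, ADAPTER)$reads$sequence, paste0(insert,
                                                                 "TGG"))
  ## 4-nt terminal overlap is trimmed
  read4 <- data.frame(id = "r", sequence = paste0(insert, "TGGA"),
                      qualities = strrep("I", 34), stringsAsFactors = FALSE)
  expect_equal(trim_reads(read4, ADAPTER)$reads$sequence, insert)

  ## quality tail removed before adapter matching
  qual <- paste0(strrep("I", 30), strrep("#", 5))
  readq <- data.frame(id = "r", sequence = paste0(insert, "GTCAG"),
                      qualities = qual, stringsAsFactors = FALSE)
  expect_equal(trim_reads(readq, ADAPTER)$reads$sequence, insert)

  ## too many N bases discards the read
  readn <- data.frame(id = "r",
                      sequence = paste0("NNN", substr(insert, 4, 30)),
                      qualities = strrep("I", 30), stringsAsFactors = FALSE)
  tn <- trim_reads(readn, ADAPTER)
  expect_equal(nrow(tn$reads), 0)
  expect_equal(tn$stats$discarded_uncalled, 1)
})

test_that("trimming matches the brute-force oracle read-for-read", {
  b <- tiny_bundle(n_study = 4)
  tr <- make_binding_truth(b, seed = 1)
  cfg <- sim_config(n_reads = 800, contaminant_rate = 0.1)
  sim <- simulate_crac_reads(tr, b, "control", cfg, seed = 5)
  dm <- demultiplex(sim$reads, cfg$barcode_table, cfg$umi_length)
  raw <- dm$samples$control
  ## sprinkle variable qualities and N bases so every rule is exercised
  set.seed(77)
  n <- nrow(raw)
  tweak <- sample(n, 80)
  raw$qualities[tweak[1:40]] <- paste0(
    substr(raw$qualities[tweak[1:40]], 1, 50), strrep("#", 16))
  substr(raw$sequence[tweak[41:80]], 5, 8) <- "NNNN"

  got <- trim_reads(raw, ADAPTER)
  want <- lapply(seq_len(n), function(i)
    bf_trim_one(raw$sequence[i], raw$qualities[i], ADAPTER))
  keep <- vapply(want, `[[`, logical(1), "keep")
  expect_equal(got$reads$id, raw$id[keep])
  expect_equal(got$reads$sequence,
               vapply(want, `[[`, character(1), "sequence")[keep])
})

test_that("duplicate collapsing keeps first of each (umi, sequence) pair", {
  reads <- data.frame(id = c("a", "b", "c", "d"),
                      sequence = c("ACGT", "ACGT", "ACGT", "TTTT"),
                      qualities = "IIII",
                      umi = c("AAA", "AAA", "CCC", "AAA"),
                      stringsAsFactors = FALSE)
  cd <- collapse_duplicates(reads)
  expect_equal(cd$reads$id, c("a", "c", "d"))
  expect_equal(cd$removed, 1)
  ## idempotence
  cd2 <- collapse_duplicates(cd$reads)
  expect_identical(cd2$reads, cd$reads)
  expect_equal(cd2$removed, 0)
})

test_that("collapsing a duplicated library matches the brute-force set", {
  b <- tiny_bundle(n_study = 4)
  tr <- make_binding_truth(b, seed = 1)
  cfg <- sim_config(n_reads = 4000, pcr_duplication_rate = 0.5)
  sim <- simulate_crac_reads(tr, b, "mock", cfg, seed = 6)
  dm <- demultiplex(sim$reads, cfg$barcode_table, cfg$umi_length)
  raw <- dm$samples$mock
  cd <- collapse_duplicates(raw)
  keep <- bf_collapse(raw$umi, raw$sequence)
  expect_equal(nrow(cd$reads), sum(keep))
  expect_equal(cd$reads$id, raw$id[keep])
})

test_that("entropy scoring matches its definition", {
  ## all windows hold a single distinct 6-mer: entropy 0, discarded
  expect_equal(entropy_score("AAAAAAAAAAAAAAAA"), 0)
  ## a 10-nt window with 5 distinct 6-mers each once: ln5/ln5 = 1
  expect_equal(entropy_score("ACGTACGTGG"), 1)
  ## reads shorter than k are unscored (kept)
  expect_true(is.na(entropy_score("ACGT")))
  expect_error(entropy_filter(data.frame(sequence = "ACGTACGTACGT"),
                              k = 12, window = 10), "k must not exceed")

  ## oracle equivalence on random + homopolymer + dinucleotide reads,
  ## including lengths below the window
  set.seed(31)
  seqs <- c(
    vapply(sample(7:40, 300, TRUE), function(L)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1)),
    strrep(sample(c("A", "C", "G", "T"), 50, TRUE), sample(10:40, 50, TRUE)),
    substr(strrep(sample(c("AC", "GT", "AG"), 50, TRUE), 20), 1,
           sample(12:40, 50, TRUE)))
  got <- entropy_score(seqs)
  want <- vapply(seqs, bf_entropy_one, numeric(1), USE.NAMES = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("pipeline composition conserves read counts and removes planted
           contaminants without touching genuine reads", {
  b <- tiny_bundle(n_study = 6)
  tr <- make_binding_truth(b, seed = 2)
  cfg <- sim_config(n_reads = 6000, pcr_duplication_rate = 0.3,
                    contaminant_rate = 0.1)
  sim <- simulate_crac_reads(tr, b, "control", cfg, seed = 7)
  pp <- preprocess_reads(sim$reads, cfg$barcode_table, cfg$adapter)
  st <- pp$stats[pp$stats$sample == "control", ]
  expect_equal(st$input_reads,
               st$discarded_uncalled + st$discarded_short +
                 st$duplicates_removed + st$entropy_removed + st$surviving)
  expect_equal(st$input_reads + nrow(pp$unassigned), 6000)

  surv <- pp$samples$control
  truth <- sim$truth
  cat_of <- truth$category[match(surv$id, truth$read_id)]
  ## no planted contaminant survives collapsed + entropy filtering
  n_contam_in <- sum(truth$category == "contaminant" &
                       is.na(truth$duplicate_of))
  n_contam_out <- sum(cat_of == "contaminant")
  expect_lt(n_contam_out / n_contam_in, 0.01)
  ## no error-free genuine read long enough to score was lost to the
  ## entropy filter: every missing genuine read is a duplicate or short
  genuine <- truth[truth$category %in% c("fivep", "pervasive",
                                         "background"), ]
  lost <- genuine[!genuine$read_id %in% surv$id, ]
  dm <- demultiplex(sim$reads, cfg$barcode_table, cfg$umi_length)
  tl <- trim_reads(dm$samples$control, cfg$adapter)
  cd <- collapse_duplicates(tl$reads)
  ef <- entropy_filter(cd$reads)
  lost_entropy <- cd$reads[!cd$reads$id %in% ef$reads$id, ]
  lost_genuine <- lost_entropy[lost_entropy$id %in% genuine$read_id, ]
  expect_equal(sum(nchar(lost_genuine$sequence) >= 10), 0)
})

test_that("re-trimming a trimmed library changes nothing", {
  b <- tiny_bundle(n_study = 4)
  tr <- make_binding_truth(b, stress_model = data.frame(
    condition = "heat", fivep_retention = 0.2, pervasive_retention = 0.5),
    seed = 1)
  cfg <- sim_config(n_reads = 500)
  sim <- simulate_crac_reads(tr, b, "heat", cfg, seed = 8)
  dm <- demultiplex(sim$reads, cfg$barcode_table, cfg$umi_length)
  t1 <- trim_reads(dm$samples$heat, cfg$adapter)
  t2 <- trim_reads(t1$reads, cfg$adapter)
  ## inserts are transcript sequence: adapter gone after the first pass in
  ## virtually every read; where a chance internal match exists the second
  ## pass must at least be a fixed point of the third
  t3 <- trim_reads(t2$reads, cfg$adapter)
  expect_identical(t3$reads, t2$reads)
})
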