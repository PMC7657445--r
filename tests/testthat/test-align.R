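# Exact-match alignment, multi-mapper policy, coverage and summits.

test_that("unique reads map to their locus; absent reads are unmapped", {
  b <- tiny_bundle(n_study = 5)
  seqs <- as.character(transcript_seqs(b))
  tx <- b$transcripts[b$transcripts$id == names(seqs)[1], ]
  frag <- substr(seqs[[1]], 41, 70)
  reads <- data.frame(id = c("hit", "miss"),
                      sequence = c(frag, strrep("ACGTT", 6)),
                      qualities = strrep("I", 30), stringsAsFactors = FALSE)
  al <- align_reads(reads, b, seed = 1)
  expect_equal(al$unmapped, 1)
  a <- al$alignments
  expect_equal(a$read_id, "hit")
  expect_false(a$multimapped)
  expect_equal(a$strand, tx$strand)
  ## the alignment covers transcript positions 41..70
  if (tx$strand == "+") {
    expect_equal(a$start, tx$start + 40)
  } else {
    expect_equal(a$end, tx$end - 40)
  }
  ## reverse-complement input maps to the opposite strand, same locus
  rc <- data.frame(id = "rc",
                   sequence = as.character(
                     Biostrings::reverseComplement(
                       Biostrings::DNAString(frag))),
                   qualities = strrep("I", 30), stringsAsFactors = FALSE)
  arc <- align_reads(rc, b, seed = 1)$alignments
  expect_equal(arc$start, a$start)
  expect_equal(arc$end, a$end)
  expect_true(arc$strand != a$strand)
})

test_that("multi-mappers are split ~50/50 between two planted loci", {
  ## a chromosome containing the same 30-mer twice
  set.seed(5)
  probe <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  b <- list(chroms = Biostrings::DNAStringSet(
    c(chr1 = paste0(left, probe, mid, probe, mid))),
    transcripts = data.frame(), spike_chroms = character(0), rrna = NULL)
  class(b) <- "genome_bundle"
  reads <- data.frame(id = sprintf("r%04d", 1:2000), sequence = probe,
                      qualities = strrep("I", 30), stringsAsFactors = FALSE)
  al <- align_reads(reads, b, seed = 3)$alignments
  expect_true(all(al$multimapped))
  expect_setequal(unique(al$start), c(101, 231))
  frac <- mean(al$start == 101)
  expect_lt(abs(frac - 0.5), qnorm(0.995) * sqrt(0.25 / 2000))
  ## deterministic given the seed, conservation of read counts
  al2 <- align_reads(reads, b, seed = 3)
  expect_identical(al2$alignments, al)
  expect_equal(nrow(al2$alignments) + al2$unmapped, 2000)

  empty <- b
  empty$chroms <- Biostrings::DNAStringSet()
  expect_error(align_reads(reads, empty), "empty genome")
})

test_that("simulated unique-insert reads map back to their true locus", {
  b <- tiny_bundle(n_study = 6)
  tr <- make_binding_truth(b, background_share = 0, seed = 2)
  cfg <- sim_config(n_reads = 2000)
  sim <- simulate_crac_reads(tr, b, "control", cfg, seed = 4)
  pp <- preprocess_reads(sim$reads, cfg$barcode_table, cfg$adapter)
  al <- align_reads(pp$samples$control, b, seed = 5)
  a <- al$alignments[!al$alignments$multimapped, ]
  truth <- sim$truth[match(a$read_id, sim$truth$read_id), ]
  got5p <- ifelse(a$strand == "+", a$start, a$end)
  expect_equal(a$chrom, truth$chrom)
  expect_equal(a$strand, truth$strand)
  expect_equal(got5p, truth$gpos)
})

test_that("coverage equals a brute-force per-base tally and scales to RPM", {
  b <- manual_bundle()
  al <- manual_alignments(c(1, 1, 5, 300), width = 30)
  cov <- compute_coverage(al, b, "raw")
  v <- as.numeric(cov$cov[["+"]][["chr1"]])
  want <- numeric(700)
  for (i in seq_len(nrow(al)))
    want[al$start[i]:al$end[i]] <- want[al$start[i]:al$end[i]] + 1
  expect_equal(v, want)
  expect_equal(sum(v) / 30, nrow(al))

  rpm <- compute_coverage(al, b, "rpm")
  expect_equal(rpm$scale_factor, 1e6 / 4)
  expect_error(compute_coverage(al[0, ], b, "rpm"), "zero aligned")
})

test_that("summit calling is greedy with separation and tie rules", {
  b <- manual_bundle()
  ## single spike
  al <- manual_alignments(rep(50, 3), width = 1)
  cov <- compute_coverage(al, b, "raw")
  s <- find_summits(cov, "chr1", "+", region = c(1, 700), top_k = 2)
  expect_equal(s$position, 150)
  expect_equal(s$height, 3)

  ## two spikes 5 nt apart with min_separation 10: only the taller kept
  al2 <- manual_alignments(c(rep(50, 3), rep(55, 2)), width = 1)
  cov2 <- compute_coverage(al2, b, "raw")
  s2 <- find_summits(cov2, "chr1", "+", region = c(1, 700), top_k = 2,
                     min_separation = 10)
  expect_equal(s2$position, 150)

  ## random track equals an exhaustive greedy oracle
  set.seed(9)
  pos <- sample(1:400, 200, TRUE)
  al3 <- manual_alignments(pos, width = 1)
  cov3 <- compute_coverage(al3, b, "raw")
  got <- find_summits(cov3, "chr1", "+", region = c(101, 500), top_k = 5,
                      min_separation = 20)
  v <- as.numeric(cov3$cov[["+"]][["chr1"]])[101:500]
  coords <- 101:500
  picked <- integer(0)
  while (length(picked) < 5) {
    ok <- which(vapply(seq_along(v), function(i)
      v[i] > 0 && all(abs(coords[i] - picked) >= 20), logical(1)))
    if (length(ok) == 0) break
    best <- ok[order(-v[ok], coords[ok])][1]
    picked <- c(picked, coords[best])
  }
  expect_equal(got$position, picked)

  expect_error(find_summits(cov3, "chr1", "+", region = c(10, 5)),
               "empty region")
})

test_that("BED and bedGraph round-trips preserve coordinates", {
  b <- manual_bundle()
  al <- manual_alignments(c(1, 10, 50), width = 25)
  d <- withr::local_tempdir()
  bed <- file.path(d, "aln.bed")
  write_alignments_bed(al, bed)
  back <- read_alignments_bed(bed)
  expect_equal(back$start, al$start)
  expect_equal(back$end, al$end)
  expect_equal(back$read_id, al$read_id)

  cov <- compute_coverage(al, b, "rpm")
  paths <- write_coverage_bedgraph(cov, file.path(d, "cov"))
  gr <- rtracklayer::import(file.path(d, "cov_plus.bedgraph"))
  v <- as.numeric(cov$cov[["+"]][["chr1"]]) * cov$scale_factor
  expect_equal(sum(GenomicRanges::width(gr) * gr$score), sum(v))
})
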