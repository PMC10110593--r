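test_that("UMI extraction returns UMIs and rejects malformed reads", {
  lay <- read_layout(umi_length = 8, anchor = "ACGTACGTACGT",
                     anchor_max_mismatch = 1)
  good <- paste0("AAAAAAAA", "ACGTACGTACGT", "GGGGCCCC")
  onemm <- paste0("CCCCCCCC", "TCGTACGTACGT", "GGGG")
  badanchor <- paste0("AAAAAAAA", "TTTTACGTACGT", "GGGG")
  short <- "AAAAAAA"
  ex <- extract_umi(c(good, onemm, badanchor, short), lay)
  expect_equal(ex$accept, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ex$umi[1], "AAAAAAAA")
  expect_equal(ex$insert[1], "GGGGCCCC")
  expect_equal(ex$reason[3], "anchor_mismatch")
  expect_equal(ex$reason[4], "too_short")
})

test_that("UMI consensus applies majority vote, support and tie rules", {
  df <- data.frame(
    sample_id = "s1",
    umi = c(rep("AAAA", 3), rep("CCCC", 1), rep("GGGG", 2), rep("TTTT", 3)),
    insert = c(rep("ACGTACGT", 3),           # identical triple
               "ACGTACGT",                   # singleton (dropped, min_reads 2)
               "ACGTACGT", "ACGTACGA",       # 2 reads, tie at last position
               "ACGTACGT", "ACGTACGT", "ACGAACGT"), # majority wins
    stringsAsFactors = FALSE)
  cons <- consensus_by_umi(df, min_reads = 2)
  cons <- cons[order(cons$umi), ]
  expect_equal(cons$umi, c("AAAA", "TTTT"))
  expect_equal(cons$consensus, c("ACGTACGT", "ACGTACGT"))
  expect_equal(cons$support, c(3L, 3L))
})

test_that("barcode annotation is parsimonious and rejects unusable input", {
  ref <- default_reference()
  germ <- paste0(ref$v_seq, ref$d_seq, ref$j_seq)
  ann <- call_barcode(germ, ref)
  expect_true(ann$accept)
  expect_equal(ann$del_v + ann$del_d5 + ann$del_d3 + ann$del_j +
                 ann$n_ins_vd + ann$n_ins_dj, 0L)
  expect_false(ann$inverted)
  ## no V match: rejected
  bad <- paste0(strrep("T", 40), ref$j_seq)
  expect_false(call_barcode(bad, ref)$accept)
  expect_false(call_barcode(paste0(germ, "N"), ref)$accept)
  ## parsimony equals the enumerate-and-minimize oracle on ambiguous
  ## junctions of the micro cassette
  ref2 <- micro_reference()
  b2 <- micro_bounds()
  set.seed(61)
  seqs <- unique(sample_recombination(micro_model(), ref2, 30)$sequences)
  for (s in seqs) {
    full <- enumerate_scenarios(ref2, s, b2)
    ann2 <- call_barcode(s, ref2, bounds = b2, min_v_match = 1,
                         min_j_match = 1)
    expect_true(ann2$accept)
    expect_equal(ann2$total_edits, min(full$total_edits))
  }
})

test_that("matrix building conserves accepted UMI counts", {
  calls <- data.frame(
    sample_id = c(rep("s1", 5), rep("s2", 2)),
    umi = c("u1", "u2", "u3", "u4", "u5", "u1", "u2"),
    barcode = c(rep("BC1", 5), "BC1", "BC2"),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("s1", "s2"), mouse = "m1",
                        compartment = "M", timepoint = 0, replicate = 1:2,
                        stringsAsFactors = FALSE)
  mat <- build_matrix(calls, samples)
  expect_equal(mat$counts["BC1", "s1"], 5L)
  expect_equal(mat$counts["BC2", "s2"], 1L)
  expect_equal(sum(mat$counts), nrow(calls))
  empty <- build_matrix(calls[0, ], samples)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("replicate filtering drops weak and one-sided detections", {
  counts <- matrix(c(1L, 5L, 4L,
                     2L, 0L, 6L), ncol = 2,
                   dimnames = list(c("BC1", "BC2", "BC3"), c("r1", "r2")))
  samples <- data.frame(sample_id = c("r1", "r2"), mouse = "m1",
                        compartment = "M", timepoint = 0, replicate = 1:2,
                        stringsAsFactors = FALSE)
  mat <- barcode_matrix(counts, samples)
  fm <- filter_matrix(mat, min_umis = 2, require_both_replicates = TRUE)
  ## BC1 below threshold in r1; BC2 absent from r2; BC3 kept and summed
  expect_equal(rownames(fm$counts), "BC3")
  expect_equal(unname(fm$counts[1, 1]), 10L)
  qc <- attr(fm, "qc")
  expect_equal(unname(qc["barcodes_dropped"]), 2)
  ## min_umis = 1 with both replicates still requires two-sided presence
  fm2 <- filter_matrix(mat, min_umis = 1, require_both_replicates = TRUE)
  expect_setequal(rownames(fm2$counts), c("BC1", "BC3"))
})

test_that("normalization yields fractions and the arcsinh transform", {
  counts <- matrix(c(3L, 1L), ncol = 1,
                   dimnames = list(c("BC1", "BC2"), "s1"))
  samples <- data.frame(sample_id = "s1", mouse = "m1", compartment = "M",
                        timepoint = 0, stringsAsFactors = FALSE)
  mat <- normalize_and_transform(barcode_matrix(counts, samples))
  expect_equal(colSums(mat$fractions), c(s1 = 1))
  expect_equal(unname(mat$transformed["BC1", 1]), asinh(0.75))
  ## single-barcode sample: fraction 1, asinh(1) = log(1 + sqrt(2))
  one <- normalize_and_transform(barcode_matrix(
    matrix(7L, 1, 1, dimnames = list("BC1", "s1")), samples))
  expect_equal(unname(one$fractions[1, 1]), 1)
  expect_equal(unname(one$transformed[1, 1]), log(1 + sqrt(2)),
               tolerance = 1e-12)
  zero <- barcode_matrix(matrix(0L, 1, 1, dimnames = list("BC1", "s1")),
                         samples)
  expect_error(normalize_and_transform(zero), "zero")
})

test_that("replicate concordance matches direct formula evaluation", {
  samples <- data.frame(sample_id = c("r1", "r2"), mouse = "m1",
                        compartment = "M", timepoint = 0, replicate = 1:2,
                        stringsAsFactors = FALSE)
  ident <- barcode_matrix(
    matrix(c(5L, 3L, 2L, 5L, 3L, 2L), ncol = 2,
           dimnames = list(c("A", "B", "C"), c("r1", "r2"))), samples)
  rc <- replicate_concordance(ident)
  expect_equal(rc$overlap, 1)
  expect_equal(rc$correlation, 1)
  disj <- barcode_matrix(
    matrix(c(5L, 0L, 0L, 3L), ncol = 2,
           dimnames = list(c("A", "B"), c("r1", "r2"))), samples)
  expect_equal(replicate_concordance(disj)$overlap, 0)
  ## hand-computed three-barcode example
  counts <- matrix(c(6L, 3L, 1L, 2L, 0L, 8L), ncol = 2,
                   dimnames = list(c("A", "B", "C"), c("r1", "r2")))
  hand_overlap <- 2 / 3
  f1 <- counts[, 1] / sum(counts[, 1])
  f2 <- counts[, 2] / sum(counts[, 2])
  hand_cor <- cor(asinh(f1), asinh(f2))
  rc3 <- replicate_concordance(barcode_matrix(counts, samples))
  expect_equal(rc3$overlap, hand_overlap)
  expect_equal(rc3$correlation, hand_cor)
})

test_that("zero-error pipeline recovers clone fractions without false positives", {
  set.seed(62)
  pop <- simulate_clone_population(80, labeling_efficiency = 1)
  spec <- sample_spec(compartment = "M", cells_sampled = 3000,
                      seq_error_rate = 0, reads_per_umi = 3)
  sim <- simulate_reads(pop, spec)
  res <- call_reads(sim$reads, default_reference())
  mat <- build_matrix(res$calls, sim$samples)
  fm <- filter_matrix(mat)
  ## no barcode that is not a true clone barcode survives filtering
  expect_length(setdiff(rownames(fm$counts), pop$clones$barcode), 0)
  ## recovered fractions track true sampled-cell fractions
  tr <- aggregate(cells ~ barcode, data = sim$truth, sum)
  tr <- tr[tr$cells > 0, ]
  got <- rowSums(fm$counts)[match(tr$barcode, rownames(fm$counts))]
  got[is.na(got)] <- 0
  expect_gt(cor(tr$cells, got, method = "spearman"), 0.95)
})

test_that("pipeline output is deterministic given identical inputs", {
  set.seed(63)
  pop <- simulate_clone_population(20, labeling_efficiency = 1)
  sim <- simulate_reads(pop, sample_spec(compartment = "M",
                                         cells_sampled = 150))
  r1 <- call_reads(sim$reads, default_reference())
  r2 <- call_reads(sim$reads, default_reference())
  expect_identical(r1, r2)
})
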