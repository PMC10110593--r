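test_that("clone population honors class structure and sizes", {
  expect_equal(nrow(simulate_clone_population(0)$clones), 0L)
  set.seed(41)
  pop <- simulate_clone_population(
    100, class_proportions = c(HSPC = 1), labeling_efficiency = 0.5)
  expect_true(all(pop$clones$cells_MP == 0))
  expect_true(all(pop$clones$cells_M == 0))
  expect_true(all(pop$clones$cells_HSPC > 0))
  ## default proportions include the 13.7% multi-outcome class and sum to 1
  cp <- default_class_proportions()
  expect_equal(sum(cp), 1)
  expect_equal(unname(cp["HSPC-MP-M"]), 0.137)
  ## recovered class fraction within the binomial 95% CI at n = 3000
  set.seed(42)
  pop2 <- simulate_clone_population(3000)
  phat <- mean(pop2$clones$fate_class == "HSPC-MP-M")
  ci <- 0.137 + c(-1, 1) * 1.96 * sqrt(0.137 * 0.863 / 3000)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
  ## compartment counts are zero exactly off the fate class
  parts <- strsplit(pop2$clones$fate_class, "-")
  for (comp in c("HSPC", "MP", "M")) {
    inc <- vapply(parts, function(x) comp %in% x, logical(1))
    expect_identical(pop2$clones[[paste0("cells_", comp)]] > 0, inc)
  }
  ## barcodes unique and producible
  expect_false(anyDuplicated(pop2$clones$barcode) > 0)
  set.seed(43)
  sub <- sample(pop2$clones$barcode, 20)
  expect_true(all(compute_pgen(default_model(), default_reference(), sub) > 0))
})

test_that("default myeloid clone sizes span the 100 to 10,000 cell range", {
  set.seed(44)
  pop <- simulate_clone_population(2000)
  msz <- pop$clones$cells_M[pop$clones$cells_M > 0]
  expect_lt(quantile(msz, 0.05), 150)
  expect_gt(quantile(msz, 0.95), 5000)
  expect_gt(mean(msz >= 100 & msz <= 10000), 0.85)
})

test_that("read simulation conserves counts and respects error settings", {
  set.seed(45)
  pop <- simulate_clone_population(50, labeling_efficiency = 1)
  spec <- sample_spec(compartment = "M", cells_sampled = 500,
                      seq_error_rate = 0)
  sim <- simulate_reads(pop, spec)
  ## conservation: truth read counts match emitted records
  expect_equal(sum(sim$truth$reads), nrow(sim$reads))
  expect_equal(sum(sim$truth$cells), 500L)
  ## zero error: every read is exactly UMI + anchor + true barcode
  lay <- read_layout()
  bc <- substr(sim$reads$sequence, lay$umi_length + nchar(lay$anchor) + 1L,
               nchar(sim$reads$sequence))
  truth_bc <- pop$clones$barcode[match(sim$reads$clone_id,
                                       pop$clones$clone_id)]
  expect_identical(bc, truth_bc)
  ## a clone with 0 cells in the compartment emits 0 reads
  zero <- sim$truth$cells == 0
  expect_true(all(sim$truth$reads[zero] == 0))
  ## oversampling errors out
  expect_error(
    simulate_reads(pop, sample_spec(compartment = "M",
                                    cells_sampled = 10^9)),
    "exceeds")
})

test_that("read simulation is reproducible under a fixed seed", {
  set.seed(46)
  pop <- simulate_clone_population(30, labeling_efficiency = 1)
  spec <- sample_spec(compartment = "M", cells_sampled = 200)
  set.seed(47)
  a <- simulate_reads(pop, spec)
  set.seed(47)
  b <- simulate_reads(pop, spec)
  expect_identical(a, b)
  ## FASTQ round trip preserves ids and sequences
  f <- tempfile(fileext = ".fastq.gz")
  write_fastq(a$reads, f)
  back <- read_fastq(f)
  expect_identical(back$sequence, a$reads$sequence)
  expect_identical(back$read_id, a$reads$read_id)
})

test_that("per-clone UMI counts track true sampled cells", {
  set.seed(48)
  pop <- simulate_clone_population(150, labeling_efficiency = 1)
  spec <- sample_spec(compartment = "M", cells_sampled = 10000,
                      pcr_replicates = 1L, seq_error_rate = 0)
  sim <- simulate_reads(pop, spec)
  tr <- sim$truth[sim$truth$cells > 0, ]
  expect_gt(cor(tr$cells, tr$umis, method = "spearman"), 0.99)
})

test_that("timecourse dynamics realize the programmed trajectory", {
  ## flat truth, no between-mouse variation: conditional expectation constant
  dyn0 <- diversity_dynamics(baseline_log = log(100), slope_before = 0,
                             slope_change = 0, sigma_u = 0, shape = Inf)
  set.seed(49)
  tc0 <- simulate_timecourse(dyn0, mice = 2, timepoints = 4:8, capture = 1,
                             pool_size = 300)
  expect_true(all(tc0$truth$K_true == 100))
  ## full capture, no noise: observed richness equals true active-clone count
  div0 <- timecourse_diversity(tc0, "richness")
  truthK <- tc0$truth$K_true[match(paste(div0$mouse, div0$t),
                                   paste(tc0$truth$mouse, tc0$truth$t))]
  expect_equal(div0$y, truthK)
  ## default dynamics: non-monotone mean diversity with minimum near month 7
  set.seed(50)
  means <- sapply(1:60, function(i) {
    obs <- simulate_diversity_observations(mice = 2)
    tapply(obs$y, obs$t, mean)
  })
  avg <- rowMeans(means)
  tmin <- as.numeric(names(which.min(avg)))
  expect_gte(tmin, 6)
  expect_lte(tmin, 8)
  expect_gt(avg["12"], avg["7"])
  expect_gt(avg["4"], avg["7"])
})

test_that("low blood capture reproduces the replicate-overlap gap", {
  set.seed(51)
  ## blood-like: 5% capture; marrow-like: near-complete capture
  tc_blood <- simulate_timecourse(mice = 2, timepoints = c(6, 8),
                                  capture = 0.05)
  tc_bm <- simulate_timecourse(mice = 2, timepoints = c(6, 8), capture = 0.9)
  jac <- function(tc) {
    ob <- tc$observations
    out <- c()
    for (k in unique(paste(ob$mouse, ob$t))) {
      sub <- ob[paste(ob$mouse, ob$t) == k, ]
      a <- sub$barcode[sub$replicate == 1]
      b <- sub$barcode[sub$replicate == 2]
      if (length(a) && length(b))
        out <- c(out, length(intersect(a, b)) / length(union(a, b)))
    }
    mean(out)
  }
  expect_lt(jac(tc_blood), 0.2)
  expect_gt(jac(tc_bm), 0.6)
})
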