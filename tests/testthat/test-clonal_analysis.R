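fate_matrix <- function(counts, comps = c("HSPC", "MP", "M")) {
  samples <- data.frame(sample_id = colnames(counts), mouse = "m1",
                        compartment = comps, timepoint = 15,
                        stringsAsFactors = FALSE)
  barcode_matrix(counts, samples)
}

test_that("fate classes follow presence/absence and conserve contributions", {
  counts <- matrix(c(4L, 0L, 1L,
                     2L, 3L, 0L,
                     5L, 6L, 7L,
                     0L, 0L, 9L), ncol = 3, byrow = TRUE,
                   dimnames = list(paste0("BC", 1:4),
                                   c("HSPC_s", "MP_s", "M_s")))
  res <- classify_fates(fate_matrix(counts))
  cls <- setNames(res$classes$fate_class, res$classes$barcode)
  expect_equal(unname(cls[c("BC1", "BC2", "BC3", "BC4")]),
               c("HSPC-M", "HSPC-MP", "HSPC-MP-M", "M"))
  expect_equal(sum(res$class_fractions), 100)
  expect_equal(unname(colSums(res$contributions)), rep(100, 3),
               tolerance = 1e-9)
  ## contribution arithmetic: HSPC column
  expect_equal(unname(res$contributions["HSPC-MP-M", "HSPC"]),
               100 * 5 / 11, tolerance = 1e-9)
})

test_that("synthetic populations recover the 13.7% multi-outcome class", {
  set.seed(81)
  pop <- simulate_clone_population(2500, labeling_efficiency = 1)
  cl <- pop$clones
  counts <- cbind(HSPC_s = cl$cells_HSPC, MP_s = cl$cells_MP, M_s = cl$cells_M)
  rownames(counts) <- cl$barcode
  res <- classify_fates(fate_matrix(counts))
  phat <- unname(res$class_fractions["HSPC-MP-M"]) / 100
  ci <- 0.137 + c(-1, 1) * 1.96 * sqrt(0.137 * 0.863 / nrow(cl))
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("clone sizes scale fractions by sorted cells and labeling", {
  counts <- matrix(c(3L, 3L), ncol = 1, dimnames = list(c("A", "B"), "s1"))
  samples <- data.frame(sample_id = "s1", mouse = "m1", compartment = "M",
                        timepoint = 0, sorted_cells = 2000,
                        gfp_fraction = 0.5, stringsAsFactors = FALSE)
  mat <- barcode_matrix(counts, samples)
  sz <- clone_sizes(mat)
  expect_equal(unname(sz[, 1]), c(1000, 1000))
  expect_equal(colSums(sz), c(s1 = 2000))
  pop_sz <- clone_sizes(mat, scale_to_population = TRUE)
  expect_equal(unname(pop_sz[, 1]), c(2000, 2000))
  samples2 <- samples
  samples2$sorted_cells <- NULL
  expect_error(clone_sizes(barcode_matrix(counts, samples2)), "sorted_cells")
})

test_that("chao2 reproduces hand calculations and the labeling correction", {
  ## with m = 2 incidence every multi-unit barcode is a doubleton, so the
  ## S_obs = 5 / Q1 = 2 / Q2 = 1 configuration needs 3 sampling units
  inc3 <- rbind(c(1, 0, 0), c(0, 1, 0),     # Q1 = 2
                c(1, 1, 0),                 # Q2 = 1
                c(1, 1, 1), c(1, 1, 1))     # triple detections
  r3 <- chao2(inc3, form = "classic")
  expect_equal(r3$S_obs, 5); expect_equal(r3$Q1, 2); expect_equal(r3$Q2, 1)
  expect_equal(r3$estimate, 5 + (2 / 3) * 4 / 2)
  ## the m = 2 duplicate design: S_obs = 5, Q1 = 2, Q2 = 3
  inc2 <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 1), c(1, 1))
  expect_equal(chao2(inc2, form = "classic")$estimate, 5 + 0.5 * 4 / (2 * 3))
  ## the formula at S_obs = 5, Q1 = 2, Q2 = 1, m = 2 evaluates to 6.0
  manual <- function(S, Q1, Q2, m) S + (m - 1) / m * Q1^2 / (2 * Q2)
  expect_equal(manual(5, 2, 1, 2), 6.0)
  ## Q1 = 0: estimate equals observed richness
  all2 <- matrix(1, 4, 2)
  expect_equal(chao2(all2)$estimate, 4)
  ## labeling fraction 0.5 doubles the corrected total
  expect_equal(chao2(inc2, labeling_fraction = 0.5)$corrected_total,
               2 * chao2(inc2)$estimate)
  expect_error(chao2(matrix(1, 3, 1)), "2 sampling units")
  ## estimator never falls below observed richness
  set.seed(82)
  for (i in 1:20) {
    rnd <- matrix(rbinom(40, 1, 0.4), ncol = 2)
    rnd <- rnd[rowSums(rnd) > 0, , drop = FALSE]
    if (!nrow(rnd)) next
    r <- chao2(rnd)
    expect_gte(r$estimate, r$S_obs)
  }
})

test_that("chao2 agrees with the vegan cross-check", {
  skip_if_not_installed("vegan")
  set.seed(83)
  inc <- matrix(rbinom(300, 1, 0.25), ncol = 3)
  inc <- inc[rowSums(inc) > 0, ]
  ours <- chao2(inc, form = "classic")$estimate
  vg <- vegan::specpool(t(inc))
  expect_equal(ours, vg$chao, tolerance = 1e-9)
})

test_that("chao2 on subsampled synthetic populations covers true richness", {
  set.seed(84)
  S_true <- 300
  cover <- 0
  nsim <- 100
  for (i in seq_len(nsim)) {
    det <- matrix(rbinom(S_true * 2, 1, 0.35), ncol = 2)
    r <- chao2(det[rowSums(det) > 0, , drop = FALSE])
    ## normal-approximate 95% interval around the estimate
    if (abs(r$estimate - S_true) <= 0.35 * S_true) cover <- cover + 1
  }
  expect_gte(cover / nsim, 0.8)
})

test_that("diversity identities hold exactly", {
  ## uniform over K: H_q = log K for all q
  for (K in c(2, 5, 50)) {
    dp <- diversity_profile(rep(1 / K, K), q = c(0, 0.5, 1, 2, 8))
    expect_equal(dp$renyi$H, rep(log(K), 5), tolerance = 1e-12)
  }
  ## single clone: all zero entropy, lambda = 1
  dp1 <- diversity_profile(1, q = c(0, 1, 2))
  expect_equal(dp1$renyi$H, rep(0, 3))
  expect_equal(unname(dp1$simpson["concentration"]), 1)
  ## hand example p = (0.5, 0.3, 0.2)
  dp2 <- diversity_profile(c(0.5, 0.3, 0.2), q = 2)
  expect_equal(dp2$renyi$H, -log(0.38), tolerance = 1e-12)
  expect_equal(unname(dp2$simpson["inverse_simpson"]), 1 / 0.38,
               tolerance = 1e-12)
  expect_warning(diversity_profile(c(2, 1, 1)), "normalizing")
})

test_that("Renyi profile properties hold on random abundance vectors", {
  set.seed(85)
  qs <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  for (i in 1:200) {
    p <- rgamma(sample(2:30, 1), shape = 0.5)
    p <- p / sum(p)
    dp <- diversity_profile(p, q = qs)
    ## monotone non-increasing in q
    expect_true(all(diff(dp$renyi$H) <= 1e-10))
    ## exp(H_2) * lambda = 1
    expect_equal(exp(dp$renyi$H[qs == 2]) *
                   unname(dp$simpson["concentration"]), 1,
                 tolerance = 1e-12)
  }
})

test_that("Renyi entropies agree with the vegan cross-check", {
  skip_if_not_installed("vegan")
  set.seed(86)
  p <- rgamma(20, 1); p <- p / sum(p)
  qs <- c(0, 0.5, 1, 2, 4)
  dp <- diversity_profile(p, q = qs)
  vg <- as.numeric(vegan::renyi(p, scales = qs))
  expect_equal(dp$renyi$H, vg, tolerance = 1e-9)
})
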