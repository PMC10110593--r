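test_that("enumeration matches the exhaustive brute-force oracle", {
  ## tiny reference with a highly ambiguous junction
  ref <- cassette_reference("AA", "A", "CC", "ACGT", "ACGT")
  b <- list(del_v = 2L, del_d5 = 1L, del_d3 = 1L, del_j = 2L,
            ins_vd = 1L, ins_dj = 1L)
  e <- enumerate_scenarios(ref, "AAACC", b)
  o <- brute_enumerate(ref, "AAACC", b)
  expect_identical(scenario_key(e), scenario_key(o))
  ## the micro cassette over sampled sequences
  ref2 <- micro_reference()
  b2 <- micro_bounds()
  set.seed(21)
  seqs <- unique(sample_recombination(micro_model(), ref2, 40)$sequences)
  for (s in seqs) {
    e2 <- enumerate_scenarios(ref2, s, b2)
    o2 <- brute_enumerate(ref2, s, b2)
    expect_identical(scenario_key(e2), scenario_key(o2))
  }
})

test_that("germline concatenation and unproducible sequences behave", {
  ref <- micro_reference()
  b <- micro_bounds()
  germ <- paste0(ref$v_seq, ref$d_seq, ref$j_seq)
  e <- enumerate_scenarios(ref, germ, b)
  zero <- e$del_v == 0 & e$del_d5 == 0 & e$del_d3 == 0 & e$del_j == 0 &
    e$ins_vd == "" & e$ins_dj == "" & !e$inverted
  expect_equal(sum(zero), 1L)
  ## a sequence that cannot be produced: wrong V start
  expect_equal(nrow(enumerate_scenarios(ref, "TTTTTTTTTTTTTTT", b)), 0L)
  expect_equal(compute_pgen(micro_model(), ref, "TTTTTTTTTTTTTTT"), 0)
})

test_that("enumeration order is deterministic and lexicographic", {
  ref <- cassette_reference("AA", "A", "CC", "ACGT", "ACGT")
  b <- list(del_v = 2L, del_d5 = 1L, del_d3 = 1L, del_j = 2L,
            ins_vd = 1L, ins_dj = 1L)
  e <- enumerate_scenarios(ref, "AAACC", b)
  key <- paste(e$inverted, e$del_v, e$del_d5, e$del_d3, e$del_j,
               e$ins_vd, e$ins_dj)
  ord <- order(e$inverted, e$del_v, e$del_d5, e$del_d3, e$del_j,
               e$ins_vd, e$ins_dj)
  expect_identical(ord, seq_len(nrow(e)))
  expect_identical(e, enumerate_scenarios(ref, "AAACC", b))
})

test_that("compute_pgen equals the exhaustive scenario-probability sum", {
  ref <- micro_reference()
  m <- micro_model()
  b <- micro_bounds()
  set.seed(22)
  seqs <- unique(sample_recombination(m, ref, 60)$sequences)
  for (s in seqs) {
    pg <- compute_pgen(m, ref, s)
    brute <- sum(scenario_probability(m, brute_enumerate(ref, s, b)))
    expect_equal(pg, brute, tolerance = 1e-12)
  }
})

test_that("pgen sums to 1 over the full producible sequence space", {
  ref <- micro_reference()
  m <- micro_model()
  seqs <- unique(realize_scenario(ref, brute_scenarios(ref, micro_bounds())))
  total <- sum(compute_pgen(m, ref, seqs))
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("point-mass model gives pgen 1 for the germline sequence", {
  ref <- micro_reference()
  pm <- point_mass_model()
  germ <- paste0(ref$v_seq, ref$d_seq, ref$j_seq)
  expect_equal(compute_pgen(pm, ref, germ), 1.0)
  expect_equal(compute_pgen(pm, ref, paste0("A", germ)), 0.0)
})

test_that("pgen agrees with Monte-Carlo frequency on a micro model", {
  ref <- micro_reference()
  m <- micro_model()
  set.seed(23)
  n <- 200000
  seqs <- sample_recombination(m, ref, n)$sequences
  tab <- sort(table(seqs), decreasing = TRUE)[1:5]
  for (s in names(tab)) {
    phat <- as.numeric(tab[s]) / n
    pg <- compute_pgen(m, ref, s)
    se <- sqrt(pg * (1 - pg) / n)
    expect_lt(abs(phat - pg), 3 * se + 1e-9)
  }
})

test_that("every sampled scenario is found by enumeration (round trip)", {
  ref <- micro_reference()
  b <- micro_bounds()
  set.seed(24)
  s <- sample_recombination(micro_model(), ref, 100)
  for (i in seq_len(50)) {
    e <- enumerate_scenarios(ref, s$sequences[i], b)
    key <- paste(e$inverted, e$del_v, e$del_d5, e$del_d3, e$del_j,
                 e$ins_vd, e$ins_dj)
    sc <- s$scenarios[i, ]
    k <- paste(sc$inverted, sc$del_v, sc$del_d5, sc$del_d3, sc$del_j,
               sc$ins_vd, sc$ins_dj)
    expect_true(k %in% key)
  }
})

test_that("edit-capped enumeration returns exactly the within-cap subset", {
  ref <- micro_reference()
  b <- micro_bounds()
  set.seed(25)
  seqs <- unique(sample_recombination(micro_model(), ref, 20)$sequences)
  for (s in seqs[1:10]) {
    full <- enumerate_scenarios(ref, s, b)
    capped <- enumerate_scenarios(ref, s, b, max_total_edits = 3)
    expect_identical(scenario_key(capped),
                     scenario_key(full[full$total_edits <= 3, ]))
  }
})
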