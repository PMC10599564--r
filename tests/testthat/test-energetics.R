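test_that("scoring reproduces constant and enumerated expectations", {
  zero <- potts_model(matrix(0, 9, 4), matrix(0, 36, 16))
  ens <- sample_random_sequences(100, seed = 71)
  prof <- score_ensemble(zero, ens)
  expect_true(all(prof$energies == 0))
  expect_equal(prof$summary$sd, 0)
  # fields-only model scored on its consensus repeated: constant energies
  h <- splicepotts:::.default_field_template(1)
  mf <- potts_model(h, matrix(0, 36, 16))
  rep_ens <- donor_ensemble(rep("CAGGTAAGT", 7))
  prof2 <- score_ensemble(mf, rep_ens)
  expect_equal(prof2$energies, rep(-sum(apply(h, 1, max)), 7))
  # mean energy of the model's own samples near the enumerated expectation
  mo <- make_random_potts(72, n_couplings = 10)
  E <- splicepotts:::cpp_all_energies(mo$h, mo$J)
  p <- exp(-E - partition_function(mo))
  expected <- sum(p * E)
  sdE <- sqrt(sum(p * (E - expected)^2))
  n <- 5e4
  own <- sample_sequences(mo, n, seed = 73)
  prof3 <- score_ensemble(mo, own)
  expect_lt(abs(prof3$summary$mean - expected), 4 * sdE / sqrt(n))
  # quantile bracket covers >= 90% of values
  q <- prof3$summary$quantiles
  covered <- mean(prof3$energies >= q[["5%"]] & prof3$energies <= q[["95%"]])
  expect_gte(covered, 0.9 - 1e-9)
})

test_that("uniform random sequences match binomial frequency bounds", {
  n <- 10000
  ens <- sample_random_sequences(n, seed = 74)
  expect_identical(sample_random_sequences(5, seed = 1)$sequences,
                   sample_random_sequences(5, seed = 1)$sequences)
  expect_equal(length(sample_random_sequences(1, seed = 2)), 1L)
  f <- estimate_marginals(ens, 0)$f1
  expect_true(all(abs(f - 0.25) <= 4 * sqrt(0.25 * 0.75 / n)))
})

test_that("decoy windows are read off GT loci and split by annotation", {
  # single GT locus with known flanks
  g <- Biostrings::DNAStringSet(
    c(chr = "AAACCCGTTCCCAAATTTAAATTTAAATTTAAA"))
  # forward GT at positions 7-8: window = pos 4..12 = CCC|GT|TCCC
  ann_miss <- donor_ensemble("AAAGTAAAA") # not the window
  dec <- sample_decoys(g, ann_miss, 200, seed = 75)
  both <- c(dec$decoy_a$sequences, dec$decoy_b$sequences)
  expect_true("CCCGTTCCC" %in% both)
  expect_true(all(substr(both, 4, 5) == "GT"))
  expect_true("CCCGTTCCC" %in% dec$decoy_a$sequences)
  # same window annotated -> lands in decoy_b
  dec2 <- sample_decoys(g, donor_ensemble("CCCGTTCCC"), 200, seed = 75)
  expect_true("CCCGTTCCC" %in% dec2$decoy_b$sequences)
  expect_length(intersect(dec2$decoy_a$sequences, dec2$decoy_b$sequences), 0)
  expect_error(sample_decoys(Biostrings::DNAStringSet(c(x = "AAAAAA")),
                             ann_miss, 10), "no GT loci")
})

test_that("decoy-B fraction tracks the planted annotation rate", {
  # plant a genome from annotated donors: a known share of its GT windows
  # spell annotated donor sequences
  planted <- sample_random_sequences(300, seed = 76)
  planted <- restrict_gt(donor_ensemble(
    paste0(substr(planted$sequences, 1, 3), "GT",
           substr(planted$sequences, 6, 9)), gt_restricted = FALSE))
  pg <- make_planted_genome(planted, seed = 77)
  genome <- Biostrings::DNAStringSet(pg$genome)
  dec <- sample_decoys(genome, planted, 20000, seed = 78)
  frac_b <- length(dec$decoy_b) / dec$n_unique
  # every planted junction window is annotated; background GT windows are
  # mostly random 7-mers, so decoy-B must be a clear minority yet present
  expect_gt(frac_b, 0)
  expect_lt(frac_b, 0.5)
  expect_equal(dec$n_unique, length(dec$decoy_a) + length(dec$decoy_b))
})

test_that("rank-sum comparison matches exact small-sample enumeration", {
  a <- c(1.1, 2.3, 3.1, 4.7, 5.2)
  b <- c(2.0, 3.3, 4.1, 6.0, 7.5)
  res <- rank_sum_compare(a, b)
  # exact U statistic by pair counting
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(res$statistic, U)
  # exact two-sided p by full enumeration of 10-choose-5 assignments
  pool <- c(a, b)
  combs <- combn(10, 5)
  Us <- apply(combs, 2, function(idx) {
    sum(outer(pool[idx], pool[-idx], ">"))
  })
  p_exact <- mean(abs(Us - 12.5) >= abs(U - 12.5))
  expect_lt(abs(res$p_value - p_exact), 0.1) # normal approx vs exact
  # identity and large-shift behavior
  expect_gt(rank_sum_compare(a, a)$p_value, 0.9)
  x <- rnorm(200)
  strong <- rank_sum_compare(x, x + 10)
  expect_lt(strong$p_value, 1e-10)
  # symmetry up to reflection of the statistic
  ab <- rank_sum_compare(a, b)
  ba <- rank_sum_compare(b, a)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$statistic + ba$statistic, 25) # U + U' = n1 n2
  expect_error(rank_sum_compare(numeric(0), a), "non-empty")
})

test_that("minimum-energy search is an exhaustive scan with lexicographic ties", {
  zero <- potts_model(matrix(0, 9, 4), matrix(0, 36, 16))
  res <- minimum_energy_sequence(zero, "all_states")
  expect_equal(res$sequence, "AAAAAAAAA")
  expect_equal(res$energy, 0)
  # fields-only model built from a consensus-dominated ensemble
  ens <- donor_ensemble(c(rep("CAGGTAAGT", 50), "AAGGTAAGT"))
  f <- estimate_marginals(ens, pseudocount = 1)$f1
  mf <- potts_model(log(f), matrix(0, 36, 16))
  expect_equal(minimum_energy_sequence(mf, "all_states")$sequence,
               "CAGGTAAGT")
  # equals an independent re-scan in shuffled order
  mo <- make_random_potts(79, n_couplings = 10)
  res2 <- minimum_energy_sequence(mo, "all_states")
  E <- r_all_state_energies(mo)
  ord <- sample(length(E))
  best <- ord[which.min(E[ord])]
  expect_equal(res2$energy, E[best], tolerance = 1e-12)
  expect_equal(res2$sequence,
               splicepotts:::cpp_decode_donor(best - 1L))
  # ensemble scope
  sub <- sample_random_sequences(100, seed = 80)
  res3 <- minimum_energy_sequence(mo, "ensemble", ensemble = sub)
  expect_equal(res3$energy, min(energy(mo, sub)))
  expect_error(minimum_energy_sequence(mo, "ensemble"), "requires")
})

test_that("energy ordering: own samples < GT decoy-like < uniform random", {
  mo <- cached_fit("panel_fit_one", function() {
    panel <- make_species_panel(species_per_group = 1, n_sequences = 20000,
                                seed = 81)
    ens <- panel$ensembles[[1]]
    fit_maxent(estimate_marginals(ens, 1), gamma = 0.025)
  })
  own <- sample_sequences(mo, 2000, seed = 82)
  rand <- sample_random_sequences(2000, seed = 83)
  # decoy-like: keep the GT core but randomize flanks
  decoyish <- donor_ensemble(paste0(
    substr(sample_random_sequences(2000, seed = 84)$sequences, 1, 3), "GT",
    substr(sample_random_sequences(2000, seed = 85)$sequences, 6, 9)))
  e_own <- score_ensemble(mo, own)$summary$mean
  e_dec <- score_ensemble(mo, decoyish)$summary$mean
  e_rand <- score_ensemble(mo, rand)$summary$mean
  expect_lt(e_own, e_dec)
  expect_lt(e_dec, e_rand)
})
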