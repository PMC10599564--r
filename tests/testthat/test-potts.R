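zero_model <- function() potts_model(matrix(0, 9, 4), matrix(0, 36, 16))

test_that("the model exposes 36 field and 576 coupling parameters", {
  mo <- zero_model()
  expect_equal(length(mo$h), 36L)
  expect_equal(length(mo$J), 576L)
})

test_that("energy matches closed forms and a term-by-term oracle", {
  mo <- zero_model()
  expect_equal(energy(mo, c("CAGGTAAGT", "AAAAAAAAA")), c(0, 0))
  # single nonzero field h_{+1}(G) = 2
  h <- matrix(0, 9, 4)
  h[4, 3] <- 2
  m1 <- potts_model(h, matrix(0, 36, 16))
  expect_equal(energy(m1, "CAGGTAAGT"), -2)
  # random model, random sequences vs independent summation
  mo2 <- make_random_potts(41, n_couplings = 25)
  seqs <- sample_random_sequences(50, seed = 42)
  oracle <- vapply(seqs$sequences, function(s) {
    letters <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    e <- 0
    for (i in 1:9) e <- e - mo2$h[i, letters[i]]
    for (i in 1:8) for (j in (i + 1):9) {
      k <- which(splicepotts:::.pair_table$i == i &
                   splicepotts:::.pair_table$j == j)
      e <- e - mo2$J[k, (letters[i] - 1) * 4 + letters[j]]
    }
    e
  }, numeric(1))
  expect_equal(energy(mo2, seqs), unname(oracle), tolerance = 1e-12)
})

test_that("log Z matches closed forms and the enumeration oracle", {
  expect_equal(partition_function(zero_model()), 9 * log(4),
               tolerance = 1e-10)
  # fields-only factorization
  set.seed(43)
  h <- matrix(rnorm(36), 9, 4)
  mf <- potts_model(h, matrix(0, 36, 16))
  expect_equal(partition_function(mf),
               sum(log(rowSums(exp(h)))), tolerance = 1e-10)
  # random sparse model vs direct summation over a materialized state list
  mo <- make_random_potts(44, n_couplings = 15)
  E <- r_all_state_energies(mo)
  m <- min(E)
  expect_equal(partition_function(mo), log(sum(exp(m - E))) - m,
               tolerance = 1e-9)
})

test_that("sequence probabilities normalize and reduce to site products", {
  mo <- zero_model()
  expect_equal(sequence_probability(mo, "CAGGTAAGT"), 1 / 262144)
  # probabilities over all states sum to 1
  mo2 <- make_random_potts(45, n_couplings = 20)
  E <- splicepotts:::cpp_all_energies(mo2$h, mo2$J)
  expect_equal(sum(exp(-E - partition_function(mo2))), 1, tolerance = 1e-9)
  # fields-only model with h = log f gives the independent-sites product
  ens <- sample_random_sequences(400, seed = 46)
  f <- estimate_marginals(ens, pseudocount = 1)$f1
  mf <- potts_model(log(f), matrix(0, 36, 16))
  some <- c("CAGGTAAGT", "AAAAAAAAA", "TTTTTTTTT")
  prod_oracle <- vapply(some, function(s) {
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    prod(f[cbind(1:9, idx)])
  }, numeric(1))
  expect_equal(sequence_probability(mf, some), unname(prod_oracle),
               tolerance = 1e-9)
})

test_that("model marginals are exact: uniform, independence, sampling", {
  mm0 <- model_marginals(zero_model())
  expect_equal(unname(mm0$f1), matrix(0.25, 9, 4), tolerance = 1e-12)
  expect_equal(unname(mm0$f2), matrix(0.0625, 36, 16), tolerance = 1e-12)
  # fields-only: P_ij = P_i P_j for all pairs
  set.seed(47)
  mf <- potts_model(matrix(rnorm(36), 9, 4), matrix(0, 36, 16))
  mm <- model_marginals(mf)
  pt <- splicepotts:::.pair_table
  for (k in 1:36) {
    expect_equal(unname(mm$f2[k, ]),
                 as.vector(t(outer(mm$f1[pt$i[k], ], mm$f1[pt$j[k], ]))),
                 tolerance = 1e-10)
  }
  # sampling oracle: empirical marginals of exact draws within 4 sigma
  mo <- make_random_potts(48, n_couplings = 12)
  mmo <- model_marginals(mo)
  n <- 2e5
  ens <- sample_sequences(mo, n, seed = 49)
  emp <- estimate_marginals(ens, 0)
  sd1 <- sqrt(mmo$f1 * (1 - mmo$f1) / n)
  expect_true(all(abs(emp$f1 - mmo$f1) <= 4 * sd1 + 1e-12))
})

test_that("gauge covariance: shifting one position's fields is harmless", {
  mo <- make_random_potts(50, n_couplings = 10)
  shifted <- mo
  shifted$h[3, ] <- shifted$h[3, ] + 1.7
  seqs <- sample_random_sequences(20, seed = 51)
  expect_equal(energy(shifted, seqs), energy(mo, seqs) - 1.7)
  expect_equal(sequence_probability(shifted, seqs),
               sequence_probability(mo, seqs), tolerance = 1e-9)
})

test_that("active_couplings lists exact nonzeros in |J| order", {
  expect_equal(nrow(active_couplings(zero_model())), 0L)
  mo <- make_random_potts(52, n_couplings = 7)
  ac <- active_couplings(mo)
  expect_equal(nrow(ac), sum(mo$J != 0))
  expect_true(all(diff(abs(ac$value)) <= 1e-12))
  expect_match(ac$id, "^[+-][0-9][ACGT]:[+-][0-9][ACGT]$")
})

test_that("sampling is seed-deterministic and uniform for the zero model", {
  mo <- zero_model()
  a <- sample_sequences(mo, 200, seed = 53)
  b <- sample_sequences(mo, 200, seed = 53)
  expect_identical(a$sequences, b$sequences)
  # positionwise letter frequencies of a fields-only model near softmax(h)
  set.seed(54)
  h <- matrix(rnorm(36, 0, 0.8), 9, 4)
  mf <- potts_model(h, matrix(0, 36, 16))
  n <- 5e4
  ens <- sample_sequences(mf, n, seed = 55)
  emp <- estimate_marginals(ens, 0)$f1
  want <- exp(h) / rowSums(exp(h))
  expect_true(all(abs(emp - want) <= 4 * sqrt(want * (1 - want) / n) + 1e-12))
})

test_that("uniform sampling passes a chi-square goodness-of-fit screen", {
  # scaled-down version of the uniform draw check: all-zero model over the
  # 16 (+1,+2) letter pairs
  ens <- sample_sequences(zero_model(), 4e4, seed = 56)
  pairs <- table(substr(ens$sequences, 4, 5))
  chi <- chisq.test(as.vector(pairs), p = rep(1 / 16, 16))
  expect_gt(chi$p.value, 1e-6)
})

test_that("model JSON serialization round-trips including exact zeros", {
  mo <- make_random_potts(57, n_couplings = 9)
  mo$gamma <- 0.025
  path <- withr::local_tempfile(fileext = ".json")
  write_potts(mo, path)
  back <- read_potts(path)
  expect_equal(back$h, mo$h, tolerance = 1e-15)
  expect_equal(back$J, mo$J, tolerance = 1e-15)
  expect_identical(sum(back$J != 0), sum(mo$J != 0))
  expect_equal(back$gamma, 0.025)
})
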