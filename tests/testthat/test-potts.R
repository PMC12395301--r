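test_that("reweighting matches a brute-force neighborhood count", {
  # all records identical
  msa <- new_msa(stats::setNames(rep("ACDE", 4), paste0("s", 1:4)))
  w <- compute_weights(msa)
  expect_equal(unname(w$weights), rep(0.25, 4))
  expect_equal(sum(w$weights), 1)

  # mutually dissimilar records
  msa2 <- new_msa(c(a = "AAAA", b = "CCCC", c = "DDDD"))
  w2 <- compute_weights(msa2)
  expect_equal(unname(w2$weights), rep(1, 3))

  # random toy family against the all-pairs oracle
  seqs <- random_gapped_seqs(20, 10, seed = 5, gap_prob = 0.1)
  msa3 <- new_msa(seqs)
  w3 <- compute_weights(msa3, 0.5)
  counts <- vapply(seq_along(seqs), function(i)
    sum(vapply(seq_along(seqs), function(j)
      naive_identity(seqs[[i]], seqs[[j]]) >= 0.5, logical(1))), numeric(1))
  expect_equal(unname(w3$weights), 1 / counts)
})

test_that("frequency tables obey their invariants and hand computation", {
  msa <- new_msa(c(a = "AC", b = "AA", c = "C-"))
  fr <- empirical_frequencies(msa, lambda = 0.5)
  expect_equal(rowSums(fr$fi), rep(1, 2))
  for (i in 1:2) for (j in 1:2)
    expect_equal(sum(fr$fij[i, j, , ]), 1)
  # f_ii(a,a) = f_i(a)
  for (i in 1:2)
    expect_equal(diag(fr$fij[i, i, , ]), fr$fi[i, ])
  # hand computation: position 1 has A,A,C -> counts (2/3, 1/3)
  expect_equal(fr$fi[1, 1], 0.5 / 21 + 0.5 * 2 / 3)
  expect_equal(fr$fi[1, 2], 0.5 / 21 + 0.5 * 1 / 3)
  # pair (1,2): (A,C),(A,A),(C,-) each weight 1/3
  expect_equal(fr$fij[1, 2, 1, 2], 0.5 / 21^2 + 0.5 * 1 / 3)
  expect_equal(fr$fij[1, 2, 2, 21], 0.5 / 21^2 + 0.5 * 1 / 3)

  # pseudocount-dominated limit
  fr2 <- empirical_frequencies(msa, lambda = 1 - 1e-12)
  expect_equal(max(abs(fr2$fi - 1 / 21)), 0, tolerance = 1e-9)
  # single sequence at lambda = 0 is an indicator
  fr3 <- empirical_frequencies(new_msa(c(x = "AC")), lambda = 0)
  expect_equal(fr3$fi[1, ], c(1, rep(0, 20)))
})

test_that("Hamiltonian matches direct sums and the naive double-loop oracle", {
  zero <- new_potts_model(matrix(0, 3, 21))
  expect_equal(hamiltonian(zero, c("ACD", "WY-")), c(0, 0))

  m <- tiny_potts()
  expect_equal(hamiltonian(m, "AA"), -3)
  expect_equal(hamiltonian(m, "AC"), -1)
  expect_error(hamiltonian(m, "AAA"), "length")

  set.seed(42)
  L <- 4; q <- 21
  h <- matrix(rnorm(L * q), L, q)
  e <- array(rnorm(L * L * q * q, sd = 0.2), dim = c(L, L, q, q))
  for (i in 1:L) e[i, i, , ] <- 0
  for (i in 1:(L - 1)) for (j in (i + 1):L) e[j, i, , ] <- t(e[i, j, , ])
  rnd <- new_potts_model(h, e)
  seqs <- random_gapped_seqs(5, 4, seed = 9)
  expect_equal(hamiltonian(rnd, seqs),
               vapply(seqs, naive_hamiltonian, numeric(1), model = rnd),
               ignore_attr = TRUE)
})

test_that("gauge shifts move all Hamiltonians by a constant, preserving ranking", {
  m <- make_planted_potts(L = 6, q = 21, planted_pairs = cbind(2, 5),
                          seed = 3)
  seqs <- random_gapped_seqs(20, 6, seed = 13)
  H0 <- hamiltonian(m, seqs)
  shifted <- m
  shifted$h[3, ] <- shifted$h[3, ] + 1.7
  H1 <- hamiltonian(shifted, seqs)
  expect_equal(H1, H0 - 1.7)
  expect_identical(order(H1), order(H0))
})

test_that("exact probabilities normalize and invert the Hamiltonian ordering", {
  m <- tiny_potts()
  states <- c("AA", "AC", "CA", "CC")
  P <- sequence_probability(m, states)
  expect_equal(sum(P), 1)
  Z <- exp(3) + exp(1) + exp(1) + exp(0)
  expect_equal(P[1], exp(3) / Z)
  expect_identical(order(P, decreasing = TRUE), order(hamiltonian(m, states)))

  zero <- new_potts_model(matrix(0, 3, 2), alphabet = "AC")
  expect_equal(sequence_probability(zero, c("AAA", "CAC")), rep(1 / 8, 2))

  big <- new_potts_model(matrix(0, 10, 21))
  expect_error(sequence_probability(big, paste(rep("A", 10), collapse = "")),
               "hamiltonian")
})

test_that("mean-field inference vanishes on independent sites and flags singularity", {
  # independent-site family: spurious couplings are pure sampling noise and
  # shrink toward zero as n grows (small lambda keeps the estimator
  # near-unbiased; the pseudocount itself perturbs the correlations)
  m <- make_planted_potts(L = 8, q = 4, field_sd = 0.5, seed = 6)
  max_e <- vapply(c(2000, 20000), function(n) {
    msa <- sample_potts(m, n, burn_in = 200, thin = 2, seed = 2)
    msa$weights <- rep(1, length(msa))
    fit <- infer_mfdca(empirical_frequencies(msa, lambda = 0.01))
    offdiag <- fit$e
    for (i in 1:8) offdiag[i, i, , ] <- 0
    max(abs(offdiag))
  }, numeric(1))
  expect_lt(max_e[2], 0.25)
  expect_lt(max_e[2], max_e[1])

  # duplicated column with zero pseudocount gives a singular system
  msa2 <- new_msa(c(a = "AA", b = "CC", c = "AA", d = "CC"), alphabet = "AC")
  expect_error(infer_mfdca(empirical_frequencies(msa2, lambda = 0)),
               "lambda")
})

test_that("direct information is zero without couplings, symmetric, and ranks planted pairs first", {
  zero <- new_potts_model(matrix(rnorm(5 * 21), 5, 21))
  msa <- sample_potts(zero, 100, burn_in = 50, thin = 1, seed = 1)
  fr <- empirical_frequencies(msa, lambda = 0.2)
  di0 <- direct_information(zero, fr)
  expect_equal(max(abs(di0)), 0, tolerance = 1e-10)

  pairs <- cbind(c(1, 4), c(7, 9))
  m <- make_planted_potts(L = 10, q = 8, planted_pairs = pairs,
                          coupling_strength = 2, seed = 4)
  msa2 <- sample_potts(m, 2000, burn_in = 300, thin = 3, seed = 8)
  msa2 <- compute_weights(msa2)
  fr2 <- empirical_frequencies(msa2, lambda = 0.5)
  fit <- infer_mfdca(fr2)
  di <- direct_information(fit, fr2)
  expect_identical(di, t(di))
  expect_true(all(di >= 0))
  top <- top_di_pairs(di, 2)
  expect_setequal(paste(top$i, top$j), paste(pairs[, 1], pairs[, 2]))
})
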