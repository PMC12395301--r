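test_that("grid construction covers the encodings with the requested pixel count", {
  enc <- cbind(c(0, 1, 0.5), c(0, 1, 0.2))
  g <- build_grid(enc, resolution = 2, margin = 0)
  expect_equal(nrow(g$coordinates), 4L)
  expect_setequal(apply(g$coordinates, 1, paste, collapse = ","),
                  c("0,0", "1,0", "0,1", "1,1"))

  g2 <- build_grid(enc, resolution = 11, margin = 0.1)
  expect_equal(nrow(g2$coordinates), 121L)
  expect_true(all(enc[, 1] > g2$z0_bounds[1] & enc[, 1] < g2$z0_bounds[2]))
  expect_true(all(enc[, 2] > g2$z1_bounds[1] & enc[, 2] < g2$z1_bounds[2]))

  expect_error(build_grid(cbind(c(1, 1), c(2, 2)), 10), "degenerate")
})

test_that("map scoring is decode-then-Hamiltonian and a pure function", {
  fam <- get_mixture_fixture()
  X <- encode_onehot(fam$msa)
  v <- get_mixture_vae()
  enc <- vae_encode(v, X)
  potts <- make_planted_potts(L = 30, q = 21,
                              planted_pairs = fam$planted_pairs, seed = 2)
  g <- build_grid(enc, resolution = 12, margin = 0.1)
  map <- score_map(v, potts, g)
  expect_equal(nrow(map$seq_idx), 144L)
  expect_true(all(is.finite(map$hamiltonians)))

  # compositionality: recompute a pixel subset by hand
  pick <- c(1L, 50L, 144L)
  redecoded <- vae_decode(v, g$coordinates[pick, ], as_indices = TRUE)
  expect_identical(map$seq_idx[pick, ], redecoded)
  expect_equal(map$hamiltonians[pick], hamiltonian(potts, redecoded))

  # purity: rerun gives the identical map
  map2 <- score_map(v, potts, g, chunk_size = 7)
  expect_identical(map$seq_idx, map2$seq_idx)
  expect_equal(map$hamiltonians, map2$hamiltonians)

  # zero Potts model scores every pixel 0
  zmap <- score_map(v, new_potts_model(matrix(0, 30, 21)), g)
  expect_equal(zmap$hamiltonians, rep(0, 144))

  wrong <- make_planted_potts(L = 10, q = 21, seed = 1)
  expect_error(score_map(v, wrong, g), "share L")
})

test_that("pixels near training encodings score better than far corners", {
  fam <- get_mixture_fixture()
  msa <- compute_weights(fam$msa)
  fr <- empirical_frequencies(msa, 0.5)
  potts <- infer_mfdca(fr)
  v <- get_sharp_vae()
  enc <- vae_encode(v, encode_onehot(msa))
  g <- build_grid(enc, resolution = 50, margin = 0.5)
  map <- score_map(v, potts, g)
  near <- unique(vapply(seq_len(min(100, nrow(enc))), function(i) {
    d2 <- (g$coordinates[, 1] - enc[i, 1])^2 +
          (g$coordinates[, 2] - enc[i, 2])^2
    which.min(d2)
  }, integer(1)))
  d_corner <- pmin(
    (g$coordinates[, 1] - g$z0_bounds[1])^2 + (g$coordinates[, 2] - g$z1_bounds[1])^2,
    (g$coordinates[, 1] - g$z0_bounds[2])^2 + (g$coordinates[, 2] - g$z1_bounds[2])^2,
    (g$coordinates[, 1] - g$z0_bounds[1])^2 + (g$coordinates[, 2] - g$z1_bounds[2])^2,
    (g$coordinates[, 1] - g$z0_bounds[2])^2 + (g$coordinates[, 2] - g$z1_bounds[1])^2)
  corner <- order(d_corner)[1:100]
  expect_lt(mean(map$hamiltonians[near]), mean(map$hamiltonians[corner]))
})

test_that("candidate decoding picks the nearest pixel deterministically", {
  enc <- cbind(c(0, 1), c(0, 1))
  g <- build_grid(enc, resolution = 3, margin = 0)
  v <- get_mixture_vae()
  potts <- make_planted_potts(L = 30, q = 21, seed = 2)
  map <- score_map(v, potts, g)

  # a coordinate exactly on a pixel returns that pixel
  on_pixel <- decode_candidates(map, g$coordinates[5, ])
  expect_equal(on_pixel$pixel, 5L)
  expect_equal(on_pixel$sequence, map_sequences(map, 5L))

  # midpoint between pixels 1 and 2 ties to the lower index
  mid <- (g$coordinates[1, ] + g$coordinates[2, ]) / 2
  expect_equal(decode_candidates(map, mid)$pixel, 1L)

  twice <- decode_candidates(map, rbind(c(0.2, 0.7), c(0.2, 0.7)))
  expect_identical(twice$sequence[1], twice$sequence[2])

  expect_error(decode_candidates(map, c(5, 5)), "outside the grid bounds")
})

test_that("novelty check reports exact maximum identity against the family", {
  msa <- new_msa(c(a = "ACDEF", b = "ACDKY", c = "WWWWW"))
  hit <- novelty_check("ACDEF", msa)
  expect_equal(hit$max_identity, 1)
  expect_equal(hit$nearest_id, "a")

  seqs <- random_gapped_seqs(20, 8, seed = 17, gap_prob = 0)
  names(seqs) <- paste0("n", 1:20)
  msa2 <- new_msa(seqs)
  cand <- "AAAAAAAA"
  res <- novelty_check(cand, msa2)
  oracle <- vapply(seqs, naive_identity, numeric(1), b = cand)
  expect_equal(res$max_identity, max(oracle))
  expect_equal(res$nearest_id, names(which.max(oracle)))

  expect_error(novelty_check("ACDEF", new_msa(character(0))), "empty")
})

test_that("motif search works on the gap-stripped sequence with ungapped positions", {
  hits <- motif_check("MA-DK--TGTLL", c(P = "DKTGT", A = "TGE"))
  expect_equal(hits$found, c(TRUE, FALSE))
  expect_equal(hits$position[1], 3L)   # ungapped: M A D K T G T ...
  expect_true(is.na(hits$position[2]))

  plain <- motif_check("AADKTGTAA", c(P = "DKTGT"))
  expect_equal(plain$position, 3L)
})

test_that("mutation reports tally substitutions and indels per domain", {
  ref <- "ACDEFGHIKLMNPQRSTVW-"
  # 3 substitutions (cols 2, 6, 12) and 1 insertion (col 20: gap in ref only)
  cand <- "AADEFAHIKLMAPQRSTVWY"
  rep1 <- mutation_report(cand, ref,
                          domains = list(P = c(1, 10), N = c(11, 15)))
  expect_equal(rep1$total_substitutions, 3)
  expect_equal(rep1$total_indels, 1)
  tab <- rep1$by_domain
  expect_equal(tab$substitutions[tab$domain == "P"], 2)
  expect_equal(tab$substitutions[tab$domain == "N"], 1)
  expect_equal(tab$indels[tab$domain == "other"], 1)

  # identical sequences: all zero
  rep0 <- mutation_report(ref, ref, domains = list(P = c(1, 10)))
  expect_equal(rep0$total_substitutions, 0)
  expect_equal(rep0$total_indels, 0)

  # symmetry of the substitution count
  rep_ba <- mutation_report(ref, cand, domains = list(P = c(1, 10)))
  expect_equal(rep_ba$total_substitutions, rep1$total_substitutions)

  expect_error(mutation_report(cand, ref,
                               domains = list(a = c(1, 5), b = c(5, 9))),
               "overlap")
  expect_error(mutation_report("AC", "ACD"), "equal aligned length")
})
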