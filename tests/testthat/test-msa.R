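test_that("FASTA parsing returns validated alignments and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc", "ACDEFGHIK-", ">b", "ACDEFGH--K",
               ">c", "ACWEFGHIKL"), path)
  msa <- read_msa(path, "fasta")
  expect_s3_class(msa, "msa")
  expect_equal(length(msa), 3L)
  expect_equal(msa$L, 10L)
  expect_equal(names(msa$seqs), c("a", "b", "c"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "ACDE"), bad)
  expect_error(read_msa(bad, "fasta"), "unequal aligned lengths.*b")

  bad2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "AXD"), bad2)
  expect_error(read_msa(bad2, "fasta"), "unknown symbol 'X'.*'b'.*column 2")
})

test_that("A2M insert states are dropped, leaving match columns only", {
  # hand-built 5-match-column toy: lowercase and '.' are inserts
  path <- withr::local_tempfile(fileext = ".a2m")
  writeLines(c(">s1", "ACstDEF", ">s2", "AC..DE-", ">s3", "GCaaDEF"), path)
  msa <- read_msa(path, "a2m")
  expect_equal(msa$L, 5L)
  expect_equal(unname(msa$seqs),
               c("ACDEF", "ACDE-", "GCDEF"))
})

test_that("Stockholm alignments are read", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACD-E", "s2 ACDKE", "//"), path)
  msa <- read_msa(path, "stockholm")
  expect_equal(msa$L, 5L)
  expect_equal(unname(msa$seqs[1]), "ACD-E")
})

test_that("length filter keeps ungapped lengths within bounds, preserving order", {
  seqs <- c(a = paste(rep("A", 500), collapse = ""),
            b = paste(rep("A", 600), collapse = ""),
            c = paste(rep("A", 700), collapse = ""))
  # pad to equal aligned width with gaps
  width <- 700
  seqs <- vapply(seqs, function(s)
    paste0(s, paste(rep("-", width - nchar(s)), collapse = "")), character(1))
  msa <- new_msa(seqs)
  kept <- length_filter(msa, 574, 661)
  expect_equal(length(kept), 1L)
  expect_equal(names(kept$seqs), "b")
  expect_equal(length(length_filter(msa, 0, 1e9)), 3L)
  expect_equal(length(length_filter(msa, 701, 800)), 0L)
})

test_that("gap-run filter removes records with runs above the limit and is idempotent", {
  run26 <- paste0("A", paste(rep("-", 26), collapse = ""), "A")
  two_runs25 <- paste0("A", paste(rep("-", 25), collapse = ""), "A",
                       paste(rep("-", 25), collapse = ""))
  pad <- function(s, w) paste0(s, paste(rep("A", w - nchar(s)), collapse = ""))
  w <- 60
  msa <- new_msa(c(x = pad(run26, w), y = pad(two_runs25, w), z = pad("AA", w)))
  out <- gap_run_filter(msa, 25)
  expect_equal(names(out$seqs), c("y", "z"))
  expect_equal(gap_run_filter(out, 25)$seqs, out$seqs)

  gapless <- gap_run_filter(msa, 0)
  expect_equal(names(gapless$seqs), "z")
})

test_that("identity subsampling satisfies the all-pairs threshold oracle", {
  msa <- new_msa(c(a = "ACDEACDE", b = "ACDEACDE"))
  expect_equal(length(identity_subsample(msa, 0.87)), 1L)

  seqs <- random_gapped_seqs(10, 8, seed = 21)
  names(seqs) <- letters[1:10]
  msa <- new_msa(seqs)
  out <- identity_subsample(msa, 0.87)
  ids <- utils::combn(length(out), 2)
  if (ncol(ids) > 0) {
    pairwise <- apply(ids, 2, function(p)
      naive_identity(out$seqs[[p[1]]], out$seqs[[p[2]]]))
    expect_true(all(pairwise < 0.87))
  }
  # a dropped record must collide with some kept one (greedy maximality)
  dropped <- setdiff(names(msa$seqs), names(out$seqs))
  for (d in dropped) {
    hits <- vapply(out$seqs, naive_identity, numeric(1), b = msa$seqs[[d]])
    expect_true(any(hits >= 0.87))
  }
  # threshold 1.0 with no exact duplicates is the identity operation
  expect_equal(identity_subsample(msa, 1.0)$seqs, msa$seqs)
})

test_that("identity subsampling under a seed still satisfies the threshold", {
  seqs <- random_gapped_seqs(50, 12, seed = 33, gap_prob = 0.05)
  msa <- new_msa(seqs)
  for (seed in c(1, 2)) {
    out <- identity_subsample(msa, 0.6, seed = seed)
    pairs <- utils::combn(length(out), 2)
    pairwise <- apply(pairs, 2, function(p)
      naive_identity(out$seqs[[p[1]]], out$seqs[[p[2]]]))
    expect_true(all(pairwise < 0.6))
  }
  expect_identical(identity_subsample(msa, 0.6, seed = 4)$seqs,
                   identity_subsample(msa, 0.6, seed = 4)$seqs)
})

test_that("one-hot encoding has row sums L, a gap channel, and exact round-trip", {
  msa <- new_msa(c(r1 = "AA-", r2 = "C-Y"))
  X <- encode_onehot(msa)
  expect_equal(dim(X), c(2L, 3L * 21L))
  expect_equal(unname(rowSums(X)), c(3, 3))
  # gap at column 3 of r1 occupies the last channel of block 3
  expect_equal(unname(X[1, 3 * 21]), 1)
  expect_equal(decode_onehot(X), unname(msa$seqs))
  # round-trip across every alphabet symbol
  full <- paste(strsplit(protein_alphabet(), "")[[1]], collapse = "")
  msa2 <- new_msa(c(all = full))
  expect_equal(decode_onehot(encode_onehot(msa2)), full)
})
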