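# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, all-pairs scans) so they stay independent of the package's
# vectorized/compiled implementations.

toy_msa <- function(seqs, ...) new_msa(seqs, ...)

# independent Hamiltonian: plain double loop over positions and pairs
naive_hamiltonian <- function(model, seq) {
  letters_ok <- strsplit(model$alphabet, "")[[1]]
  s <- match(strsplit(seq, "")[[1]], letters_ok)
  H <- 0
  for (i in seq_len(model$L)) {
    H <- H - model$h[i, s[i]]
    if (i < model$L) for (j in (i + 1):model$L)
      H <- H - model$e[i, j, s[i], s[j]]
  }
  H
}

# independent pairwise identity: matches at mutually non-gap columns over
# the shorter ungapped length
naive_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  both <- ca != "-" & cb != "-"
  denom <- min(sum(ca != "-"), sum(cb != "-"))
  if (denom == 0) return(0)
  sum(ca == cb & both) / denom
}

# tiny L=2, q=2 model over alphabet "AC": h1(A)=1, h2(A)=1, e12(A,A)=1
tiny_potts <- function() {
  h <- matrix(c(1, 0, 1, 0), nrow = 2, byrow = TRUE)
  e <- array(0, dim = c(2, 2, 2, 2))
  e[1, 2, 1, 1] <- 1; e[2, 1, 1, 1] <- 1
  new_potts_model(h, e, alphabet = "AC")
}

# deterministic random aligned sequences over the full protein alphabet
random_gapped_seqs <- function(n, L, seed, gap_prob = 0.15) {
  set.seed(seed)
  letters_ok <- strsplit(protein_alphabet(), "")[[1]]
  probs <- c(rep((1 - gap_prob) / 20, 20), gap_prob)
  vapply(seq_len(n), function(i)
    paste(sample(letters_ok, L, replace = TRUE, prob = probs),
          collapse = ""), character(1))
}

# cached two-subgroup family fixture shared by VAE and acceptance tests
.fixture_cache <- new.env(parent = emptyenv())
get_mixture_fixture <- function() {
  if (is.null(.fixture_cache$mixture)) {
    .fixture_cache$mixture <- make_family_mixture(
      L = 30, q = 21, n = 500, k = 2, separation = 2,
      burn_in = 300, thin = 3, seed = 11)
  }
  .fixture_cache$mixture
}

# a better-converged decoder (higher learning rate) for landscape-geometry
# checks, where decoder sharpness matters more than the training contract
get_sharp_vae <- function() {
  if (is.null(.fixture_cache$vae_sharp)) {
    fam <- get_mixture_fixture()
    X <- encode_onehot(fam$msa)
    .fixture_cache$vae_sharp <- vae_train(X, q = 21, seed = 5, lr = 1e-3,
                                          max_epochs = 300)
  }
  .fixture_cache$vae_sharp
}

get_mixture_vae <- function() {
  if (is.null(.fixture_cache$vae)) {
    fam <- get_mixture_fixture()
    X <- encode_onehot(fam$msa)
    .fixture_cache$vae <- vae_train(X, q = 21, seed = 5, max_epochs = 300)
  }
  .fixture_cache$vae
}

# cluster purity of a 2-group labelling against binary truth
cluster_purity <- function(cluster, truth) {
  max(mean((cluster == 1) == (truth == 1)),
      mean((cluster == 2) == (truth == 1)))
}

rotation_matrix <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2)); th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
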