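#' Construct a Potts model
#'
#' Pairwise Markov random field over aligned sequences: local fields
#' \code{h[i, a]} and couplings \code{e[i, j, a, b]} for positions
#' \code{i < j} (stored as a full symmetric array,
#' \code{e[i,j,a,b] == e[j,i,b,a]}, zero diagonal blocks).
#'
#' @param h \code{L x q} numeric matrix of fields.
#' @param e \code{L x L x q x q} numeric array of couplings, or \code{NULL}
#'   for an all-zero coupling set.
#' @param alphabet Alphabet string of length \code{q}.
#' @param meta Optional list of metadata (lambda, Meff, ...).
#' @return Object of class \code{"potts_model"}.
#' @export
new_potts_model <- function(h, e = NULL, alphabet = protein_alphabet(),
                            meta = list()) {
  L <- nrow(h); q <- ncol(h)
  stopifnot(q == nchar(alphabet))
  if (is.null(e)) e <- array(0, dim = c(L, L, q, q))
  stopifnot(identical(dim(e), c(L, L, q, q)))
  stopifnot(all(is.finite(h)), all(is.finite(e)))
  structure(list(L = L, q = q, h = h, e = e, alphabet = alphabet, meta = meta),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat("Potts model: L =", x$L, ", q =", x$q, "\n")
  if (!is.null(x$meta$Meff)) cat("Meff =", format(x$meta$Meff), "\n")
  invisible(x)
}

# symmetrize an upper-triangle coupling array in place
symmetrize_couplings <- function(e) {
  L <- dim(e)[1]
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    e[j, i, , ] <- t(e[i, j, , ])
  }
  e
}

#' Sequence reweighting for DCA
#'
#' Assigns each record the weight \code{1 / m}, where \code{m} is the number
#' of records (itself included) with pairwise identity at or above
#' \code{sim_threshold}. The sum of weights is the effective sequence count
#' Meff. The identity definition is that of [pairwise_identity()].
#'
#' @param msa An \code{msa} object.
#' @param sim_threshold Similarity threshold, default 0.8.
#' @return The \code{msa} with \code{weights} filled in; \code{sum(weights)}
#'   is Meff.
#' @export
compute_weights <- function(msa, sim_threshold = 0.8) {
  stopifnot(length(msa$seqs) > 0)
  idx <- msa_index_matrix(msa)
  gap_idx <- match(GAP, strsplit(msa$alphabet, "")[[1]])
  if (is.na(gap_idx)) gap_idx <- 0L  # gapless alphabet: no symbol is a gap
  cnt <- identity_neighbors_cpp(idx, gap_idx, sim_threshold)
  msa$weights <- 1 / cnt
  msa
}

#' Weighted single- and two-site frequencies with pseudocount
#'
#' \code{f_i(a) = lambda/q + (1-lambda) * c_i(a)/Meff} and analogously
#' \code{f_ij(a,b)} with pseudocount \code{lambda/q^2}, where \code{c} are
#' weighted counts. Diagonal pair tables satisfy
#' \code{f_ii(a,a) = f_i(a)}.
#'
#' @param msa An \code{msa} object, weighted or not (unweighted records count
#'   as 1 each).
#' @param lambda Pseudocount fraction in \code{[0, 1)}; the mean-field DCA
#'   default is 0.5.
#' @return List of class \code{"freq_tables"}: \code{fi} (\code{L x q}),
#'   \code{fij} (\code{L x L x q x q}), \code{Meff}, \code{lambda}.
#' @export
empirical_frequencies <- function(msa, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda < 1)
  idx <- msa_index_matrix(msa)
  n <- nrow(idx); L <- ncol(idx); q <- msa$q
  w <- if (is.null(msa$weights)) rep(1, n) else msa$weights
  Meff <- sum(w)
  fi <- matrix(0, L, q)
  for (i in seq_len(L)) {
    tab <- vapply(seq_len(q), function(a) sum(w[idx[, i] == a]), numeric(1))
    fi[i, ] <- lambda / q + (1 - lambda) * tab / Meff
  }
  fij <- array(0, dim = c(L, L, q, q))
  # one-hot trick: weighted cross-products give all pair counts at once
  X <- matrix(0, n, L * q)
  cols <- sweep(idx, 2, (seq_len(L) - 1L) * q, "+")
  X[cbind(rep(seq_len(n), L), as.vector(cols))] <- 1
  XtWX <- crossprod(X * w, X) / Meff   # (L*q) x (L*q) weighted pair freqs
  for (i in seq_len(L)) for (j in seq_len(L)) {
    blk <- XtWX[((i - 1) * q + 1):(i * q), ((j - 1) * q + 1):(j * q)]
    if (i == j) {
      diag_vals <- lambda / q + (1 - lambda) * diag(blk)
      for (a in seq_len(q)) fij[i, i, a, a] <- diag_vals[a]
    } else {
      fij[i, j, , ] <- lambda / q^2 + (1 - lambda) * blk
    }
  }
  structure(list(fi = fi, fij = fij, Meff = Meff, lambda = lambda,
                 L = L, q = q, alphabet = msa$alphabet),
            class = "freq_tables")
}

#' Mean-field DCA inference
#'
#' Estimates couplings as the negative inverse of the connected-correlation
#' matrix in the reduced (q-1) alphabet, with the gap (last) symbol as the
#' reference state, then sets fields self-consistently from the single-site
#' frequencies:
#' \code{h_i(a) = log(f_i(a)/f_i(q)) - sum_j sum_b e_ij(a,b) f_j(b)}.
#'
#' @param freqs A \code{"freq_tables"} object from [empirical_frequencies()].
#' @return A \code{"potts_model"}.
#' @export
infer_mfdca <- function(freqs) {
  L <- freqs$L; q <- freqs$q; r <- q - 1L
  # connected correlations on the reduced alphabet
  C <- matrix(0, L * r, L * r)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    blk <- freqs$fij[i, j, 1:r, 1:r] -
      tcrossprod(freqs$fi[i, 1:r], freqs$fi[j, 1:r])
    C[((i - 1) * r + 1):(i * r), ((j - 1) * r + 1):(j * r)] <- blk
  }
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("connected-correlation matrix is singular; increase the pseudocount lambda",
         call. = FALSE))
  e <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    e[i, j, 1:r, 1:r] <- -Cinv[((i - 1) * r + 1):(i * r),
                               ((j - 1) * r + 1):(j * r)]
  }
  # enforce exact pair symmetry (numerical inversion leaves tiny asymmetry)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    sym <- (e[i, j, , ] + t(e[j, i, , ])) / 2
    e[i, j, , ] <- sym
    e[j, i, , ] <- t(sym)
  }
  h <- matrix(0, L, q)
  for (i in seq_len(L)) {
    h[i, ] <- log(freqs$fi[i, ] / freqs$fi[i, q])
    for (j in seq_len(L)) {
      if (j == i) next
      h[i, ] <- h[i, ] - e[i, j, , ] %*% freqs$fi[j, ]
    }
  }
  new_potts_model(h, e, alphabet = freqs$alphabet,
                  meta = list(lambda = freqs$lambda, Meff = freqs$Meff))
}

seq_to_idx <- function(seq, alphabet) {
  letters_ok <- strsplit(alphabet, "")[[1]]
  idx <- match(strsplit(toupper(seq), "")[[1]], letters_ok)
  if (anyNA(idx)) stop("sequence contains symbols outside the model alphabet",
                       call. = FALSE)
  idx
}

#' Potts Hamiltonian of sequences
#'
#' \code{H(S) = -sum_i h_i(s_i) - sum_{i<j} e_ij(s_i, s_j)}. More negative
#' values predict higher family fitness. Gap symbols carry no special
#' treatment; they contribute through their learned parameters like any
#' other symbol.
#'
#' @param model A \code{"potts_model"}.
#' @param seqs Character vector of aligned sequences of length \code{model$L},
#'   or an integer index matrix (\code{n x L}, 1-based alphabet indices).
#' @return Numeric vector of Hamiltonian values.
#' @export
hamiltonian <- function(model, seqs) {
  if (is.matrix(seqs)) {
    idx <- seqs
  } else {
    if (any(nchar(seqs) != model$L))
      stop("sequence length must equal model L = ", model$L, call. = FALSE)
    idx <- t(vapply(seqs, seq_to_idx, integer(model$L),
                    alphabet = model$alphabet))
  }
  stopifnot(ncol(idx) == model$L)
  storage.mode(idx) <- "integer"
  hamiltonian_batch_cpp(idx, model$h, model$e)
}

all_states <- function(L, q) {
  as.matrix(rev(expand.grid(rev(lapply(seq_len(L), function(i) seq_len(q))))))
}

#' Exact sequence probability under a Potts model
#'
#' Computes \code{P(S) = exp(-H(S)) / Z} with the partition function by full
#' enumeration of all \code{q^L} states. Guarded to enumerable models
#' (\code{q^L <= 1e6}); for larger models use [hamiltonian()] for relative
#' scoring.
#'
#' @param model A \code{"potts_model"}.
#' @param seqs Sequences as in [hamiltonian()].
#' @return Numeric vector of probabilities.
#' @export
sequence_probability <- function(model, seqs) {
  if (model$q^model$L > 1e6)
    stop("state space q^L exceeds 1e6; use hamiltonian() for relative scores",
         call. = FALSE)
  states <- all_states(model$L, model$q)
  storage.mode(states) <- "integer"
  logw <- -hamiltonian_batch_cpp(states, model$h, model$e)
  mx <- max(logw)
  Z <- sum(exp(logw - mx))
  Hs <- hamiltonian(model, seqs)
  exp(-Hs - mx) / Z
}

#' Exact marginals of an enumerable Potts model
#'
#' Single- and two-site marginals by full enumeration; used as an oracle for
#' mean-field inference on small models.
#'
#' @param model A \code{"potts_model"} with \code{q^L <= 1e6}.
#' @return List with \code{fi} (\code{L x q}) and \code{fij}
#'   (\code{L x L x q x q}).
#' @export
enumerate_marginals <- function(model) {
  L <- model$L; q <- model$q
  states <- all_states(L, q)
  storage.mode(states) <- "integer"
  logw <- -hamiltonian_batch_cpp(states, model$h, model$e)
  p <- exp(logw - max(logw)); p <- p / sum(p)
  fi <- matrix(0, L, q)
  fij <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) {
    for (a in seq_len(q)) fi[i, a] <- sum(p[states[, i] == a])
    for (j in seq_len(L)) for (a in seq_len(q)) for (b in seq_len(q))
      fij[i, j, a, b] <- sum(p[states[, i] == a & states[, j] == b])
  }
  list(fi = fi, fij = fij)
}

#' Direct Information matrix
#'
#' For each position pair, builds the coupling-induced two-site distribution
#' \code{P_ij(a,b) = W_ij(a,b) mu_i(a) mu_j(b) / Z} with
#' \code{W_ij = exp(e_ij)}, where the auxiliary fields \code{mu} are fitted
#' iteratively so the marginals of \code{P_ij} match the empirical
#' single-site frequencies. DI is the mutual information of that
#' distribution: nonnegative, symmetric, zero diagonal.
#'
#' @param model A \code{"potts_model"}.
#' @param freqs Matching \code{"freq_tables"}.
#' @param tol Convergence tolerance of the marginal fit (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return \code{L x L} numeric DI matrix.
#' @export
direct_information <- function(model, freqs, tol = 1e-6, max_iter = 500L) {
  stopifnot(model$L == freqs$L, model$q == freqs$q)
  L <- model$L; q <- model$q
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    W <- exp(model$e[i, j, , ])
    mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
    fi <- freqs$fi[i, ]; fj <- freqs$fi[j, ]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      s1 <- as.vector(W %*% mu2)
      s2 <- as.vector(crossprod(W, mu1))
      new1 <- fi / s1; new1 <- new1 / sum(new1)
      new2 <- fj / s2; new2 <- new2 / sum(new2)
      delta <- max(abs(new1 - mu1), abs(new2 - mu2))
      mu1 <- new1; mu2 <- new2
      if (delta < tol) { ok <- TRUE; break }
    }
    if (!ok) stop("two-site marginal fitting did not converge for pair (",
                  i, ", ", j, ")", call. = FALSE)
    P <- W * tcrossprod(mu1, mu2)
    P <- P / sum(P)
    Pi <- rowSums(P); Pj <- colSums(P)
    ratio <- P / tcrossprod(Pi, Pj)
    val <- sum(P[P > 0] * log(ratio[P > 0]))
    di[i, j] <- di[j, i] <- max(val, 0)
  }
  di
}

#' Top coupled pairs by DI
#'
#' @param di DI matrix.
#' @param k Number of pairs.
#' @return Data frame with columns \code{i}, \code{j} (\code{i < j}),
#'   \code{di}, strongest first.
#' @export
top_di_pairs <- function(di, k) {
  L <- nrow(di)
  ut <- which(upper.tri(di), arr.ind = TRUE)
  ord <- order(di[ut], decreasing = TRUE)
  sel <- ut[ord[seq_len(min(k, nrow(ut)))], , drop = FALSE]
  data.frame(i = sel[, 1], j = sel[, 2], di = di[sel])
}

#' Write a DI matrix to TSV
#' @param di DI matrix.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_di_tsv <- function(di, path) {
  utils::write.table(di, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
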