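## Variational autoencoder over one-hot encoded alignments.
##
## Architecture: one ReLU hidden layer of 3*L units in the encoder and in the
## decoder, a 2-D Gaussian latent with a standard-normal prior, and a
## per-position categorical likelihood over the alphabet. Optimized with Adam
## (lr 1e-4) plus an L2 penalty (1e-4) on the weight matrices, stopping when
## the epoch loss has not improved for `patience` consecutive epochs.
## Implemented directly in base R matrix algebra; model sizes here (hundreds
## of sequences, L of a few hundred) do not need GPU machinery.

vae_init_params <- function(D, H, latent) {
  # He-style scaling for the ReLU layers, smaller for the heads
  init <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  list(
    We1 = init(D, H, sqrt(2 / D)),  be1 = rep(0, H),
    Wmu = init(H, latent, 0.01),    bmu = rep(0, latent),
    Wlv = init(H, latent, 0.01),    blv = rep(0, latent),
    Wd1 = init(latent, H, 0.5),     bd1 = rep(0, H),
    Wd2 = init(H, D, sqrt(2 / H)),  bd2 = rep(0, D)
  )
}

# blockwise softmax over L blocks of q columns (position-major layout);
# returns list(P = probabilities, ll = per-row reconstruction log-likelihood)
softmax_blocks <- function(G, X, L, q) {
  B <- nrow(G)
  GA <- array(G, dim = c(B, q, L))
  mx <- matrix(GA[, 1, ], B, L)
  for (a in seq_len(q)[-1]) mx <- pmax(mx, matrix(GA[, a, ], B, L))
  S <- matrix(0, B, L)
  EX <- array(0, dim = c(B, q, L))
  for (a in seq_len(q)) {
    EX[, a, ] <- exp(matrix(GA[, a, ], B, L) - mx)
    S <- S + matrix(EX[, a, ], B, L)
  }
  for (a in seq_len(q)) EX[, a, ] <- matrix(EX[, a, ], B, L) / S
  P <- matrix(EX, B, L * q)
  ll <- rowSums(G * X) - rowSums(mx + log(S))
  list(P = P, ll = ll)
}

vae_forward <- function(params, X, L, q, eps = NULL) {
  A1 <- sweep(X %*% params$We1, 2, params$be1, "+")
  H1 <- pmax(A1, 0)
  mu <- sweep(H1 %*% params$Wmu, 2, params$bmu, "+")
  lv <- sweep(H1 %*% params$Wlv, 2, params$blv, "+")
  if (is.null(eps)) eps <- matrix(0, nrow(X), ncol(mu))
  z <- mu + exp(lv / 2) * eps
  A2 <- sweep(z %*% params$Wd1, 2, params$bd1, "+")
  H2 <- pmax(A2, 0)
  G <- sweep(H2 %*% params$Wd2, 2, params$bd2, "+")
  sm <- softmax_blocks(G, X, L, q)
  kl <- 0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)
  list(A1 = A1, H1 = H1, mu = mu, lv = lv, eps = eps, z = z,
       A2 = A2, H2 = H2, G = G, P = sm$P, recon_ll = sm$ll, kl = kl)
}

vae_backward <- function(params, X, fw, l2) {
  B <- nrow(X)
  dG <- (fw$P - X) / B
  dWd2 <- crossprod(fw$H2, dG) + l2 * params$Wd2
  dbd2 <- colSums(dG)
  dH2 <- tcrossprod(dG, params$Wd2)
  dA2 <- dH2 * (fw$A2 > 0)
  dWd1 <- crossprod(fw$z, dA2) + l2 * params$Wd1
  dbd1 <- colSums(dA2)
  dz <- tcrossprod(dA2, params$Wd1)
  dmu <- dz + fw$mu / B
  dlv <- dz * fw$eps * 0.5 * exp(fw$lv / 2) + 0.5 * (exp(fw$lv) - 1) / B
  dWmu <- crossprod(fw$H1, dmu) + l2 * params$Wmu
  dbmu <- colSums(dmu)
  dWlv <- crossprod(fw$H1, dlv) + l2 * params$Wlv
  dblv <- colSums(dlv)
  dH1 <- tcrossprod(dmu, params$Wmu) + tcrossprod(dlv, params$Wlv)
  dA1 <- dH1 * (fw$A1 > 0)
  dWe1 <- crossprod(X, dA1) + l2 * params$We1
  dbe1 <- colSums(dA1)
  list(We1 = dWe1, be1 = dbe1, Wmu = dWmu, bmu = dbmu, Wlv = dWlv,
       blv = dblv, Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2)
}

#' Evidence lower bound of a batch
#'
#' Returns the mean per-sequence ELBO: the categorical reconstruction
#' log-likelihood minus the closed-form KL divergence between the Gaussian
#' posterior and the standard-normal prior. The reconstruction expectation is
#' evaluated at the posterior mean unless noise \code{eps} is supplied, so
#' repeated calls are deterministic.
#'
#' @param model A trained \code{"vae_model"}.
#' @param batch One-hot matrix with \code{L*q} columns.
#' @param eps Optional latent noise matrix (\code{nrow(batch) x 2}).
#' @return List with \code{elbo}, \code{recon} and \code{kl} (means over the
#'   batch); \code{elbo = recon - kl}.
#' @export
vae_elbo <- function(model, batch, eps = NULL) {
  stopifnot(inherits(model, "vae_model"))
  if (ncol(batch) != model$L * model$q)
    stop("batch has ", ncol(batch), " columns; expected L*q = ",
         model$L * model$q, call. = FALSE)
  fw <- vae_forward(model$params, batch, model$L, model$q, eps = eps)
  list(elbo = mean(fw$recon_ll) - mean(fw$kl),
       recon = mean(fw$recon_ll), kl = mean(fw$kl))
}

#' Train the sequence VAE
#'
#' Minimizes the negative ELBO with Adam. The per-epoch loss recorded in
#' \code{training_log} is the mean minibatch loss of that epoch; training
#' stops once the loss has failed to improve on its running best for
#' \code{patience} consecutive epochs (or at \code{max_epochs}). Fully
#' deterministic given \code{seed}.
#'
#' @param X One-hot matrix (\code{n x L*q}) from [encode_onehot()].
#' @param q Alphabet size (default 21).
#' @param alphabet Alphabet string used when decoding.
#' @param hidden Hidden width; default \code{3 * L}.
#' @param latent Latent dimension (default 2).
#' @param lr Adam learning rate (default 1e-4).
#' @param l2 L2 penalty on weight matrices (default 1e-4).
#' @param patience Consecutive non-improving epochs tolerated (default 10).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Hard cap on epochs (default 1000).
#' @param seed Integer seed controlling initialization, shuffling and latent
#'   noise.
#' @return Object of class \code{"vae_model"}: fields \code{L}, \code{q},
#'   \code{alphabet}, \code{hidden}, \code{latent}, \code{params},
#'   \code{training_log} (one loss per epoch), \code{epochs}.
#' @export
vae_train <- function(X, q = 21L, alphabet = protein_alphabet(),
                      hidden = NULL, latent = 2L, lr = 1e-4, l2 = 1e-4,
                      patience = 10L, batch_size = 64L, max_epochs = 1000L,
                      seed = 1L) {
  stopifnot(nrow(X) > 0, ncol(X) %% q == 0)
  L <- ncol(X) %/% q
  if (is.null(hidden)) hidden <- 3L * L
  set.seed(as.integer(seed))
  params <- vae_init_params(ncol(X), hidden, latent)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0L
  n <- nrow(X)
  best <- Inf; stale <- 0L
  training_log <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    losses <- numeric(length(starts))
    for (b in seq_along(starts)) {
      rows <- ord[starts[b]:min(starts[b] + batch_size - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(rows) * latent), length(rows), latent)
      fw <- vae_forward(params, Xb, L, q, eps = eps)
      loss <- -(mean(fw$recon_ll) - mean(fw$kl))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      losses[b] <- loss
      gr <- vae_backward(params, Xb, fw, l2)
      step <- step + 1L
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gr[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gr[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    epoch_loss <- mean(losses)
    training_log <- c(training_log, epoch_loss)
    if (epoch_loss < best) {
      best <- epoch_loss; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  structure(list(L = L, q = q, alphabet = alphabet, hidden = hidden,
                 latent = latent, params = params,
                 training_log = training_log,
                 epochs = length(training_log), trained = TRUE),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cat("VAE: L =", x$L, ", q =", x$q, ", hidden =", x$hidden,
      ", latent =", x$latent, "\n")
  cat("trained for", x$epochs, "epochs; final loss",
      format(utils::tail(x$training_log, 1)), "\n")
  invisible(x)
}

#' Encode sequences to latent coordinates
#'
#' Maps one-hot rows to the posterior mean of the latent Gaussian: one fixed
#' point per sequence, no sampling, so repeated calls are identical.
#'
#' @param model A trained \code{"vae_model"}.
#' @param X One-hot matrix (or a single one-hot vector).
#' @return \code{n x latent} matrix of coordinates.
#' @export
vae_encode <- function(model, X) {
  if (!inherits(model, "vae_model") || !isTRUE(model$trained))
    stop("model is not a trained vae_model", call. = FALSE)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  A1 <- sweep(X %*% model$params$We1, 2, model$params$be1, "+")
  H1 <- pmax(A1, 0)
  sweep(H1 %*% model$params$Wmu, 2, model$params$bmu, "+")
}

#' Decode latent coordinates to sequences
#'
#' Runs the decoder and takes the per-position argmax of the categorical
#' output, ties broken toward the lowest alphabet index, yielding one
#' deterministic aligned sequence of length \code{L} per coordinate.
#'
#' @param model A trained \code{"vae_model"}.
#' @param z Latent coordinates: numeric vector of length \code{latent} or an
#'   \code{n x latent} matrix.
#' @param as_indices If \code{TRUE}, return the \code{n x L} integer index
#'   matrix instead of character sequences.
#' @return Character vector of sequences (or index matrix).
#' @export
vae_decode <- function(model, z, as_indices = FALSE) {
  if (!inherits(model, "vae_model") || !isTRUE(model$trained))
    stop("model is not a trained vae_model", call. = FALSE)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  p <- model$params
  A2 <- sweep(z %*% p$Wd1, 2, p$bd1, "+")
  H2 <- pmax(A2, 0)
  G <- sweep(H2 %*% p$Wd2, 2, p$bd2, "+")
  L <- model$L; q <- model$q
  idx <- matrix(0L, nrow(G), L)
  for (i in seq_len(L)) {
    block <- G[, ((i - 1L) * q + 1L):(i * q), drop = FALSE]
    idx[, i] <- max.col(block, ties.method = "first")
  }
  if (as_indices) return(idx)
  letters_ok <- strsplit(model$alphabet, "")[[1]]
  apply(idx, 1L, function(r) paste(letters_ok[r], collapse = ""))
}
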