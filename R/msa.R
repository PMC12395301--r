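#' @useDynLib seqlandscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Protein alphabet used throughout the package
#'
#' Twenty amino acids in fixed order followed by the gap symbol. One-hot
#' encoding, Potts model parameters and decoded sequences all use this
#' ordering, so encodings are reproducible across sessions.
#'
#' @return Single string, \code{"ACDEFGHIKLMNPQRSTVWY-"}.
#' @export
protein_alphabet <- function() "ACDEFGHIKLMNPQRSTVWY-"

GAP <- "-"

#' Construct a multiple sequence alignment object
#'
#' Light container for an aligned protein family: named aligned sequences
#' over a fixed alphabet, with optional per-record weights attached later by
#' [compute_weights()].
#'
#' @param seqs Named character vector of aligned sequences (equal width).
#' @param alphabet Alphabet string; defaults to [protein_alphabet()].
#' @param weights Optional numeric vector of per-record weights in (0, 1].
#' @return An object of class \code{"msa"} with fields \code{seqs},
#'   \code{L} (aligned length), \code{q} (alphabet size), \code{alphabet},
#'   \code{weights}.
#' @export
new_msa <- function(seqs, alphabet = protein_alphabet(), weights = NULL) {
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- nm
  if (length(seqs) == 0L) {
    obj <- list(seqs = character(0), L = 0L, q = nchar(alphabet),
                alphabet = alphabet, weights = NULL)
    class(obj) <- "msa"
    return(obj)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- names(seqs)[widths != widths[1L]][1L]
    stop("unequal aligned lengths: record '", bad, "' has width ",
         nchar(seqs[[bad]]), ", expected ", widths[1L], call. = FALSE)
  }
  letters_ok <- strsplit(alphabet, "")[[1]]
  mat <- do.call(rbind, strsplit(seqs, ""))
  bad <- which(!(mat %in% letters_ok))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop("unknown symbol '", mat[bad[1L]], "' in record '", names(seqs)[i],
         "' at column ", j, call. = FALSE)
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(seqs), all(weights > 0), all(weights <= 1))
  }
  obj <- list(seqs = seqs, L = widths[[1L]], q = nchar(alphabet),
              alphabet = alphabet, weights = weights)
  class(obj) <- "msa"
  obj
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA: ", length(x$seqs), " sequences, aligned length ", x$L,
      ", alphabet size ", x$q, "\n", sep = "")
  if (!is.null(x$weights)) cat("Meff = ", format(sum(x$weights)), "\n", sep = "")
  invisible(x)
}

#' @export
length.msa <- function(x) length(x$seqs)

#' Number of non-gap residues per record
#' @param msa An [new_msa()] object.
#' @return Integer vector, one entry per record.
#' @export
ungapped_lengths <- function(msa) {
  nchar(gsub(GAP, "", msa$seqs, fixed = TRUE))
}

msa_subset <- function(msa, keep) {
  new_msa(msa$seqs[keep], alphabet = msa$alphabet,
          weights = if (!is.null(msa$weights)) msa$weights[keep] else NULL)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Stockholm alignments via Biostrings, or A2M files in which
#' lowercase letters and '.' mark insert states relative to the profile match
#' columns. Insert states are removed per record, so the returned aligned
#' length equals the number of match columns. All residues are uppercased
#' and '.' in FASTA/Stockholm dialects is mapped to the gap symbol.
#'
#' @param path File path.
#' @param format One of \code{"fasta"}, \code{"stockholm"}, \code{"a2m"}.
#' @return An \code{msa} object.
#' @export
read_msa <- function(path, format = c("fasta", "stockholm", "a2m")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "stockholm") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(aln)
  } else {
    # read raw to preserve case for the A2M dialect
    set <- Biostrings::readBStringSet(path, format = "fasta")
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
  }
  if (format == "a2m") {
    # lowercase and '.' are insert states: drop them per record
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      keep <- !(ch == "." | (ch >= "a" & ch <= "z"))
      paste(ch[keep], collapse = "")
    }, character(1))
  } else {
    seqs <- gsub(".", GAP, toupper(seqs), fixed = TRUE)
  }
  new_msa(seqs)
}

#' Write an MSA to FASTA
#'
#' @param msa An \code{msa} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_msa <- function(msa, path) {
  set <- Biostrings::BStringSet(msa$seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Filter records by ungapped length
#'
#' Retains records whose residue count (gaps excluded) lies in
#' \code{[min_len, max_len]}; input order is preserved. The family curation
#' used for the transporter landscape keeps 574-661 residue sequences.
#'
#' @param msa An \code{msa} object.
#' @param min_len,max_len Inclusive bounds on ungapped length.
#' @return Filtered \code{msa}.
#' @export
length_filter <- function(msa, min_len, max_len) {
  stopifnot(min_len <= max_len)
  n <- ungapped_lengths(msa)
  msa_subset(msa, n >= min_len & n <= max_len)
}

#' Remove records with long gap runs
#'
#' Drops any record containing a run of more than \code{max_run} consecutive
#' gap symbols (default 25). Idempotent.
#'
#' @param msa An \code{msa} object.
#' @param max_run Longest tolerated gap run.
#' @return Filtered \code{msa}.
#' @export
gap_run_filter <- function(msa, max_run = 25L) {
  stopifnot(max_run >= 0)
  pattern <- sprintf("-{%d}", max_run + 1L)
  bad <- grepl(pattern, msa$seqs)
  msa_subset(msa, !bad)
}

#' Pairwise sequence identity
#'
#' Identity = matches at columns where both records are non-gap, divided by
#' the shorter ungapped length of the two. This is the single identity
#' definition used by [identity_subsample()], [compute_weights()] and
#' [novelty_check()].
#'
#' @param a,b Aligned sequences (equal width strings).
#' @return Fraction in \code{[0, 1]} (0 when there is no comparable column).
#' @export
pairwise_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != GAP & cb != GAP
  denom <- min(sum(ca != GAP), sum(cb != GAP))
  if (denom == 0) return(0)
  sum(ca == cb & both) / denom
}

msa_index_matrix <- function(msa) {
  letters_ok <- strsplit(msa$alphabet, "")[[1]]
  mat <- do.call(rbind, strsplit(unname(msa$seqs), ""))
  idx <- matrix(match(mat, letters_ok), nrow = nrow(mat))
  storage.mode(idx) <- "integer"
  idx
}

#' Greedy identity-based redundancy reduction
#'
#' Scans records in input order (optionally shuffled under \code{seed}) and
#' keeps a record iff its identity to every previously kept record is below
#' \code{threshold}. Every retained pair is therefore below the threshold.
#' The curation for the transporter family uses 0.87.
#'
#' @param msa An \code{msa} object.
#' @param threshold Identity threshold in (0, 1].
#' @param seed Optional integer; when given, records are scanned in a
#'   seed-controlled random order but returned in original order.
#' @return Subsampled \code{msa}.
#' @export
identity_subsample <- function(msa, threshold = 0.87, seed = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- length(msa$seqs)
  if (n <= 1L) return(msa)
  ord <- seq_len(n)
  if (!is.null(seed)) {
    ord <- local({ set.seed(as.integer(seed)); sample.int(n) })
  }
  idx <- msa_index_matrix(msa)
  gap_idx <- match(GAP, strsplit(msa$alphabet, "")[[1]])
  kept <- identity_greedy_cpp(idx, as.integer(ord), gap_idx, threshold)
  msa_subset(msa, sort(ord[kept]))
}

#' One-hot encode an alignment
#'
#' Each record becomes a binary row of length \code{L * q} laid out
#' position-major: columns \code{(i-1)*q + 1 .. i*q} hold the indicator of
#' alignment column \code{i} over the alphabet, in alphabet order (gap is the
#' last channel of each block). Row sums equal \code{L}.
#'
#' @param msa An \code{msa} object.
#' @return \code{n x (L*q)} numeric 0/1 matrix with rownames from record ids.
#' @export
encode_onehot <- function(msa) {
  idx <- msa_index_matrix(msa)
  n <- nrow(idx); L <- ncol(idx); q <- msa$q
  out <- matrix(0, n, L * q)
  cols <- sweep(idx, 2, (seq_len(L) - 1L) * q, "+")
  out[cbind(rep(seq_len(n), L), as.vector(cols))] <- 1
  rownames(out) <- names(msa$seqs)
  out
}

#' Decode one-hot rows back to sequences
#'
#' Inverse of [encode_onehot()] for exact one-hot input; for arbitrary
#' nonnegative rows (e.g. decoder probabilities) takes the per-position
#' argmax, ties broken toward the lowest alphabet index.
#'
#' @param x Numeric matrix with \code{L*q} columns.
#' @param alphabet Alphabet string.
#' @return Character vector of sequences of length \code{nrow(x)}.
#' @export
decode_onehot <- function(x, alphabet = protein_alphabet()) {
  q <- nchar(alphabet)
  stopifnot(ncol(x) %% q == 0)
  L <- ncol(x) %/% q
  letters_ok <- strsplit(alphabet, "")[[1]]
  idx <- matrix(0L, nrow(x), L)
  for (i in seq_len(L)) {
    block <- x[, ((i - 1L) * q + 1L):(i * q), drop = FALSE]
    idx[, i] <- max.col(block, ties.method = "first")
  }
  apply(idx, 1L, function(r) paste(letters_ok[r], collapse = ""))
}
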