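#' Build a regular latent grid
#'
#' The grid covers the bounding box of the supplied latent encodings,
#' expanded by \code{margin} per side, with \code{resolution} points per axis
#' (default 500, i.e. 250,000 pixels). Pixels are ordered row-major with
#' \code{z0} varying fastest.
#'
#' @param encodings \code{n x 2} matrix of latent coordinates.
#' @param resolution Points per axis (>= 2).
#' @param margin Fractional expansion of the bounding box per side
#'   (default 0.1).
#' @return Object of class \code{"latent_grid"}: \code{z0}, \code{z1} (axis
#'   vectors), \code{z0_bounds}, \code{z1_bounds}, \code{resolution},
#'   \code{coordinates} (\code{resolution^2 x 2} matrix).
#' @export
build_grid <- function(encodings, resolution = 500L, margin = 0.1) {
  encodings <- as.matrix(encodings)
  stopifnot(nrow(encodings) > 0, ncol(encodings) == 2, resolution >= 2)
  r0 <- range(encodings[, 1]); r1 <- range(encodings[, 2])
  if (diff(r0) == 0 || diff(r1) == 0)
    stop("degenerate bounding box: encodings do not span both latent axes",
         call. = FALSE)
  pad0 <- margin * diff(r0); pad1 <- margin * diff(r1)
  b0 <- c(r0[1] - pad0, r0[2] + pad0)
  b1 <- c(r1[1] - pad1, r1[2] + pad1)
  z0 <- seq(b0[1], b0[2], length.out = resolution)
  z1 <- seq(b1[1], b1[2], length.out = resolution)
  coords <- cbind(z0 = rep(z0, times = resolution),
                  z1 = rep(z1, each = resolution))
  structure(list(z0 = z0, z1 = z1, z0_bounds = b0, z1_bounds = b1,
                 resolution = as.integer(resolution), coordinates = coords),
            class = "latent_grid")
}

#' @export
print.latent_grid <- function(x, ...) {
  cat("latent grid: ", x$resolution, " x ", x$resolution, " = ",
      nrow(x$coordinates), " pixels\n", sep = "")
  invisible(x)
}

#' Score a latent grid into an LGL map
#'
#' Decodes every grid pixel with the VAE and scores the decoded sequence with
#' the Potts Hamiltonian: the latent generative landscape. Decoding is done
#' in chunks to bound memory; the result is a pure function of its inputs.
#'
#' @param vae A trained \code{"vae_model"}.
#' @param potts A \code{"potts_model"} sharing \code{L} and alphabet with the
#'   VAE.
#' @param grid A \code{"latent_grid"}.
#' @param overlay Optional data frame (id, z0, z1, label) of native
#'   sequences' encodings to carry with the map.
#' @param chunk_size Pixels decoded per chunk (default 25000).
#' @return Object of class \code{"lgl_map"}: \code{grid}, \code{seq_idx}
#'   (\code{pixels x L} integer matrix of alphabet indices),
#'   \code{hamiltonians} (numeric per pixel), \code{alphabet},
#'   \code{overlay}.
#' @export
score_map <- function(vae, potts, grid, overlay = NULL, chunk_size = 25000L) {
  if (vae$L != potts$L || vae$alphabet != potts$alphabet)
    stop("VAE (L = ", vae$L, ") and Potts model (L = ", potts$L,
         ") must share L and alphabet", call. = FALSE)
  coords <- grid$coordinates
  n <- nrow(coords)
  seq_idx <- matrix(0L, n, vae$L)
  scores <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    rows <- s:min(s + chunk_size - 1L, n)
    idx <- vae_decode(vae, coords[rows, , drop = FALSE], as_indices = TRUE)
    seq_idx[rows, ] <- idx
    scores[rows] <- hamiltonian(potts, idx)
  }
  structure(list(grid = grid, seq_idx = seq_idx, hamiltonians = scores,
                 alphabet = vae$alphabet, overlay = overlay),
            class = "lgl_map")
}

#' @export
print.lgl_map <- function(x, ...) {
  cat("LGL map: ", nrow(x$seq_idx), " pixels, L = ", ncol(x$seq_idx), "\n",
      "Hamiltonian range: [", format(min(x$hamiltonians)), ", ",
      format(max(x$hamiltonians)), "]\n", sep = "")
  invisible(x)
}

#' Pixel sequence as character
#' @param map An \code{"lgl_map"}.
#' @param pixels Pixel indices.
#' @return Character vector of decoded sequences.
#' @export
map_sequences <- function(map, pixels) {
  letters_ok <- strsplit(map$alphabet, "")[[1]]
  apply(map$seq_idx[pixels, , drop = FALSE], 1L,
        function(r) paste(letters_ok[r], collapse = ""))
}

nearest_pixel <- function(grid, z) {
  d2 <- (grid$coordinates[, 1] - z[1])^2 + (grid$coordinates[, 2] - z[2])^2
  which.min(d2)  # which.min takes the first (lowest-index) minimum on ties
}

#' Decode candidate sequences at latent coordinates
#'
#' Returns the cached decoded sequence of the grid pixel nearest (Euclidean)
#' to each requested coordinate, ties resolved toward the lower pixel index,
#' so candidates are exactly reproducible from a stored map.
#'
#' @param map An \code{"lgl_map"}.
#' @param coords \code{n x 2} matrix (or length-2 vector) of latent
#'   coordinates; must lie within the grid bounds.
#' @return Data frame with \code{z0}, \code{z1}, \code{pixel},
#'   \code{sequence}, \code{hamiltonian}.
#' @export
decode_candidates <- function(map, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  g <- map$grid
  out <- vector("list", nrow(coords))
  for (k in seq_len(nrow(coords))) {
    z <- as.numeric(coords[k, ])
    if (z[1] < g$z0_bounds[1] || z[1] > g$z0_bounds[2] ||
        z[2] < g$z1_bounds[1] || z[2] > g$z1_bounds[2])
      stop("coordinate (", z[1], ", ", z[2], ") lies outside the grid bounds",
           call. = FALSE)
    px <- nearest_pixel(g, z)
    out[[k]] <- data.frame(z0 = z[1], z1 = z[2], pixel = px,
                           sequence = map_sequences(map, px),
                           hamiltonian = map$hamiltonians[px])
  }
  do.call(rbind, out)
}

#' Novelty of a candidate against the training family
#'
#' Exact maximum pairwise identity of the candidate to every record of the
#' MSA (identity as in [pairwise_identity()]), and the record achieving it.
#'
#' @param candidate Aligned candidate sequence (width \code{msa$L}).
#' @param msa The training \code{msa}.
#' @return List with \code{max_identity} and \code{nearest_id}.
#' @export
novelty_check <- function(candidate, msa) {
  if (length(msa$seqs) == 0) stop("msa is empty", call. = FALSE)
  if (nchar(candidate) != msa$L)
    stop("candidate width ", nchar(candidate), " != msa L = ", msa$L,
         call. = FALSE)
  idx <- msa_index_matrix(msa)
  gap_idx <- match(GAP, strsplit(msa$alphabet, "")[[1]])
  if (is.na(gap_idx)) gap_idx <- 0L
  qidx <- seq_to_idx(candidate, msa$alphabet)
  res <- max_identity_cpp(idx, as.integer(qidx), gap_idx)
  list(max_identity = res[1], nearest_id = names(msa$seqs)[res[2]])
}

#' Motif presence in a candidate sequence
#'
#' Searches the gap-stripped sequence for plain residue motifs (e.g. the
#' P-domain DKTGT and A-domain TGE signatures) and reports the 1-based
#' ungapped position of the first occurrence.
#'
#' @param seq Aligned or ungapped sequence.
#' @param motifs Named character vector (or list) of motif strings.
#' @return Data frame with \code{motif}, \code{pattern}, \code{found},
#'   \code{position} (NA when absent).
#' @export
motif_check <- function(seq, motifs) {
  stripped <- gsub(GAP, "", seq, fixed = TRUE)
  motifs <- unlist(motifs)
  if (is.null(names(motifs))) names(motifs) <- motifs
  pos <- vapply(motifs, function(p)
    regexpr(p, stripped, fixed = TRUE)[[1]], numeric(1))
  data.frame(motif = names(motifs), pattern = unname(motifs),
             found = pos > 0,
             position = ifelse(pos > 0, pos, NA_integer_),
             row.names = NULL)
}

expand_domains <- function(domains, L) {
  cols <- lapply(domains, function(rg) {
    rg <- as.integer(rg)
    stopifnot(length(rg) == 2, rg[1] >= 1, rg[2] <= L, rg[1] <= rg[2])
    rg[1]:rg[2]
  })
  all_cols <- unlist(cols)
  if (anyDuplicated(all_cols))
    stop("domain ranges overlap at column ",
         all_cols[duplicated(all_cols)][1], call. = FALSE)
  cols
}

#' Per-domain mutation report for a candidate against a reference
#'
#' Compares two aligned sequences column by column: a substitution is a
#' column where both are non-gap and differ; an insertion/deletion is a
#' column gapped in exactly one. Counts are reported per domain (1-based
#' inclusive column ranges) and in total; columns outside every domain are
#' tallied under \code{"other"}.
#'
#' @param candidate,reference Aligned sequences of equal width.
#' @param domains Named list of length-2 integer vectors
#'   \code{c(first, last)}; ranges must not overlap.
#' @return List of class \code{"candidate_report"} with \code{by_domain}
#'   (data frame: domain, substitutions, indels), \code{total_substitutions},
#'   \code{total_indels}.
#' @export
mutation_report <- function(candidate, reference, domains = list()) {
  if (nchar(candidate) != nchar(reference))
    stop("candidate and reference must have equal aligned length",
         call. = FALSE)
  L <- nchar(candidate)
  ca <- strsplit(candidate, "")[[1]]; cr <- strsplit(reference, "")[[1]]
  subs <- ca != GAP & cr != GAP & ca != cr
  indel <- xor(ca == GAP, cr == GAP)
  cols <- expand_domains(domains, L)
  covered <- unlist(cols)
  rest <- setdiff(seq_len(L), covered)
  if (length(rest) > 0) cols <- c(cols, list(other = rest))
  by_domain <- data.frame(
    domain = names(cols),
    substitutions = vapply(cols, function(ix) sum(subs[ix]), numeric(1)),
    indels = vapply(cols, function(ix) sum(indel[ix]), numeric(1)),
    row.names = NULL)
  structure(list(by_domain = by_domain,
                 total_substitutions = sum(subs),
                 total_indels = sum(indel)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  print(x$by_domain)
  cat("total: ", x$total_substitutions, " substitutions, ",
      x$total_indels, " indels\n", sep = "")
  invisible(x)
}

#' Full candidate report
#'
#' Combines Hamiltonian, novelty, motif and mutation analyses for one
#' decoded candidate.
#'
#' @param candidate Aligned candidate sequence.
#' @param msa Training \code{msa}.
#' @param potts A \code{"potts_model"}.
#' @param reference Aligned reference sequence (e.g. the wild-type
#'   transporter).
#' @param motifs Named motif vector (see [motif_check()]).
#' @param domains Named domain ranges (see [mutation_report()]).
#' @return List: \code{hamiltonian}, \code{novelty}, \code{motifs},
#'   \code{mutations}.
#' @export
candidate_report <- function(candidate, msa, potts, reference,
                             motifs = c(P_domain = "DKTGT", A_domain = "TGE"),
                             domains = list()) {
  list(hamiltonian = hamiltonian(potts, candidate),
       novelty = novelty_check(candidate, msa),
       motifs = motif_check(candidate, motifs),
       mutations = mutation_report(candidate, reference, domains))
}

#' Export the Hamiltonian surface of a map to TSV
#'
#' Long format: one row per pixel with \code{z0}, \code{z1},
#' \code{hamiltonian}.
#'
#' @param map An \code{"lgl_map"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_map_tsv <- function(map, path) {
  df <- data.frame(map$grid$coordinates, hamiltonian = map$hamiltonians)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
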