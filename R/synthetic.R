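## Seeded generators for validation fixtures: Potts families with planted
## couplings (optionally as subgroup mixtures) and two-state toy
## trajectories with known per-frame ground truth.

#' Potts model with planted couplings
#'
#' Builds a model with Gaussian local fields and "matching" couplings
#' \code{e_ij(a, a) = strength} on the planted pairs (zero elsewhere): a
#' planted pair favors identical symbols at its two positions, the classic
#' covariation signal that DCA is designed to detect.
#'
#' @param L Alignment length.
#' @param q Alphabet size; the alphabet is the first \code{q} symbols of
#'   [protein_alphabet()] unless \code{alphabet} is given.
#' @param planted_pairs Two-column matrix (or data frame) of position pairs
#'   \code{i < j}.
#' @param coupling_strength Coupling magnitude on planted pairs (default 2).
#' @param field_sd Standard deviation of the random fields (default 0.3).
#' @param alphabet Optional explicit alphabet string.
#' @param seed Integer seed.
#' @return A \code{"potts_model"} with \code{meta$planted_pairs}.
#' @export
make_planted_potts <- function(L, q = 21L, planted_pairs = NULL,
                               coupling_strength = 2, field_sd = 0.3,
                               alphabet = NULL, seed = 1L) {
  if (is.null(alphabet)) alphabet <- substr(protein_alphabet(), 1L, q)
  stopifnot(nchar(alphabet) == q)
  set.seed(as.integer(seed))
  h <- matrix(stats::rnorm(L * q, 0, field_sd), L, q)
  e <- array(0, dim = c(L, L, q, q))
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.matrix(planted_pairs)[, 1:2, drop = FALSE]
    stopifnot(all(planted_pairs[, 1] < planted_pairs[, 2]))
    for (r in seq_len(nrow(planted_pairs))) {
      i <- planted_pairs[r, 1]; j <- planted_pairs[r, 2]
      blk <- diag(coupling_strength, q, q)
      e[i, j, , ] <- blk
      e[j, i, , ] <- t(blk)
    }
  }
  new_potts_model(h, e, alphabet = alphabet,
                  meta = list(planted_pairs = planted_pairs,
                              coupling_strength = coupling_strength,
                              seed = seed))
}

#' Gibbs-sample an MSA from a Potts model
#'
#' Single-chain Gibbs sampler over the model's Boltzmann distribution:
#' \code{burn_in} sweeps are discarded, then one sequence is recorded every
#' \code{thin} sweeps. Bit-reproducible given \code{seed}.
#'
#' @param model A \code{"potts_model"}.
#' @param n Number of sequences.
#' @param burn_in Burn-in sweeps (default 1000).
#' @param thin Sweeps between recorded samples (default 10).
#' @param seed Integer seed.
#' @return An \code{msa} over the model's alphabet.
#' @export
sample_potts <- function(model, n, burn_in = 1000L, thin = 10L, seed = 1L) {
  stopifnot(n > 0)
  set.seed(as.integer(seed))
  idx <- gibbs_sample_potts_cpp(model$h, model$e, as.integer(n),
                                as.integer(burn_in), as.integer(thin))
  letters_ok <- strsplit(model$alphabet, "")[[1]]
  seqs <- apply(idx, 1L, function(r) paste(letters_ok[r], collapse = ""))
  names(seqs) <- sprintf("synth%05d", seq_len(n))
  new_msa(seqs, alphabet = model$alphabet)
}

#' Synthetic family with subgroup mixture structure
#'
#' Generates \code{k} subgroups from Potts models that share the planted
#' couplings but differ in their local fields: in each subgroup a
#' seed-chosen preferred symbol receives a field bonus of \code{separation}
#' at a fraction \code{bias_fraction} of positions. Large separation makes
#' intra-subgroup identity exceed inter-subgroup identity, emulating the
#' clustered families seen in real latent landscapes.
#'
#' @param L,q Alignment dimensions.
#' @param n Total sequence count (split as evenly as possible across
#'   subgroups).
#' @param k Number of subgroups (>= 1).
#' @param planted_pairs Position pairs shared by all subgroups; default 4
#'   seeded pairs when \code{L >= 8}.
#' @param coupling_strength,field_sd As in [make_planted_potts()].
#' @param separation Field bonus of subgroup-preferred symbols (default 2).
#' @param bias_fraction Fraction of positions biased per subgroup
#'   (default 0.5).
#' @param burn_in,thin Gibbs settings per subgroup chain.
#' @param seed Integer seed.
#' @return List: \code{msa}, \code{labels} (integer subgroup per record),
#'   \code{models} (per-subgroup Potts models), \code{planted_pairs}.
#' @export
make_family_mixture <- function(L = 30L, q = 21L, n = 500L, k = 2L,
                                planted_pairs = NULL, coupling_strength = 2,
                                field_sd = 0.3, separation = 2,
                                bias_fraction = 0.5, burn_in = 1000L,
                                thin = 10L, seed = 1L) {
  stopifnot(k >= 1, n > 0)
  set.seed(as.integer(seed))
  if (is.null(planted_pairs) && L >= 8) {
    pos <- sample.int(L, 8L)
    planted_pairs <- cbind(pmin(pos[1:4], pos[5:8]), pmax(pos[1:4], pos[5:8]))
    # regenerate any degenerate pair (i == j)
    while (any(planted_pairs[, 1] == planted_pairs[, 2]) ||
           anyDuplicated(planted_pairs)) {
      pos <- sample.int(L, 8L)
      planted_pairs <- cbind(pmin(pos[1:4], pos[5:8]),
                             pmax(pos[1:4], pos[5:8]))
    }
  }
  base <- make_planted_potts(L, q, planted_pairs, coupling_strength,
                             field_sd, seed = seed)
  n_biased <- max(1L, round(bias_fraction * L))
  counts <- diff(round(seq(0, n, length.out = k + 1)))
  models <- vector("list", k)
  pieces <- vector("list", k)
  labels <- integer(0)
  for (g in seq_len(k)) {
    m <- base
    if (k > 1) {
      sites <- sample.int(L, n_biased)
      prefs <- sample.int(q, n_biased, replace = TRUE)
      m$h[cbind(sites, prefs)] <- m$h[cbind(sites, prefs)] + separation
    }
    models[[g]] <- m
    sub <- sample_potts(m, counts[g], burn_in = burn_in, thin = thin,
                        seed = seed + g)
    names(sub$seqs) <- sprintf("g%d_%s", g, names(sub$seqs))
    pieces[[g]] <- sub$seqs
    labels <- c(labels, rep(g, counts[g]))
  }
  msa <- new_msa(unlist(pieces), alphabet = base$alphabet)
  list(msa = msa, labels = labels, models = models,
       planted_pairs = planted_pairs)
}

# fixed zero-mean offset clouds used for rigid toy bodies
group_offsets <- function(n_atoms, scale = 1) {
  base <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1), c(1, 1, 0), c(-1, -1, 0),
                c(0, 1, 1), c(0, -1, -1))
  stopifnot(n_atoms %% nrow(base) == 0)
  out <- base[rep(seq_len(nrow(base)), n_atoms / nrow(base)), , drop = FALSE]
  reps <- n_atoms / nrow(base)
  if (reps > 1) {
    shift <- rep(seq_len(reps) - (reps + 1) / 2, each = nrow(base))
    out[, 3] <- out[, 3] + 0.3 * shift  # spread stacked copies, mean stays 0
  }
  out * scale
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Two-state toy trajectory with known ground truth
#'
#' Builds a toy multidomain structure: a static transmembrane scaffold of 8
#' helix groups in two blocks, static kink and basal-anchor groups defining
#' the tilt vectors, and a rigid actuator domain that travels from its E2Pi
#' placement to its E1 placement as the interpolation parameter \code{t}
#' goes 0 to 1. The domain's center of mass follows an in-plane path whose
#' direction angle from the kink vector is linear in \code{t} and whose
#' distance to the E1 position equals \code{(1 - t) * travel}: the frame's
#' (tilt, delta-d) vector then moves along the straight segment between the
#' two reference vectors, so the noise-free movement score equals
#' \code{100 t} exactly. Optionally, block 2 of the scaffold translates
#' along x by \code{t * block2_shift} (helix pairs are laid out so the
#' maximum interblock distance change equals the shift exactly). I.i.d.
#' Gaussian noise of sd \code{sigma} is added to every atom coordinate of
#' every frame after placement; the references stay noise-free.
#'
#' @param n_frames Number of frames (default 400).
#' @param sigma Coordinate noise sd in angstrom (default 0.5).
#' @param block2_shift Final x-displacement of block 2 in angstrom
#'   (default 0).
#' @param total_time Trajectory duration in ns (default 400).
#' @param phi0,phi1 Direction angle (degrees from the kink vector) of the
#'   actuator domain at E2Pi and E1 (defaults 60 and 40).
#' @param r1 Anchor-to-domain distance at E1 in angstrom (default 20).
#' @param travel Delta-distance at E2Pi in angstrom (default 12); must
#'   exceed the arc length \code{r1 * |phi1 - phi0|} for the path to exist.
#' @param seed Integer seed (noise only; geometry is deterministic).
#' @return List: \code{e2pi}, \code{e1} (\code{N x 3} reference matrices),
#'   \code{traj} (a \code{"trajectory"}), \code{t} (ground-truth parameter
#'   per frame), \code{selections} (atom groups incl. \code{helices}),
#'   \code{atoms} (metadata), \code{params}.
#' @export
make_two_state_trajectory <- function(n_frames = 400L, sigma = 0.5,
                                      block2_shift = 0, total_time = 400,
                                      phi0 = 60, phi1 = 40, r1 = 20,
                                      travel = 12, seed = 1L) {
  stopifnot(n_frames >= 2, sigma >= 0, phi0 != phi1 || travel > 0)
  dphi <- abs(phi1 - phi0) * pi / 180
  if (travel <= r1 * dphi)
    stop("travel must exceed r1 * |phi1 - phi0| (radians) = ",
         format(r1 * dphi), " for the domain path to exist", call. = FALSE)
  helix_names <- c("MA", "MB", "M1", "M2", "M3", "M4", "M5", "M6")
  helix_xy <- rbind(c(0, 0), c(4, 6), c(8, 0), c(12, 6),
                    c(16, 0), c(20, 6), c(24, 0), c(28, 6))
  helix_atoms <- 10L
  helix_z <- seq(-4.5, 4.5, length.out = helix_atoms)
  coords <- list(); groups <- character(0)
  for (hn in seq_along(helix_names)) {
    coords[[length(coords) + 1L]] <-
      cbind(helix_xy[hn, 1], helix_xy[hn, 2], helix_z)
    groups <- c(groups, rep(helix_names[hn], helix_atoms))
  }
  anchor <- c(6, 14, 0)
  fixed_groups <- list(kink_a = c(2, 10, 5), kink_b = c(12, 10, 5),
                       basal_anchor = anchor)
  for (gn in names(fixed_groups)) {
    coords[[length(coords) + 1L]] <-
      sweep(group_offsets(10L, 0.8), 2, fixed_groups[[gn]], "+")
    groups <- c(groups, rep(gn, 10L))
  }
  a_offsets <- group_offsets(60L, 1.2)
  n_scaffold <- length(groups)
  groups <- c(groups, rep("a_domain", 60L))
  scaffold <- do.call(rbind, coords)

  place_domain <- function(t) {
    phi <- (phi0 + (phi1 - phi0) * t) * pi / 180
    psi <- dphi * (1 - t)
    r <- r1 * cos(psi) + sqrt(((1 - t) * travel)^2 - (r1 * sin(psi))^2)
    com <- anchor + r * c(cos(phi), sin(phi), 0)
    body <- a_offsets %*% t(rot_z((phi1 - phi0) * t))
    sweep(body, 2, com, "+")
  }
  block2_atoms <- which(groups %in% c("M3", "M4", "M5", "M6"))
  build_frame <- function(t) {
    sc <- scaffold
    sc[block2_atoms, 1] <- sc[block2_atoms, 1] + t * block2_shift
    rbind(sc, place_domain(t))
  }
  e2pi <- build_frame(0)
  e1 <- build_frame(1)
  tgrid <- seq(0, 1, length.out = n_frames)
  set.seed(as.integer(seed))
  frames <- lapply(tgrid, function(t) {
    f <- build_frame(t)
    if (sigma > 0) f <- f + matrix(stats::rnorm(length(f), 0, sigma),
                                   nrow(f), 3)
    f
  })
  times <- tgrid * total_time
  sel_idx <- split(seq_along(groups), groups)
  selections <- list(
    helices = sel_idx[helix_names],
    a_domain = sel_idx$a_domain,
    a_domain_beta = sel_idx$a_domain,
    basal_anchor = sel_idx$basal_anchor,
    kink_a = sel_idx$kink_a,
    kink_b = sel_idx$kink_b)
  atoms <- data.frame(index = seq_along(groups), group = groups)
  list(e2pi = e2pi, e1 = e1,
       traj = new_trajectory(frames, times, atoms),
       t = tgrid, selections = selections, atoms = atoms,
       params = list(n_frames = n_frames, sigma = sigma,
                     block2_shift = block2_shift, total_time = total_time,
                     phi0 = phi0, phi1 = phi1, r1 = r1, travel = travel,
                     seed = seed, n_scaffold_atoms = n_scaffold))
}

#' Write a structure to PDB
#'
#' @param xyz \code{N x 3} coordinates.
#' @param path Output path.
#' @param atoms Optional metadata (uses \code{group} for residue naming).
#' @return Invisibly, \code{path}.
#' @export
write_structure_pdb <- function(xyz, path, atoms = NULL) {
  resno <- if (!is.null(atoms)) as.integer(factor(atoms$group,
                                                  levels = unique(atoms$group)))
           else rep(1L, nrow(xyz))
  bio3d::write.pdb(file = path, xyz = mat2xyz(xyz),
                   resno = resno, resid = rep("GLY", nrow(xyz)),
                   elety = rep("CA", nrow(xyz)))
  invisible(path)
}

#' Read a structure from PDB
#' @param path PDB file.
#' @return \code{N x 3} coordinate matrix.
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  xyz2mat(pdb$xyz[1, ])
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL block per frame. PDB carries no time axis; recover times on
#' read via the \code{times}/\code{stride} arguments of
#' [read_trajectory_pdb()].
#'
#' @param traj A \code{"trajectory"}.
#' @param path Output path.
#' @param atoms Optional metadata (uses \code{group} for residue numbering).
#' @return Invisibly, \code{path}.
#' @export
write_trajectory_pdb <- function(traj, path, atoms = NULL) {
  stopifnot(length(traj$frames) > 0)
  N <- nrow(traj$frames[[1]])
  resno <- if (!is.null(atoms)) as.integer(factor(atoms$group,
                                                  levels = unique(atoms$group)))
           else rep(1L, N)
  xyz <- do.call(rbind, lapply(traj$frames, mat2xyz))
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno,
                   resid = rep("GLY", N), elety = rep("CA", N))
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' @param path PDB file with one MODEL per frame.
#' @param times Frame times in ns; alternatively give \code{stride} (ns per
#'   frame, frames at 0, stride, 2*stride, ...).
#' @param stride Time step in ns, used when \code{times} is \code{NULL}.
#' @return A \code{"trajectory"}.
#' @export
read_trajectory_pdb <- function(path, times = NULL, stride = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  n <- nrow(pdb$xyz)
  frames <- lapply(seq_len(n), function(i) xyz2mat(pdb$xyz[i, ]))
  if (is.null(times)) times <- (seq_len(n) - 1) * stride
  new_trajectory(frames, times)
}

#' Write a trajectory in plain XYZ format
#'
#' One block per frame: atom count, a comment line carrying \code{t=<ns>},
#' then one \code{C x y z} line per atom.
#'
#' @param traj A \code{"trajectory"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_along(traj$frames)) {
    f <- traj$frames[[j]]
    writeLines(c(as.character(nrow(f)),
                 sprintf("t=%.6f", traj$times[j]),
                 sprintf("C %.6f %.6f %.6f", f[, 1], f[, 2], f[, 3])), con)
  }
  invisible(path)
}

#' Read a plain XYZ trajectory
#' @param path XYZ file written by [write_trajectory_xyz()] (comment lines
#'   of the form \code{t=<time>} supply frame times; otherwise frame index).
#' @return A \code{"trajectory"}.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1L]
    tm <- if (grepl("^t=", comment)) as.numeric(sub("^t=", "", comment))
          else length(frames) + 1
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), n, 3)
    times <- c(times, tm)
    i <- i + 2L + n
  }
  new_trajectory(frames, times)
}
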