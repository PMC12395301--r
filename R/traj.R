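## Domain-motion analysis of coordinate trajectories against two reference
## conformations (an E2Pi start and an E1 target): actuator-domain tilt
## angle and displacement, a percent movement score combining both, helix
## distance difference matrices, and unit-root stationarity checks of RMSD
## series.

mat2xyz <- function(m) as.vector(t(m))
xyz2mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Center of mass of an atom selection
#'
#' Unweighted mean of the selected coordinates (all atoms in the toy systems
#' carry equal mass; real selections are conventionally C-alpha only).
#'
#' @param xyz \code{N x 3} coordinate matrix.
#' @param idx Integer atom indices.
#' @return Length-3 numeric vector.
#' @export
center_of_mass <- function(xyz, idx = seq_len(nrow(xyz))) {
  colMeans(xyz[idx, , drop = FALSE])
}

#' Construct a trajectory object
#'
#' @param frames List of \code{N x 3} coordinate matrices (angstrom).
#' @param times Numeric frame times in ns (same length as \code{frames}).
#' @param atoms Optional atom metadata data frame with \code{N} rows.
#' @return Object of class \code{"trajectory"}.
#' @export
new_trajectory <- function(frames, times, atoms = NULL) {
  stopifnot(length(frames) == length(times))
  if (length(frames) > 0) {
    N <- nrow(frames[[1]])
    stopifnot(all(vapply(frames, nrow, integer(1)) == N))
    if (!is.null(atoms)) stopifnot(nrow(atoms) == N)
  }
  structure(list(frames = frames, times = as.numeric(times), atoms = atoms),
            class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", length(x$frames), " frames",
      if (length(x$times)) paste0(", t in [", min(x$times), ", ",
                                  max(x$times), "] ns"), "\n", sep = "")
  invisible(x)
}

check_selection <- function(sel, N, what) {
  if (is.null(sel) || length(sel) == 0)
    stop("selection group '", what, "' is missing or empty", call. = FALSE)
  if (any(sel < 1 | sel > N))
    stop("selection group '", what, "' indexes atoms outside the structure",
         call. = FALSE)
  as.integer(sel)
}

#' Superpose one structure onto a reference
#'
#' Least-squares rigid-body fit over the selected atoms (bio3d's Kabsch
#' superposition); the returned coordinates are the whole structure moved by
#' the fitted transform.
#'
#' @param xyz \code{N x 3} mobile coordinates.
#' @param reference \code{N x 3} reference coordinates.
#' @param sel Atom indices used for the fit.
#' @return Fitted \code{N x 3} matrix.
#' @export
superpose <- function(xyz, reference, sel) {
  sel <- check_selection(sel, nrow(xyz), "fit")
  xi <- bio3d::atom2xyz(sel)
  fitted <- bio3d::fit.xyz(fixed = mat2xyz(reference),
                           mobile = mat2xyz(xyz),
                           fixed.inds = xi, mobile.inds = xi)
  xyz2mat(fitted)
}

#' Align every trajectory frame to a reference over a selection
#'
#' Rigid-body superposition of each frame onto the reference over the
#' transmembrane-helix selection (the measurement convention: all domain
#' metrics are computed in the frame of the E2Pi TM helices).
#'
#' @param traj A \code{"trajectory"}.
#' @param reference \code{N x 3} reference coordinates.
#' @param sel Atom indices of the alignment selection.
#' @return Aligned \code{"trajectory"}.
#' @export
align_frames <- function(traj, reference, sel) {
  if (length(traj$frames) == 0) stop("empty trajectory", call. = FALSE)
  sel <- check_selection(sel, nrow(reference), "alignment")
  if (nrow(traj$frames[[1]]) != nrow(reference))
    stop("trajectory and reference have different atom counts", call. = FALSE)
  traj$frames <- lapply(traj$frames, superpose, reference = reference,
                        sel = sel)
  traj
}

#' Drop the equilibration segment of a trajectory
#'
#' Removes frames with time at or below \code{trim_time} (default 50 ns, the
#' equilibration window excluded before analysis).
#'
#' @param traj A \code{"trajectory"} with frame times.
#' @param trim_time Equilibration time in ns.
#' @return Trimmed \code{"trajectory"}.
#' @export
equilibration_trim <- function(traj, trim_time = 50) {
  if (trim_time <= 0) return(traj)
  keep <- traj$times > trim_time
  if (!any(keep))
    stop("equilibration trim at ", trim_time, " ns removes every frame",
         call. = FALSE)
  new_trajectory(traj$frames[keep], traj$times[keep], traj$atoms)
}

#' Per-frame RMSD over a selection
#'
#' @param traj An (aligned) \code{"trajectory"}.
#' @param reference \code{N x 3} reference coordinates.
#' @param sel Atom indices.
#' @return Numeric RMSD series in angstrom.
#' @export
rmsd_series <- function(traj, reference, sel = seq_len(nrow(reference))) {
  sel <- check_selection(sel, nrow(reference), "rmsd")
  ref <- reference[sel, , drop = FALSE]
  vapply(traj$frames, function(f) {
    d <- f[sel, , drop = FALSE] - ref
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
}

#' Tilt angle of the actuator domain
#'
#' Angle between two vectors: v1 along the MB' helix kink (center of mass of
#' \code{kink_b} minus \code{kink_a}) and v2 from the basal helix anchor to
#' the center of mass of the actuator domain's beta-sheets. Computed as
#' \code{atan2(|v1 x v2|, v1 . v2)} in degrees, range [0, 180].
#'
#' @param xyz \code{N x 3} frame coordinates.
#' @param selections Named list with integer groups \code{kink_a},
#'   \code{kink_b}, \code{basal_anchor}, and \code{a_domain_beta} (falls back
#'   to \code{a_domain}).
#' @return Angle in degrees.
#' @export
tilt_angle <- function(xyz, selections) {
  N <- nrow(xyz)
  beta <- if (!is.null(selections$a_domain_beta)) selections$a_domain_beta
          else selections$a_domain
  ka <- check_selection(selections$kink_a, N, "kink_a")
  kb <- check_selection(selections$kink_b, N, "kink_b")
  an <- check_selection(selections$basal_anchor, N, "basal_anchor")
  bt <- check_selection(beta, N, "a_domain_beta")
  v1 <- center_of_mass(xyz, kb) - center_of_mass(xyz, ka)
  v2 <- center_of_mass(xyz, bt) - center_of_mass(xyz, an)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("zero-length tilt vector; check the kink/anchor selections",
         call. = FALSE)
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  atan2(sqrt(sum(cr^2)), sum(v1 * v2)) * 180 / pi
}

#' Actuator-domain displacement toward the E1 state
#'
#' Euclidean distance between the domain's center of mass in a frame and in
#' the E1 reference. Both structures must already be aligned to the E2Pi TM
#' reference.
#'
#' @param xyz Frame coordinates.
#' @param e1_xyz E1 reference coordinates (aligned to E2Pi).
#' @param sel Actuator-domain atom indices.
#' @return Distance in angstrom.
#' @export
delta_distance <- function(xyz, e1_xyz, sel) {
  sel <- check_selection(sel, nrow(xyz), "a_domain")
  d <- center_of_mass(xyz, sel) - center_of_mass(e1_xyz, sel)
  sqrt(sum(d^2))
}

#' Percent movement score of a frame between two reference states
#'
#' With frame vector \code{F = (theta, delta_d)} and reference vectors for
#' the E2Pi start and E1 target states,
#' \code{score = (1 - |E1 - F| / |E1 - E2Pi|) * 100}. A frame at the E1
#' vector scores 100, a frame at the E2Pi vector scores 0; positive values
#' are progress toward E1, negative values deviation away from it.
#'
#' @param frame_vec,e2pi_vec,e1_vec Length-2 numeric vectors
#'   \code{(theta_degrees, delta_d_angstrom)}.
#' @return Score in percent.
#' @export
movement_score <- function(frame_vec, e2pi_vec, e1_vec) {
  stopifnot(length(frame_vec) == 2, length(e2pi_vec) == 2,
            length(e1_vec) == 2)
  target <- sqrt(sum((e1_vec - e2pi_vec)^2))
  if (target == 0)
    stop("E1 and E2Pi reference vectors coincide: zero target distance",
         call. = FALSE)
  frame_d <- sqrt(sum((e1_vec - frame_vec)^2))
  (1 - frame_d / target) * 100
}

#' Per-frame motion metrics of a trajectory
#'
#' Aligns the trajectory and the E1 reference to the E2Pi reference over the
#' TM-helix selection, measures reference (theta, delta-d) vectors from the
#' two reference structures, and returns the per-frame tilt angle,
#' displacement and movement score.
#'
#' @param traj A \code{"trajectory"}.
#' @param e2pi_ref,e1_ref \code{N x 3} reference coordinate matrices.
#' @param selections Named list with \code{helices} (named list of 8 atom
#'   groups MA, MB, M1..M6), \code{a_domain}, \code{basal_anchor},
#'   \code{kink_a}, \code{kink_b}, optional \code{a_domain_beta}.
#' @param align If \code{FALSE}, assume the trajectory is already aligned.
#' @return Data frame: \code{time}, \code{theta}, \code{delta_d},
#'   \code{score}, with reference vectors in attributes \code{e2pi_vec} /
#'   \code{e1_vec}.
#' @export
motion_analysis <- function(traj, e2pi_ref, e1_ref, selections,
                            align = TRUE) {
  tm_idx <- sort(unique(unlist(selections$helices)))
  tm_idx <- check_selection(tm_idx, nrow(e2pi_ref), "tm_helices")
  e1_aligned <- superpose(e1_ref, e2pi_ref, tm_idx)
  if (align) traj <- align_frames(traj, e2pi_ref, tm_idx)
  a_sel <- check_selection(selections$a_domain, nrow(e2pi_ref), "a_domain")
  e2pi_vec <- c(tilt_angle(e2pi_ref, selections),
                delta_distance(e2pi_ref, e1_aligned, a_sel))
  e1_vec <- c(tilt_angle(e1_aligned, selections),
              delta_distance(e1_aligned, e1_aligned, a_sel))
  theta <- vapply(traj$frames, tilt_angle, numeric(1),
                  selections = selections)
  dd <- vapply(traj$frames, delta_distance, numeric(1),
               e1_xyz = e1_aligned, sel = a_sel)
  score <- vapply(seq_along(theta), function(j)
    movement_score(c(theta[j], dd[j]), e2pi_vec, e1_vec), numeric(1))
  out <- data.frame(time = traj$times, theta = theta, delta_d = dd,
                    score = score)
  attr(out, "e2pi_vec") <- e2pi_vec
  attr(out, "e1_vec") <- e1_vec
  out
}

#' Normalized density of movement scores
#'
#' Histogram density (integrates to 1 over the binned range) plus the
#' maximum score attained, the per-trial "maximum coupled progress" summary.
#'
#' @param scores Numeric score series.
#' @param bins Number of bins (default 50) or a break vector.
#' @return List: \code{table} (data frame \code{mid}, \code{density},
#'   \code{width}), \code{max_score}.
#' @export
score_density <- function(scores, bins = 50) {
  stopifnot(length(scores) > 0)
  if (length(unique(scores)) == 1L) {
    # degenerate series: one occupied unit-width bin centered on the value
    return(list(table = data.frame(mid = scores[1], density = 1, width = 1),
                max_score = scores[1]))
  }
  h <- graphics::hist(scores, breaks = bins, plot = FALSE)
  list(table = data.frame(mid = h$mids, density = h$density,
                          width = diff(h$breaks)),
       max_score = max(scores))
}

#' Helix distance difference matrix
#'
#' Entry (a, b) is the change in the center-of-mass distance between helices
#' a and b from the reference to the frame, absolute by default (signed
#' frame-minus-reference behind \code{signed = TRUE}). Symmetric with zero
#' diagonal; invariant to global rigid motion of either structure.
#'
#' @param xyz Frame coordinates.
#' @param ref_xyz Reference coordinates.
#' @param helices Named list of 8 atom-index groups (MA, MB, M1..M6).
#' @param signed Report signed differences instead of absolute.
#' @return 8 x 8 labelled numeric matrix (angstrom).
#' @export
helix_ddm <- function(xyz, ref_xyz, helices, signed = FALSE) {
  if (length(helices) != 8 || is.null(names(helices)))
    stop("expected 8 named helix groups", call. = FALSE)
  for (nm in names(helices)) check_selection(helices[[nm]], nrow(xyz), nm)
  com_f <- t(vapply(helices, function(ix) center_of_mass(xyz, ix),
                    numeric(3)))
  com_r <- t(vapply(helices, function(ix) center_of_mass(ref_xyz, ix),
                    numeric(3)))
  d_f <- as.matrix(stats::dist(com_f))
  d_r <- as.matrix(stats::dist(com_r))
  ddm <- d_f - d_r
  if (!signed) ddm <- abs(ddm)
  dimnames(ddm) <- list(names(helices), names(helices))
  ddm
}

#' Interblock and intrablock DDM summaries
#'
#' Statistics over the 4 x 4 interblock submatrix (entries pairing a helix
#' of block 1 with one of block 2) versus the two intrablock triangles.
#'
#' @param ddm Matrix from [helix_ddm()].
#' @param blocks List of two character vectors naming the helices in each
#'   block; default the (MA, MB, M1, M2) / (M3, M4, M5, M6) partition.
#' @return List: \code{max_interblock}, \code{mean_interblock},
#'   \code{mean_intrablock}.
#' @export
interblock_summary <- function(ddm,
                               blocks = list(block1 = c("MA", "MB", "M1", "M2"),
                                             block2 = c("M3", "M4", "M5", "M6"))) {
  stopifnot(length(blocks) == 2)
  b1 <- blocks[[1]]; b2 <- blocks[[2]]
  if (!setequal(c(b1, b2), rownames(ddm)))
    stop("blocks must partition the helix labels of the DDM", call. = FALSE)
  inter <- ddm[b1, b2, drop = FALSE]
  intra1 <- ddm[b1, b1][upper.tri(ddm[b1, b1])]
  intra2 <- ddm[b2, b2][upper.tri(ddm[b2, b2])]
  list(max_interblock = max(inter),
       mean_interblock = mean(inter),
       mean_intrablock = mean(c(intra1, intra2)))
}

#' Write a DDM to TSV
#' @param ddm Matrix from [helix_ddm()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ddm_tsv <- function(ddm, path) {
  utils::write.table(ddm, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
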