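## Config-driven orchestration: curate -> DCA -> VAE -> LGL -> candidate
## reports, and the trajectory analysis pipeline. A single strictly
## validated config (YAML file or list) holds every threshold; each run
## writes its artifacts plus a manifest recording the config hash, seeds and
## artifact digests, so identical configs reproduce identical manifests.

config_error <- function(...) {
  stop(structure(class = c("seqlandscape_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "seqlandscape_config_error")) stop(e)
    stop(structure(class = c("seqlandscape_stage_error", "error", "condition"),
                   list(message = paste0("stage '", name, "' failed: ",
                                         conditionMessage(e)), call = NULL)))
  })
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    config_error("unknown config key", if (length(extra) > 1) "s", " in ",
                 where, ": ", paste(extra, collapse = ", "))
}

default_design_config <- function() {
  list(
    curation = list(min_len = NULL, max_len = NULL, max_gap_run = 25,
                    identity_threshold = 0.87, seed = NULL),
    dca = list(lambda = 0.5, reweight_threshold = 0.8),
    vae = list(lr = 1e-4, l2 = 1e-4, patience = 10, batch_size = 64,
               max_epochs = 1000, seed = 1, hidden_multiplier = 3,
               latent_dim = 2),
    lgl = list(resolution = 500, margin = 0.1),
    candidates = NULL, candidate_space = "latent",
    motifs = list(P_domain = "DKTGT", A_domain = "TGE"),
    domains = list(), reference = NULL)
}

merge_section <- function(defaults, user, where) {
  if (is.null(user)) return(defaults)
  check_keys(user, names(defaults), where)
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

in_range <- function(x, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
  if (is.null(x)) return(invisible())
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad || (if (hi_open) x >= hi else x > hi)
  if (bad) config_error(name, " = ", x, " outside [", lo, ", ", hi, "]")
}

#' Validate a design-pipeline config
#'
#' Merges user settings over the documented defaults, rejecting unknown keys
#' and out-of-range thresholds.
#'
#' @param config List, or path to a YAML file. Recognized top-level keys:
#'   \code{input} (either \code{msa}/\code{format} or a \code{synthetic}
#'   spec for [make_family_mixture()]), \code{curation}, \code{dca},
#'   \code{vae}, \code{lgl}, \code{candidates}, \code{candidate_space}
#'   (\code{"latent"} for absolute coordinates, \code{"fraction"} for
#'   positions as fractions of the grid bounds), \code{motifs},
#'   \code{domains}, \code{reference}, \code{out_dir}.
#' @return Validated config list.
#' @export
validate_design_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, c("input", "curation", "dca", "vae", "lgl",
                       "candidates", "candidate_space", "motifs", "domains",
                       "reference", "out_dir"), "config")
  if (is.null(config$candidate_space)) config$candidate_space <- "latent"
  if (!config$candidate_space %in% c("latent", "fraction"))
    config_error("candidate_space must be 'latent' or 'fraction'")
  if (is.null(config$input))
    config_error("config$input is required (msa path or synthetic spec)")
  check_keys(config$input, c("msa", "format", "synthetic"), "config$input")
  defaults <- default_design_config()
  for (nm in c("curation", "dca", "vae", "lgl"))
    config[[nm]] <- merge_section(defaults[[nm]], config[[nm]],
                                  paste0("config$", nm))
  for (nm in c("motifs", "domains"))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  cur <- config$curation
  in_range(cur$identity_threshold, 0, 1, "curation$identity_threshold",
           lo_open = TRUE)
  if (!is.null(cur$max_gap_run) && cur$max_gap_run < 0)
    config_error("curation$max_gap_run must be >= 0")
  in_range(config$dca$lambda, 0, 1, "dca$lambda", hi_open = TRUE)
  in_range(config$dca$reweight_threshold, 0, 1, "dca$reweight_threshold")
  v <- config$vae
  for (nm in c("lr", "l2")) in_range(v[[nm]], 0, Inf, paste0("vae$", nm))
  if (v$patience < 1) config_error("vae$patience must be >= 1")
  if (config$lgl$resolution < 2) config_error("lgl$resolution must be >= 2")
  in_range(config$lgl$margin, 0, 10, "lgl$margin")
  config
}

artifact_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  md5 <- tools::md5sum(files)
  stats::setNames(unname(md5), substring(files, nchar(dir) + 2L))
}

write_manifest <- function(out_dir, config, extra = list()) {
  config$out_dir <- NULL   # hash the scientific settings, not the run location
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                               digits = NA)
  cfg_file <- tempfile(); writeLines(cfg_json, cfg_file)
  manifest <- c(list(config_hash = unname(tools::md5sum(cfg_file)),
                     artifacts = as.list(artifact_digests(out_dir))),
                extra)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Run the design pipeline
#'
#' Executes curate -> reweight -> mean-field DCA -> VAE training -> latent
#' grid scoring -> candidate decoding and reporting, writing every artifact
#' and a manifest to \code{out_dir}. Reruns with the same config and seeds
#' reproduce identical artifact digests.
#'
#' @param config Config list or YAML path; see [validate_design_config()].
#' @return List: \code{msa} (curated), \code{potts}, \code{di}, \code{vae},
#'   \code{encodings}, \code{map}, \code{candidates},
#'   \code{candidate_reports}, \code{manifest}.
#' @export
run_design <- function(config) {
  config <- validate_design_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  msa <- run_stage("input", {
    inp <- config$input
    if (!is.null(inp$synthetic)) {
      fam <- do.call(make_family_mixture, inp$synthetic)
      attr(fam$msa, "labels") <- fam$labels
      fam$msa
    } else {
      read_msa(inp$msa, format = if (is.null(inp$format)) "fasta"
                                 else inp$format)
    }
  })
  msa <- run_stage("curation", {
    cur <- config$curation
    if (!is.null(cur$min_len) && !is.null(cur$max_len))
      msa <- length_filter(msa, cur$min_len, cur$max_len)
    msa <- gap_run_filter(msa, cur$max_gap_run)
    identity_subsample(msa, cur$identity_threshold, seed = cur$seed)
  })
  if (length(msa$seqs) == 0)
    stop(structure(class = c("seqlandscape_stage_error", "error", "condition"),
                   list(message = "stage 'curation' failed: no sequences survive curation",
                        call = NULL)))
  potts_bits <- run_stage("dca", {
    w <- compute_weights(msa, config$dca$reweight_threshold)
    fr <- empirical_frequencies(w, config$dca$lambda)
    model <- infer_mfdca(fr)
    list(msa = w, freqs = fr, model = model,
         di = direct_information(model, fr))
  })
  msa <- potts_bits$msa
  vae <- run_stage("vae", {
    X <- encode_onehot(msa)
    v <- config$vae
    vae_train(X, q = msa$q, alphabet = msa$alphabet,
              hidden = v$hidden_multiplier * msa$L,
              latent = v$latent_dim, lr = v$lr, l2 = v$l2,
              patience = v$patience, batch_size = v$batch_size,
              max_epochs = v$max_epochs, seed = v$seed)
  })
  enc <- run_stage("encode", vae_encode(vae, encode_onehot(msa)))
  map <- run_stage("lgl", {
    grid <- build_grid(enc, resolution = config$lgl$resolution,
                       margin = config$lgl$margin)
    labels <- attr(msa, "labels")
    overlay <- data.frame(id = names(msa$seqs), z0 = enc[, 1], z1 = enc[, 2],
                          label = if (is.null(labels)) NA else labels)
    score_map(vae, potts_bits$model, grid, overlay = overlay)
  })
  candidates <- NULL; reports <- NULL
  if (!is.null(config$candidates)) {
    candidates <- run_stage("candidates", {
      coords <- do.call(rbind, lapply(config$candidates, as.numeric))
      if (config$candidate_space == "fraction") {
        g <- map$grid
        coords <- cbind(g$z0_bounds[1] + coords[, 1] * diff(g$z0_bounds),
                        g$z1_bounds[1] + coords[, 2] * diff(g$z1_bounds))
      }
      decode_candidates(map, coords)
    })
    reports <- run_stage("report", {
      ref <- config$reference
      if (!is.null(ref)) {
        if (ref %in% names(msa$seqs)) ref <- msa$seqs[[ref]]
        else if (nchar(ref) != msa$L)
          stop("reference '", ref, "' is neither a curated record id nor ",
               "an aligned sequence of width ", msa$L, call. = FALSE)
      }
      lapply(seq_len(nrow(candidates)), function(k) {
        cand <- candidates$sequence[k]
        rep_k <- list(hamiltonian = candidates$hamiltonian[k],
                      novelty = novelty_check(cand, msa),
                      motifs = motif_check(cand, config$motifs))
        if (!is.null(ref))
          rep_k$mutations <- mutation_report(cand, ref, config$domains)
        rep_k
      })
    })
  }
  manifest <- NULL
  if (!is.null(out_dir)) {
    run_stage("artifacts", {
      write_msa(msa, file.path(out_dir, "curated.fasta"))
      utils::write.table(
        data.frame(id = names(msa$seqs), z0 = enc[, 1], z1 = enc[, 2]),
        file.path(out_dir, "encodings.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_di_tsv(potts_bits$di, file.path(out_dir, "di.tsv"))
      write_map_tsv(map, file.path(out_dir, "lgl_map.tsv"))
      if (!is.null(candidates)) {
        cand_msa <- new_msa(stats::setNames(candidates$sequence,
                                            sprintf("GS%d", seq_len(nrow(candidates)))),
                            alphabet = msa$alphabet)
        write_msa(cand_msa, file.path(out_dir, "candidates.fasta"))
      }
    })
    manifest <- write_manifest(out_dir, config,
                               list(seeds = list(vae = config$vae$seed,
                                                 curation = config$curation$seed)))
  }
  list(msa = msa, potts = potts_bits$model, di = potts_bits$di, vae = vae,
       encodings = enc, map = map, candidates = candidates,
       candidate_reports = reports, manifest = manifest)
}

#' Validate a trajectory-pipeline config
#'
#' @param config List or YAML path. Keys: \code{trials} (integer, synthetic
#'   runs) or explicit inputs (\code{e2pi_pdb}, \code{e1_pdb},
#'   \code{trajectory_xyz}, \code{selections}), plus \code{synthetic}
#'   (arguments of [make_two_state_trajectory()]), \code{trim_time},
#'   \code{bins}, \code{blocks}, \code{out_dir}, \code{seed}.
#' @return Validated config list.
#' @export
validate_traj_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, c("trials", "synthetic", "e2pi_pdb", "e1_pdb",
                       "trajectory_xyz", "trajectory_pdb", "selections",
                       "trim_time", "bins", "blocks", "out_dir", "seed"),
             "config")
  if (is.null(config$synthetic) &&
      (is.null(config$e2pi_pdb) || is.null(config$e1_pdb) ||
       (is.null(config$trajectory_xyz) && is.null(config$trajectory_pdb)) ||
       is.null(config$selections)))
    config_error("config needs either a synthetic spec or explicit ",
                 "e2pi_pdb/e1_pdb/trajectory_xyz/selections inputs")
  if (is.null(config$trials)) config$trials <- 1L
  if (is.null(config$trim_time)) config$trim_time <- 50
  if (is.null(config$bins)) config$bins <- 50
  if (is.null(config$seed)) config$seed <- 1L
  if (config$trim_time < 0) config_error("trim_time must be >= 0")
  config
}

analyze_trial <- function(traj, e2pi, e1, selections, trim_time, bins) {
  if (length(traj$frames) == 0) stop("empty trajectory", call. = FALSE)
  traj <- equilibration_trim(traj, trim_time)
  tm_idx <- sort(unique(unlist(selections$helices)))
  traj <- align_frames(traj, e2pi, tm_idx)
  motion <- motion_analysis(traj, e2pi, e1, selections, align = FALSE)
  dens <- score_density(motion$score, bins)
  rmsd <- rmsd_series(traj, e2pi, tm_idx)
  stat <- if (length(rmsd) >= 20) stationarity_test(rmsd)
          else list(statistic = NA, p_value = NA, stationary = NA,
                    degenerate = NA)
  peak <- which.max(motion$score)
  ddm_peak <- helix_ddm(traj$frames[[peak]], e2pi, selections$helices)
  inter <- interblock_summary(ddm_peak)
  list(motion = motion, density = dens, max_progress = dens$max_score,
       rmsd = rmsd, stationarity = stat, peak_frame = peak,
       ddm_at_peak = ddm_peak, interblock = inter,
       coupled_max_interblock = inter$max_interblock)
}

#' Run the trajectory-analysis pipeline
#'
#' For each trial: equilibration trim, TM alignment, per-frame tilt /
#' delta-distance / movement score, score density and maximum progress, RMSD
#' stationarity verdict, and the helix DDM plus interblock summary at the
#' frame of maximum progress (the "coupled" values).
#'
#' @param config Config list or YAML path; see [validate_traj_config()].
#' @return List of per-trial reports (fields \code{motion}, \code{density},
#'   \code{max_progress}, \code{stationarity}, \code{ddm_at_peak},
#'   \code{interblock}, \code{coupled_max_interblock}), with a
#'   \code{manifest} attribute when \code{out_dir} is set.
#' @export
run_traj <- function(config) {
  config <- validate_traj_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  reports <- vector("list", config$trials)
  for (trial in seq_len(config$trials)) {
    inputs <- run_stage("input", {
      if (!is.null(config$synthetic)) {
        args <- config$synthetic
        args$seed <- config$seed + trial - 1L
        sim <- do.call(make_two_state_trajectory, args)
        list(traj = sim$traj, e2pi = sim$e2pi, e1 = sim$e1,
             selections = sim$selections)
      } else {
        list(traj = if (!is.null(config$trajectory_xyz))
                      read_trajectory_xyz(config$trajectory_xyz)
                    else read_trajectory_pdb(config$trajectory_pdb),
             e2pi = read_structure_pdb(config$e2pi_pdb),
             e1 = read_structure_pdb(config$e1_pdb),
             selections = lapply(config$selections, function(g)
               if (is.list(g)) lapply(g, as.integer) else as.integer(g)))
      }
    })
    reports[[trial]] <- run_stage("analysis",
      analyze_trial(inputs$traj, inputs$e2pi, inputs$e1, inputs$selections,
                    config$trim_time, config$bins))
    if (!is.null(out_dir)) run_stage("artifacts", {
      pre <- file.path(out_dir, sprintf("trial%02d", trial))
      utils::write.table(reports[[trial]]$motion,
                         paste0(pre, "_motion.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_ddm_tsv(reports[[trial]]$ddm_at_peak, paste0(pre, "_ddm.tsv"))
      utils::write.table(reports[[trial]]$density$table,
                         paste0(pre, "_density.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }
  if (!is.null(out_dir))
    attr(reports, "manifest") <- write_manifest(out_dir, config,
                                                list(seed = config$seed))
  reports
}
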