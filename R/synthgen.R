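#' Seeded synthetic-data generators
#'
#' Every generator is a pure function of (seed, parameters): it saves and
#' restores the caller's RNG state, seeds a fixed generator kind, and
#' returns the dataset together with a `GroundTruth` record of every latent
#' parameter, so downstream recovery tests are sharp. Wherever a target
#' proportion must be achieved exactly (violator counts, cluster
#' occupancies, voxel occupancies) allocation is deterministic by count,
#' not sampled.
#'
#' Synthetic structures use a minimal poly-alanine-plus-lysine topology
#' sufficient for selections and RMSD bookkeeping; no stereochemical
#' realism is claimed.
#'
#' @name synthgen
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

ground_truth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed, params = list(...)),
            class = "GroundTruth")
}

#' Serialize a GroundTruth record to JSON
#' @param gt `GroundTruth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- synthetic structures ---------------------------------------------------

res_atoms_bb <- function(resno, origin, resname = "ALA", chain = "C",
                         with_cb = TRUE) {
  # local geometry: N, CA, C along x with small y zig-zag, O off C, CB up
  base <- rbind(N  = c(0.00,  0.30, 0),
                CA = c(1.46,  0.00, 0),
                C  = c(2.40,  1.10, 0),
                O  = c(2.10,  2.28, 0))
  if (with_cb && resname != "GLY") base <- rbind(base, CB = c(1.80, -0.80, 1.20))
  nm <- rownames(base)
  data.frame(chain = chain, resno = resno, icode = "", resname = resname,
             atom = nm, element = substr(nm, 1L, 1L),
             x = base[, 1L] + origin[1L], y = base[, 2L] + origin[2L],
             z = base[, 3L] + origin[3L], stringsAsFactors = FALSE)
}

#' Minimal synthetic peptide chain
#'
#' @param n_res residues (default 10, decamer).
#' @param chain chain id.
#' @param resno_start first author residue number.
#' @param origin xyz offset of the chain.
#' @param special named integer: positions (1-based within the chain)
#'   mapped to residue names, e.g. `c("7" = "LYS")`.
#' @return `StructureModel`.
#' @export
synth_peptide_model <- function(n_res = 10, chain = "C", resno_start = 181,
                                origin = c(0, 0, 0),
                                special = c("7" = "LYS")) {
  rows <- lapply(seq_len(n_res), function(i) {
    rn <- if (as.character(i) %in% names(special))
      special[[as.character(i)]] else "ALA"
    res_atoms_bb(resno_start + i - 1L, origin + c(3.5 * (i - 1L), 0, 0),
                 resname = rn, chain = chain)
  })
  structure_model(do.call(rbind, rows))
}

#' Minimal synthetic receptor stub
#'
#' A short groove-like chain placed parallel to the peptide axis.
#'
#' @param n_res residues.
#' @param chain chain id.
#' @param resno_start first residue number.
#' @param origin xyz offset.
#' @return `StructureModel`.
#' @export
synth_receptor_model <- function(n_res = 20, chain = "A", resno_start = 140,
                                 origin = c(0, 6, 0)) {
  synth_peptide_model(n_res, chain = chain, resno_start = resno_start,
                      origin = origin, special = c())
}

#' Synthetic receptor + peptide complex
#'
#' @inheritParams synth_peptide_model
#' @return `StructureModel` with receptor chain A (residues 140+) and
#'   peptide chain C (residues 181-190).
#' @export
synth_complex_model <- function(n_res = 10) {
  rec <- synth_receptor_model()
  pep <- synth_peptide_model(n_res)
  structure_model(rbind(rec$atoms, pep$atoms))
}

# ---- decoys -----------------------------------------------------------------

#' Generate a funnel-shaped docking decoy set with injected violations
#'
#' Peptide coordinates (all atoms except the residue-181 amide nitrogen,
#' which anchors the restraints) are perturbed from the reference with an
#' exact per-decoy RMSD drawn uniformly from `rmsd_range`; pseudo-energies
#' follow `E0 + slope * RMSD + N(0, energy_noise)` (an energy funnel).
#' Exactly `floor(n * violation_fraction)` decoys additionally displace the
#' anchor nitrogen by `violation_shift`, breaking the anchored restraints;
#' labels are recorded.
#'
#' @param seed integer seed.
#' @param n number of decoys (>= 10).
#' @param violation_fraction fraction in [0, 1].
#' @param funnel_slope REU per Angstrom (default 5).
#' @param rmsd_range uniform range of programmed peptide RMSDs (Angstrom).
#' @param energy_noise SD of the energy noise (REU).
#' @param violation_shift anchor displacement of violators (Angstrom).
#' @param reference optional reference `StructureModel` (defaults to
#'   [synth_complex_model()]).
#' @return list with `decoys` (`Ensemble`), `scores` (`DecoyScores`),
#'   `restraints` (`RestraintTable`), `reference` and `truth`
#'   (`GroundTruth` carrying `violator_tags`).
#' @export
gen_decoy_set <- function(seed, n = 100, violation_fraction = 0.37,
                          funnel_slope = 5, rmsd_range = c(0.2, 6),
                          energy_noise = 2, violation_shift = 5,
                          reference = NULL) {
  if (n < 10L) stop("n must be >= 10")
  if (violation_fraction < 0 || violation_fraction > 1)
    stop("violation_fraction must be in [0, 1]")
  if (is.null(reference)) reference <- synth_complex_model()
  pep_idx <- which(reference$atoms$chain == "C")
  anchor <- which(reference$atoms$chain == "C" &
                    reference$atoms$resno == 181L &
                    reference$atoms$atom == "N")
  stopifnot(length(anchor) == 1L)
  move_idx <- setdiff(pep_idx, anchor)
  n_viol <- floor(n * violation_fraction)
  with_seed(seed, {
    violators <- sort(sample.int(n, n_viol))
    rmsds <- stats::runif(n, rmsd_range[1L], rmsd_range[2L])
    energies <- -300 + funnel_slope * rmsds + stats::rnorm(n, 0, energy_noise)
    tags <- sprintf("decoy_%04d", seq_len(n))
    models <- vector("list", n)
    for (i in seq_len(n)) {
      m <- reference
      disp <- matrix(stats::rnorm(length(move_idx) * 3L), ncol = 3L)
      disp <- disp * rmsds[i] / sqrt(mean(rowSums(disp^2)))
      xyz <- coords(m)
      xyz[move_idx, ] <- xyz[move_idx, ] + disp
      if (i %in% violators)
        xyz[anchor, ] <- xyz[anchor, ] + c(0, -violation_shift, 0)
      m <- set_coords(m, xyz)
      m$model_id <- i
      models[[i]] <- m
    }
    # restraint anchored at the fixed peptide amide: satisfied exactly by
    # non-violators, broken by construction for violators
    rec_atom <- which(reference$atoms$chain == "A" &
                        reference$atoms$resno == 140L &
                        reference$atoms$atom == "CA")
    d_ref <- sqrt(sum((coords(reference)[anchor, ] -
                         coords(reference)[rec_atom, ])^2))
    rt <- structure(list(restraints = list(
      noe_restraint(atom_group("CA", 140L, "A"),
                    atom_group("N", 181L, "C"),
                    lower_bound = max(d_ref - 2, 0),
                    upper_bound = d_ref + 0.2, width = 0.5,
                    label = "anchor_noe")),
      provenance = "gen_decoy_set"), class = "RestraintTable")
    list(decoys = ensemble(models), scores = decoy_scores(tags, energies),
         restraints = rt, reference = reference,
         truth = ground_truth("gen_decoy_set", seed, n = n,
                              violation_fraction = violation_fraction,
                              n_violators = n_viol,
                              violator_tags = tags[violators],
                              funnel_slope = funnel_slope,
                              rmsd_range = rmsd_range,
                              programmed_rmsd = rmsds))
  })
}

# ---- trajectories -----------------------------------------------------------

exact_counts <- function(proportions, n) {
  cnt <- floor(proportions * n)
  rem <- n - sum(cnt)
  if (rem > 0L) {
    o <- order(proportions * n - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  cnt
}

#' Generate a two-stage (backbone + rotamer) switching trajectory
#'
#' Frames occupy programmed backbone states (rigid +y offsets of the
#' peptide backbone, `separation` apart) with exact per-state counts;
#' inside each backbone state, side-chain rotamer states offset the CB
#' atoms by `rot_separation` in +z, again with exact counts. Isotropic
#' Gaussian jitter of `thermal_sigma` is added to all peptide atoms. The
#' receptor is static, so frames share the common receptor frame.
#'
#' @param seed integer seed.
#' @param n_frames total frames.
#' @param backbone_states numeric proportions summing to 1 (e.g.
#'   `c(0.7, 0.3)`).
#' @param rotamer_states integer number of rotamer states per backbone
#'   state (recycled), with equal programmed proportions inside the parent.
#' @param thermal_sigma jitter SD in Angstrom.
#' @param separation backbone inter-state offset (Angstrom).
#' @param rot_separation CB rotamer offset (Angstrom).
#' @param replicate replicate id stored with the frames.
#' @return list with `frames` (`Ensemble`), `replicate`, and `truth`
#'   (state sequence and counts). A warning is issued when states are
#'   closer than 3x the jitter.
#' @export
gen_trajectory <- function(seed, n_frames = 100, backbone_states = c(0.7, 0.3),
                           rotamer_states = 1L, thermal_sigma = 0.1,
                           separation = 3, rot_separation = 3,
                           replicate = 1L) {
  if (abs(sum(backbone_states) - 1) > 1e-8)
    stop("backbone_states proportions must sum to 1")
  if (separation < 3 * thermal_sigma || rot_separation < 3 * thermal_sigma)
    warning("states closer than 3x jitter; clustering recovery not guaranteed")
  n_bb <- length(backbone_states)
  rotamer_states <- rep_len(as.integer(rotamer_states), n_bb)
  base <- synth_complex_model()
  pep_idx <- which(base$atoms$chain == "C")
  bb_idx <- which(base$atoms$chain == "C" &
                    base$atoms$atom %in% c("N", "CA", "C", "O"))
  cb_idx <- which(base$atoms$chain == "C" & base$atoms$atom == "CB")
  counts <- exact_counts(backbone_states, n_frames)
  with_seed(seed, {
    bb_seq <- rep(seq_len(n_bb), counts)
    rot_seq <- integer(n_frames)
    for (s in seq_len(n_bb)) {
      at <- which(bb_seq == s)
      rc <- exact_counts(rep(1 / rotamer_states[s], rotamer_states[s]),
                         length(at))
      rot_seq[at] <- rep(seq_len(rotamer_states[s]), rc)
    }
    perm <- sample.int(n_frames)
    bb_seq <- bb_seq[perm]
    rot_seq <- rot_seq[perm]
    models <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      xyz <- coords(base)
      xyz[bb_idx, 2L] <- xyz[bb_idx, 2L] + (bb_seq[f] - 1L) * separation
      xyz[cb_idx, 3L] <- xyz[cb_idx, 3L] + (rot_seq[f] - 1L) * rot_separation
      xyz[pep_idx, ] <- xyz[pep_idx, ] +
        matrix(stats::rnorm(length(pep_idx) * 3L, 0, thermal_sigma),
               ncol = 3L)
      m <- set_coords(base, xyz)
      m$model_id <- f
      models[[f]] <- m
    }
    list(frames = ensemble(models), replicate = replicate,
         truth = ground_truth("gen_trajectory", seed, n_frames = n_frames,
                              backbone_states = backbone_states,
                              rotamer_states = rotamer_states,
                              thermal_sigma = thermal_sigma,
                              separation = separation,
                              rot_separation = rot_separation,
                              backbone_sequence = bb_seq,
                              rotamer_sequence = rot_seq,
                              backbone_counts = counts))
  })
}

# ---- HDX --------------------------------------------------------------------

#' Generate an HDX fragment dataset with a protected span
#'
#' Per-residue uptake follows `u_i(t) = D_frac * (1 - exp(-k_i t))` with a
#' uniform intrinsic rate `k_exposed` slowed by `protection_factor` inside
#' `protected_span`. Fragment centroids are
#' `m_t = m0 + sum_i u_i(t) * dm_D + noise`; the all-H reference is `m0`
#' and the all-D reference `m100 = m0 + n_res * dm_D` (full deuteration),
#' so span-corrected uptake saturates at `100 * D_frac` and d-scaled
#' uptake at 100%.
#'
#' @param seed integer seed.
#' @param protein_length residues (default 30).
#' @param fragments data.frame with `start`, `end` spans tiling the protein
#'   (default: overlapping 10-mers every 5 residues).
#' @param k_exposed exchange rate of exposed residues (1/s, default 0.02).
#' @param protected_span integer range of protected residues (default
#'   11:20).
#' @param protection_factor rate reduction inside the span (default 100).
#' @param D_frac solvent deuterium fraction (default 0.8).
#' @param timepoints labeling times in seconds.
#' @param replicates replicate count (default 3).
#' @param noise_sd centroid-mass noise SD in Da (default 0.02).
#' @return list with `fragments` (list of `HdxFragmentSeries`), `config`
#'   (`HdxConfig`) and `truth` (per-residue rates).
#' @export
gen_hdx_dataset <- function(seed, protein_length = 30, fragments = NULL,
                            k_exposed = 0.02, protected_span = 11:20,
                            protection_factor = 100, D_frac = 0.8,
                            timepoints = c(0, 20, 60, 180, 600),
                            replicates = 3, noise_sd = 0.02) {
  if (is.null(fragments)) {
    starts <- seq(1L, protein_length - 9L, by = 5L)
    fragments <- data.frame(start = starts,
                            end = pmin(starts + 9L, protein_length))
  }
  if (nrow(fragments) == 0L) stop("empty fragment tiling")
  dm_d <- 1.00628
  k <- rep(k_exposed, protein_length)
  k[protected_span] <- k_exposed / protection_factor
  with_seed(seed, {
    frs <- lapply(seq_len(nrow(fragments)), function(i) {
      s <- fragments$start[i]
      e <- fragments$end[i]
      n_res <- e - s + 1L
      m0 <- 110 * n_res + stats::runif(1, -5, 5)
      m100 <- m0 + n_res * dm_d
      obs <- do.call(rbind, lapply(timepoints, function(tt) {
        u <- D_frac * (1 - exp(-k[s:e] * tt))
        data.frame(time_s = tt, replicate = seq_len(replicates),
                   m_t = m0 + sum(u) * dm_d +
                     if (tt == 0) 0 else stats::rnorm(replicates, 0, noise_sd))
      }))
      hdx_fragment("synthetic", s, e, strrep("A", n_res), m0, m100, obs)
    })
    list(fragments = frs,
         config = hdx_config(D_frac = D_frac, timepoints = timepoints),
         truth = ground_truth("gen_hdx_dataset", seed,
                              protein_length = protein_length,
                              k_per_residue = k,
                              protected_span = range(protected_span),
                              protection_factor = protection_factor,
                              D_frac = D_frac, noise_sd = noise_sd))
  })
}

# ---- NMR peaks, decays, melts, competition ----------------------------------

#' Generate two-state methyl peak lists with programmed outliers
#'
#' Background probes carry tiny shift differences (`noise_H`, `noise_C`)
#' and intensity ratios near 1; programmed CSP outliers receive
#' `outlier_dH`/`outlier_dC`, programmed broadened probes a ratio of
#' `broadened_ratio`. The outlier and broadened sets must be disjoint.
#'
#' @param seed integer seed.
#' @param n_probes number of methyl probes.
#' @param outlier_idx indices of programmed CSP outliers.
#' @param broadened_idx indices of programmed broadened probes.
#' @param outlier_dH,outlier_dC programmed shift changes (ppm).
#' @param broadened_ratio programmed intensity ratio of broadened probes.
#' @param noise_H,noise_C background shift noise SD (ppm); zero gives the
#'   exact-recovery regime.
#' @return list with `free`, `bound` (data.frames of peaks), `records`
#'   (CSP/ratio table via [methyl_csp()]) and `truth`.
#' @export
gen_two_state_peaks <- function(seed, n_probes = 20, outlier_idx = c(3, 11),
                                broadened_idx = c(7), outlier_dH = 0.2,
                                outlier_dC = 0.5, broadened_ratio = 0.2,
                                noise_H = 0, noise_C = 0) {
  if (length(intersect(outlier_idx, broadened_idx)) > 0L)
    stop("outlier and broadened sets must be disjoint")
  with_seed(seed, {
    probes <- sprintf("M%02d", seq_len(n_probes))
    free <- data.frame(probe = probes,
                       delta_H = stats::runif(n_probes, 0.2, 1.4),
                       delta_C = stats::runif(n_probes, 15, 25),
                       intensity = stats::runif(n_probes, 0.8, 1.2),
                       stringsAsFactors = FALSE)
    bound <- free
    bound$delta_H <- bound$delta_H + stats::rnorm(n_probes, 0, noise_H)
    bound$delta_C <- bound$delta_C + stats::rnorm(n_probes, 0, noise_C)
    bound$delta_H[outlier_idx] <- bound$delta_H[outlier_idx] + outlier_dH
    bound$delta_C[outlier_idx] <- bound$delta_C[outlier_idx] + outlier_dC
    ratio <- rep(1, n_probes)
    ratio[broadened_idx] <- broadened_ratio
    bound$intensity <- free$intensity / ratio
    records <- data.frame(
      probe = probes,
      csp = vapply(seq_len(n_probes), function(i)
        methyl_csp(free[i, ], bound[i, ]), numeric(1)),
      intensity_ratio = free$intensity / bound$intensity,
      stringsAsFactors = FALSE)
    list(free = free, bound = bound, records = records,
         truth = ground_truth("gen_two_state_peaks", seed,
                              outlier_idx = outlier_idx,
                              broadened_idx = broadened_idx,
                              outlier_dH = outlier_dH,
                              outlier_dC = outlier_dC,
                              broadened_ratio = broadened_ratio))
  })
}

#' Generate a single-phase intensity decay series
#'
#' @param seed integer seed.
#' @param t_half half-life in hours (default 3.7).
#' @param times sampling times (default 1-hour increments over 9 h).
#' @param I0,plateau amplitudes.
#' @param noise relative noise SD (fraction of the decaying amplitude).
#' @return list with `times`, `intensities`, `truth`.
#' @export
gen_decay <- function(seed, t_half = 3.7, times = 0:9, I0 = 1,
                      plateau = 0.2, noise = 0) {
  k <- log(2) / t_half
  with_seed(seed, {
    clean <- plateau + (I0 - plateau) * exp(-k * times)
    obs <- clean + stats::rnorm(length(times), 0, noise * (I0 - plateau))
    list(times = times, intensities = obs,
         truth = ground_truth("gen_decay", seed, t_half = t_half, k = k,
                              I0 = I0, plateau = plateau, noise = noise))
  })
}

#' Generate a Boltzmann thermal melt curve
#'
#' @param seed integer seed.
#' @param T_m midpoint (deg C, default 53).
#' @param slope transition width (deg C, default 2.5).
#' @param t_range scanned temperatures (default 25-95 deg C in 1-degree
#'   steps, the conventional scan).
#' @param F_min,F_max asymptotes.
#' @param noise absolute noise SD in fluorescence units.
#' @return list with `temperatures`, `fluorescence`, `truth`.
#' @export
gen_melt <- function(seed, T_m = 53, slope = 2.5, t_range = seq(25, 95, 1),
                     F_min = 0.1, F_max = 1, noise = 0) {
  with_seed(seed, {
    clean <- F_min + (F_max - F_min) / (1 + exp((T_m - t_range) / slope))
    obs <- clean + stats::rnorm(length(t_range), 0, noise)
    list(temperatures = t_range, fluorescence = obs,
         truth = ground_truth("gen_melt", seed, T_m = T_m, slope = slope,
                              F_min = F_min, F_max = F_max, noise = noise))
  })
}

#' Generate a competitive-anisotropy displacement series
#'
#' The competitor Kd is solved numerically so the forward model's
#' half-displacement concentration equals the requested IC50 exactly; data
#' are generated on the stated concentration grid in replicate with
#' relative noise on the anisotropy change.
#'
#' @param seed integer seed.
#' @param ic50 target IC50 (same unit as the grid; default 0.26 uM =
#'   260 nM).
#' @param concentrations competitor grid (default 0, 0.25, 4, 25 uM).
#' @param replicates replicate count (default 3).
#' @param noise relative noise SD on the anisotropy change (default 0).
#' @param R_tot,L_tot,Kd_L assay constants (uM): receptor available for
#'   exchange, tracer concentration (25 nM) and tracer Kd.
#' @param r_max,r_min anisotropy asymptotes.
#' @return list with `concentrations`, `anisotropy` (replicate-expanded),
#'   `constants`, `truth`.
#' @export
gen_competition <- function(seed, ic50 = 0.26,
                            concentrations = c(0, 0.25, 4, 25),
                            replicates = 3, noise = 0,
                            R_tot = 0.2, L_tot = 0.025, Kd_L = 0.26,
                            r_max = 0.25, r_min = 0.05) {
  kd_c <- kd_from_ic50(ic50, R_tot, L_tot, Kd_L)
  with_seed(seed, {
    cc <- rep(concentrations, each = replicates)
    clean <- vapply(cc, aniso_at, numeric(1), R_tot = R_tot, L_tot = L_tot,
                    Kd_L = Kd_L, Kd_C = kd_c, r_min = r_min, r_max = r_max)
    obs <- clean + stats::rnorm(length(cc), 0, noise * (r_max - r_min))
    list(concentrations = cc, anisotropy = obs,
         constants = list(R_tot = R_tot, L_tot = L_tot, Kd_L = Kd_L),
         truth = ground_truth("gen_competition", seed, ic50 = ic50,
                              Kd_C = kd_c, r_max = r_max, r_min = r_min,
                              noise = noise))
  })
}

# ---- waters -----------------------------------------------------------------

#' Generate water frames realizing exact voxel occupancies
#'
#' Each programmed site is a water position near the receptor's
#' residue-150-155 stretch; the water is present (at its site) in exactly
#' `round(occupancy * n_frames)` frames (deterministic allocation over a
#' seeded frame permutation) and parked far outside the analysis region
#' otherwise. When `round()` cannot realize a target exactly the nearest
#' achievable count is used and reported in the truth record.
#'
#' @param seed integer seed.
#' @param occupancies numeric targets in [0, 1], one per water site.
#' @param n_frames frame count.
#' @return list with `frames` (`Ensemble` retaining solvent), `sites`
#'   (site coordinates), `near` (the `AtomSelection` used for analysis)
#'   and `truth` (achieved occupancies).
#' @export
gen_waters <- function(seed, occupancies = c(1, 0.5, 0.25), n_frames = 20) {
  if (any(occupancies < 0 | occupancies > 1))
    stop("occupancies must lie in [0, 1]")
  rec <- synth_receptor_model(n_res = 20, chain = "A", resno_start = 140)
  near <- atom_select(chain = "A", resno = 150:155)
  near_xyz <- coords(rec, select_atoms(rec, near))
  anchor <- colMeans(near_xyz)
  n_w <- length(occupancies)
  sites <- t(vapply(seq_len(n_w), function(i)
    anchor + c(2.5 * (i - 1), -3.5, 2.0), numeric(3)))
  park <- matrix(rep(anchor, each = n_w), ncol = 3L) +
    cbind(200 + 10 * seq_len(n_w), 200, 200)
  counts <- round(occupancies * n_frames)
  achieved <- counts / n_frames
  with_seed(seed, {
    present <- lapply(counts, function(k) sort(sample.int(n_frames)[seq_len(k)]))
    models <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      wat <- do.call(rbind, lapply(seq_len(n_w), function(i) {
        p <- if (f %in% present[[i]]) sites[i, ] else park[i, ]
        data.frame(chain = "W", resno = 900L + i, icode = "",
                   resname = "HOH", atom = "O", element = "O",
                   x = p[1L], y = p[2L], z = p[3L],
                   stringsAsFactors = FALSE)
      }))
      m <- structure_model(rbind(rec$atoms, wat), model_id = f)
      models[[f]] <- m
    }
    list(frames = ensemble(models), sites = sites, near = near,
         truth = ground_truth("gen_waters", seed,
                              target_occupancies = occupancies,
                              achieved_occupancies = achieved,
                              n_frames = n_frames))
  })
}
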