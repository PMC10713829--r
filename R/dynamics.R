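#' Equally-spaced frame subsampling
#'
#' Deterministic indices `round(i*(N-1)/(n-1)) + 1` for `i = 0..n-1`; the
#' first and last frames are always included.
#'
#' @param e `Ensemble` of trajectory frames.
#' @param n number of frames to keep (`2 <= n <= length(e)`).
#' @return subsampled `Ensemble`.
#' @export
subsample_frames <- function(e, n) {
  stopifnot(inherits(e, "Ensemble"))
  big_n <- length(e$models)
  if (n > big_n) stop("n (", n, ") exceeds frame count (", big_n, ")")
  if (n < 2L) stop("n must be >= 2")
  idx <- round((seq_len(n) - 1L) * (big_n - 1L) / (n - 1L)) + 1L
  ensemble(e$models[idx], shared_topology = e$shared_topology)
}

#' Replicate-averaged RMSF
#'
#' The per-atom RMSF is computed for each replicate ensemble independently
#' (via [per_atom_rmsf()]) and averaged arithmetically across replicates.
#'
#' @param replicates list of `Ensemble`s with identical topology.
#' @param fit,report selections passed to [per_atom_rmsf()].
#' @return `FluctProfile` with the replicate-mean `rmsf` column.
#' @export
averaged_rmsf <- function(replicates, fit = NULL, report = NULL) {
  stopifnot(length(replicates) >= 1L)
  profs <- lapply(replicates, per_atom_rmsf, fit = fit, report = report)
  ref <- profs[[1L]]
  for (p in profs[-1L]) {
    if (nrow(p) != nrow(ref) ||
        !all(paste(p$chain, p$resno, p$atom) ==
               paste(ref$chain, ref$resno, ref$atom)))
      stop("replicate topology mismatch")
  }
  ref$rmsf <- Reduce(`+`, lapply(profs, function(p) p$rmsf)) / length(profs)
  ref
}

#' Circular dihedral order parameter S2
#'
#' `S2 = <cos theta>^2 + <sin theta>^2`, the squared length of the mean
#' resultant vector of the angle series: 1 for a rigid (constant) angle,
#' 0 for angles cancelling around the circle. Missing values are skipped
#' and counted.
#'
#' @param series `DihedralSeries` (or a numeric vector of degrees).
#' @return object of class `OrderParameter`: list with `S2` in [0, 1],
#'   `n_frames` used and `n_missing`.
#' @export
dihedral_s2 <- function(series) {
  values <- if (inherits(series, "DihedralSeries")) series$values else series
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need >= 2 defined angles")
  th <- values[ok] * pi / 180
  s2 <- mean(cos(th))^2 + mean(sin(th))^2
  s2 <- min(max(s2, 0), 1)
  structure(list(
    chain = if (inherits(series, "DihedralSeries")) series$chain else NA,
    resno = if (inherits(series, "DihedralSeries")) series$resno else NA,
    angle = if (inherits(series, "DihedralSeries")) series$angle else NA,
    S2 = s2, n_frames = sum(ok), n_missing = sum(!ok)),
    class = "OrderParameter")
}

#' Order parameters for every residue of a chain
#'
#' @param e shared-topology `Ensemble` of frames.
#' @param chain chain id.
#' @param angles subset of phi/psi/chi1.
#' @return data.frame (`resno`, `angle`, `S2`, `n_frames`).
#' @export
chain_s2 <- function(e, chain, angles = c("phi", "psi")) {
  per_frame <- lapply(e$models, backbone_dihedrals, chain = chain,
                      angles = angles)
  resnos <- per_frame[[1L]]$resno
  rows <- list()
  for (ang in angles) {
    vals <- vapply(per_frame, function(d) d[[ang]], numeric(length(resnos)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    for (i in seq_along(resnos)) {
      v <- vals[i, ]
      if (sum(!is.na(v)) < 2L) next
      op <- dihedral_s2(v)
      rows[[length(rows) + 1L]] <- data.frame(
        resno = resnos[i], angle = ang, S2 = op$S2,
        n_frames = op$n_frames)
    }
  }
  do.call(rbind, rows)
}

frame_rmsd_matrix <- function(models, sel = NULL, fit = NULL) {
  n <- length(models)
  idx <- select_atoms(models[[1L]], sel)
  if (length(idx) == 0L) stop("empty clustering selection")
  if (is.null(fit)) {
    xs <- lapply(models, coords, idx = idx)
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
      dm[i, j] <- dm[j, i] <- rmsd_xyz(xs[[i]], xs[[j]])
    dm
  } else {
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      mi <- apply_transform(models[[i]],
                            superpose(models[[i]], models[[j]], fit))
      dm[i, j] <- dm[j, i] <- rmsd_xyz(coords(mi, idx),
                                       coords(models[[j]], idx))
    }
    dm
  }
}

single_linkage_clusters <- function(dm, cutoff) {
  n <- nrow(dm)
  if (n == 1L) return(list(1L))
  hc <- stats::hclust(stats::as.dist(dm), method = "single")
  # merges strictly above the cutoff are undone
  labels <- stats::cutree(hc, h = cutoff)
  lapply(unique(labels), function(l) unname(which(labels == l)))
}

#' Single-linkage backbone clustering of trajectory frames
#'
#' Frames are assumed pre-aligned to a common receptor frame (the default;
#' pass `fit` for per-pair superposition on the clustering selection).
#' Single-linkage agglomeration with merge threshold `cutoff` over the
#' pairwise RMSD of `sel`; clusters are reported by descending occupancy
#' (members / total frames x 100). The representative frame is the cluster
#' medoid (minimum summed RMSD to co-members).
#'
#' @param fe shared-topology `Ensemble` of frames.
#' @param cutoff merge threshold in Angstrom (default 0.5).
#' @param sel clustering selection (e.g. peptide backbone-no-O).
#' @param fit optional per-pair fit selection (self-fit mode).
#' @param total_frames denominator for occupancies (defaults to
#'   `length(fe)`; pass the grand total when clustering a subset).
#' @return list of `ClusterAssignment`s: each a list with `level`,
#'   `members` (frame indices), `occupancy` (percent of `total_frames`),
#'   `representative` (frame index) and `size`.
#' @export
backbone_cluster <- function(fe, cutoff = 0.5, sel = NULL, fit = NULL,
                             total_frames = NULL) {
  stopifnot(inherits(fe, "Ensemble"))
  if (is.null(total_frames)) total_frames <- length(fe$models)
  dm <- frame_rmsd_matrix(fe$models, sel = sel, fit = fit)
  cls <- single_linkage_clusters(dm, cutoff)
  out <- lapply(cls, function(members) {
    rep_i <- if (length(members) == 1L) members else
      members[which.min(rowSums(dm[members, members, drop = FALSE]))]
    list(level = "backbone", members = members,
         occupancy = 100 * length(members) / total_frames,
         representative = rep_i, size = length(members))
  })
  out[order(vapply(out, function(cl) -cl$occupancy, numeric(1)))]
}

#' Side-chain sub-clustering within a backbone cluster
#'
#' Re-runs single-linkage clustering restricted to a parent cluster's
#' frames, over a heavy-atom selection and a wider cutoff; occupancies
#' remain relative to the grand total, so subcluster occupancies sum to the
#' parent's.
#'
#' @param parent a `ClusterAssignment` from [backbone_cluster()].
#' @param fe the full frame `Ensemble` the parent indexes into.
#' @param cutoff merge threshold in Angstrom (default 1.0).
#' @param sel heavy-atom selection (e.g. peptide all-heavy).
#' @param fit optional per-pair fit selection.
#' @param total_frames occupancy denominator (defaults to `length(fe)`).
#' @return list of `ClusterAssignment`s with `level = "sidechain"`,
#'   `members` as frame indices into `fe`, and `parent` recorded.
#' @export
sidechain_subcluster <- function(parent, fe, cutoff = 1.0, sel = NULL,
                                 fit = NULL, total_frames = NULL) {
  if (length(parent$members) < 1L) stop("empty parent cluster")
  if (is.null(total_frames)) total_frames <- length(fe$models)
  sub <- ensemble(fe$models[parent$members],
                  shared_topology = fe$shared_topology)
  if (length(sub$models) == 1L) {
    return(list(list(level = "sidechain", members = parent$members,
                     occupancy = 100 / total_frames,
                     representative = parent$members, size = 1L,
                     parent = parent$representative)))
  }
  dm <- frame_rmsd_matrix(sub$models, sel = sel, fit = fit)
  cls <- single_linkage_clusters(dm, cutoff)
  out <- lapply(cls, function(members) {
    rep_i <- if (length(members) == 1L) members else
      members[which.min(rowSums(dm[members, members, drop = FALSE]))]
    list(level = "sidechain", members = parent$members[members],
         occupancy = 100 * length(members) / total_frames,
         representative = parent$members[rep_i], size = length(members),
         parent = parent$representative)
  })
  out[order(vapply(out, function(cl) -cl$occupancy, numeric(1)))]
}

#' Cluster table for reporting
#' @param clusters list from [backbone_cluster()] / [sidechain_subcluster()].
#' @return data.frame (`level`, `cluster`, `size`, `occupancy`,
#'   `representative`).
#' @export
cluster_table <- function(clusters) {
  data.frame(
    level = vapply(clusters, function(cl) cl$level, character(1)),
    cluster = seq_along(clusters),
    size = vapply(clusters, function(cl) cl$size, integer(1)),
    occupancy = vapply(clusters, function(cl) cl$occupancy, numeric(1)),
    representative = vapply(clusters, function(cl) cl$representative,
                            integer(1)),
    stringsAsFactors = FALSE
  )
}
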