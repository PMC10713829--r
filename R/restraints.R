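#' NOE distance restraints
#'
#' Restraints carry two atom groups (ambiguous members, e.g. the protons of
#' a methyl group), flat-bottom lower/upper bounds in Angstrom and a width
#' (the BOUNDED padding column). Effective distances over groups use
#' r^-6 summation, the standard treatment for ambiguous NOEs.
#'
#' @name restraints
NULL

# NMR pseudo-atom expansions. Names follow common methyl/aromatic
# pseudo-atom conventions; expansion is by atom-name template, with the
# residue type disambiguating where needed (handled at resolution time by
# matching whichever template atoms exist in the model).
PSEUDO_ATOMS <- list(
  MB  = c("HB1", "HB2", "HB3"),                  # Ala beta methyl
  MG  = c("HG1", "HG2", "HG3"),
  MG1 = c("HG11", "HG12", "HG13"),
  MG2 = c("HG21", "HG22", "HG23"),
  MD  = c("HD1", "HD2", "HD3"),
  MD1 = c("HD11", "HD12", "HD13"),
  MD2 = c("HD21", "HD22", "HD23"),
  ME  = c("HE1", "HE2", "HE3"),
  QB  = c("HB1", "HB2", "HB3"),
  QG  = c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23"),
  QD  = c("HD1", "HD2", "HD11", "HD12", "HD13", "HD21", "HD22", "HD23"),
  QE  = c("HE1", "HE2", "HE21", "HE22"),
  QQD = c("HD11", "HD12", "HD13", "HD21", "HD22", "HD23"),
  QQG = c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23")
)

#' Construct a single NOE restraint
#'
#' @param group_a,group_b data.frames with columns `chain` (may be `NA` for
#'   "any chain"), `resno`, `atom`.
#' @param lower_bound,upper_bound flat-bottom bounds in Angstrom.
#' @param width BOUNDED padding column in Angstrom.
#' @param label unique restraint label.
#' @return object of class `NoeRestraint`.
#' @export
noe_restraint <- function(group_a, group_b, lower_bound, upper_bound,
                          width = 0.5, label = "noe") {
  stopifnot(nrow(group_a) >= 1L, nrow(group_b) >= 1L)
  if (!(lower_bound >= 0 && lower_bound <= upper_bound))
    stop("require 0 <= lower_bound <= upper_bound (got ", lower_bound,
         ", ", upper_bound, ")")
  structure(list(group_a = group_a, group_b = group_b,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 width = width, label = label),
            class = "NoeRestraint")
}

atom_group <- function(atom, resno, chain = NA_character_) {
  if (atom %in% names(PSEUDO_ATOMS)) atom <- PSEUDO_ATOMS[[atom]]
  data.frame(chain = chain, resno = as.integer(resno), atom = atom,
             stringsAsFactors = FALSE)
}

#' Read a restraint table (AtomPair/BOUNDED dialect)
#'
#' One restraint per line:
#' `AtomPair <atom1> <res1> <atom2> <res2> BOUNDED <lb> <ub> <sd> [tag]`.
#' Atoms may carry an explicit chain as `A:CD1`; bare residue numbers are
#' matched across all chains of the model (author numbering). Methyl and
#' aromatic pseudo-atoms (`MD1`, `QD`, ...) are expanded to their proton
#' groups; group members absent from a model are dropped at resolution time
#' (at least one must resolve). Blank lines and `#` comments are ignored.
#'
#' @param path restraint file.
#' @return object of class `RestraintTable` (list of `NoeRestraint` plus a
#'   provenance note).
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  restraints <- list()
  labels <- character()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    if (trimws(raw) == "") next
    tok <- strsplit(trimws(raw), "[[:space:]]+")[[1L]]
    if (length(tok) < 9L || tok[1L] != "AtomPair" || tok[6L] != "BOUNDED")
      stop("malformed restraint at line ", ln, ": '", trimws(lines[ln]), "'")
    parse_atom <- function(x) {
      if (grepl(":", x, fixed = TRUE)) {
        p <- strsplit(x, ":", fixed = TRUE)[[1L]]
        list(chain = p[1L], atom = p[2L])
      } else list(chain = NA_character_, atom = x)
    }
    a1 <- parse_atom(tok[2L])
    a2 <- parse_atom(tok[4L])
    known <- function(nm) grepl("^[A-Z0-9']+$", nm)
    if (!known(a1$atom) || !known(a2$atom))
      stop("unparseable atom name at line ", ln)
    nums <- suppressWarnings(as.numeric(tok[c(3L, 5L, 7L, 8L, 9L)]))
    if (any(is.na(nums)))
      stop("malformed numeric field at line ", ln, ": '",
           trimws(lines[ln]), "'")
    label <- if (length(tok) >= 10L) tok[10L] else paste0("noe", length(restraints) + 1L)
    if (label %in% labels)
      stop("duplicate restraint label '", label, "' at line ", ln)
    labels <- c(labels, label)
    restraints[[length(restraints) + 1L]] <- noe_restraint(
      atom_group(a1$atom, nums[1L], a1$chain),
      atom_group(a2$atom, nums[2L], a2$chain),
      lower_bound = nums[3L], upper_bound = nums[4L], width = nums[5L],
      label = label
    )
  }
  structure(list(restraints = restraints,
                 provenance = paste0("read from ", path)),
            class = "RestraintTable")
}

#' @export
length.RestraintTable <- function(x) length(x$restraints)

#' Write a restraint table in the AtomPair/BOUNDED dialect
#' @param t `RestraintTable`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(t, path) {
  fmt_atom <- function(g) {
    # collapse proton groups back to their pseudo-atom when possible
    for (nm in names(PSEUDO_ATOMS))
      if (setequal(g$atom, PSEUDO_ATOMS[[nm]])) {
        at <- nm
        if (!is.na(g$chain[1L])) at <- paste0(g$chain[1L], ":", at)
        return(at)
      }
    at <- g$atom[1L]
    if (!is.na(g$chain[1L])) at <- paste0(g$chain[1L], ":", at)
    at
  }
  lines <- vapply(t$restraints, function(r)
    sprintf("AtomPair %s %d %s %d BOUNDED %.2f %.2f %.2f %s",
            fmt_atom(r$group_a), r$group_a$resno[1L],
            fmt_atom(r$group_b), r$group_b$resno[1L],
            r$lower_bound, r$upper_bound, r$width, r$label),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

resolve_group <- function(m, g, label) {
  idx <- integer()
  for (k in seq_len(nrow(g))) {
    keep <- m$atoms$atom == g$atom[k] & m$atoms$resno == g$resno[k]
    if (!is.na(g$chain[k])) keep <- keep & m$atoms$chain == g$chain[k]
    idx <- c(idx, which(keep))
  }
  idx <- unique(idx)
  if (length(idx) == 0L)
    stop("restraint '", label, "': no atom of group (",
         paste(unique(g$atom), collapse = "/"), " res ", g$resno[1L],
         ") resolvable in model")
  idx
}

#' Effective (ambiguous) distance of a restraint in a model
#'
#' `d_eff = (sum_ab d_ab^-6)^(-1/6)` over all cross-group atom pairs;
#' reduces to the plain distance for 1x1 groups and never exceeds the
#' minimum pairwise distance. `method = "min"` returns the group minimum
#' instead.
#'
#' @param m `StructureModel`.
#' @param r `NoeRestraint`.
#' @param method `"r6"` (default) or `"min"`.
#' @return distance in Angstrom.
#' @export
effective_distance <- function(m, r, method = c("r6", "min")) {
  method <- match.arg(method)
  ia <- resolve_group(m, r$group_a, r$label)
  ib <- resolve_group(m, r$group_b, r$label)
  xa <- coords(m, ia)
  xb <- coords(m, ib)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d <- sqrt(pmax(d2, 0))
  if (method == "min") min(d) else sum(d^(-6))^(-1 / 6)
}

#' Evaluate restraint violations over a model or ensemble
#'
#' A restraint is violated iff `d_eff > upper_bound + tolerance` or
#' `d_eff < lower_bound - tolerance`; the excess beyond the padded bound is
#' recorded (positive iff violated).
#'
#' @param x `StructureModel` or `Ensemble`.
#' @param t `RestraintTable`.
#' @param tolerance padding in Angstrom added to both bounds (default 0.5,
#'   the conventional BOUNDED width).
#' @param method distance averaging passed to [effective_distance()].
#' @return for a model: a `ViolationReport` data.frame (one row per
#'   restraint: `label`, `d_eff`, `lower`, `upper`, `excess`, `violated`);
#'   for an ensemble: a list of reports, one per model.
#' @export
evaluate_violations <- function(x, t, tolerance = 0.5,
                                method = c("r6", "min")) {
  method <- match.arg(method)
  if (inherits(x, "Ensemble"))
    return(lapply(x$models, evaluate_violations, t = t,
                  tolerance = tolerance, method = method))
  stopifnot(inherits(x, "StructureModel"), inherits(t, "RestraintTable"))
  rows <- lapply(t$restraints, function(r) {
    d <- effective_distance(x, r, method)
    up_ex <- d - (r$upper_bound + tolerance)
    lo_ex <- (r$lower_bound - tolerance) - d
    excess <- max(up_ex, lo_ex, 0)
    data.frame(label = r$label, d_eff = d, lower = r$lower_bound,
               upper = r$upper_bound, excess = excess,
               violated = up_ex > 0 || lo_ex > 0,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("ViolationReport", "data.frame")
  rep
}

#' Decoy score table
#'
#' @param tag character decoy tags (unique).
#' @param total_energy numeric Rosetta energy units (finite).
#' @param source optional source path per decoy.
#' @return object of class `DecoyScores` (data.frame).
#' @export
decoy_scores <- function(tag, total_energy, source = NA_character_) {
  if (anyDuplicated(tag)) stop("duplicate decoy tags")
  if (!all(is.finite(total_energy))) stop("non-finite energies")
  d <- data.frame(tag = as.character(tag), total_energy = total_energy,
                  source = source, stringsAsFactors = FALSE)
  class(d) <- c("DecoyScores", "data.frame")
  d
}

#' Read a whitespace-delimited docking score table
#'
#' The header line must name a tag column (`description` or `tag`) and a
#' total-score column (`total_score`, `total_energy` or `score`).
#'
#' @param path score file.
#' @return `DecoyScores`.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  tag_col <- intersect(c("description", "tag"), names(tab))[1L]
  sc_col <- intersect(c("total_score", "total_energy", "score"),
                      names(tab))[1L]
  if (is.na(tag_col) || is.na(sc_col))
    stop("score table must name a tag column (description/tag) and a ",
         "total-score column (total_score/total_energy/score)")
  decoy_scores(tab[[tag_col]], tab[[sc_col]], source = path)
}

#' Filter decoys by restraint violations and sort by energy
#'
#' Decoys with at least one violated restraint are removed; survivors are
#' returned sorted ascending by total energy (ties keep input order).
#' The operation never increases the decoy count and is idempotent.
#'
#' @param scores `DecoyScores`.
#' @param reports named list of `ViolationReport`s, one per decoy tag (as
#'   from [evaluate_violations()] on the decoy ensemble, named by tag).
#' @return filtered, sorted `DecoyScores`.
#' @export
filter_decoys <- function(scores, reports) {
  stopifnot(inherits(scores, "DecoyScores"))
  missing_tags <- setdiff(scores$tag, names(reports))
  if (length(missing_tags) > 0L)
    stop("missing violation report for decoy(s): ",
         paste(utils::head(missing_tags, 5L), collapse = ", "))
  ok <- vapply(scores$tag, function(tg) !any(reports[[tg]]$violated),
               logical(1))
  out <- scores[ok, , drop = FALSE]
  out <- out[order(out$total_energy), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("DecoyScores", "data.frame")
  out
}

#' Energy-vs-RMSD landscape to the lowest-energy decoy
#'
#' The reference is the minimum-energy decoy (ties broken by tag order,
#' with a message); every decoy contributes one point (the reference at
#' RMSD 0).
#'
#' @param scores `DecoyScores` covering every decoy.
#' @param decoys `Ensemble` with shared topology, ordered as `scores`.
#' @param sel report selection for the RMSD (e.g. peptide backbone).
#' @param fit optional fit selection; when `NULL` coordinates are assumed
#'   already in a common frame (no per-pair fit).
#' @return data.frame (`tag`, `rms`, `energy`), input order.
#' @export
energy_landscape <- function(scores, decoys, sel = NULL, fit = NULL) {
  stopifnot(inherits(scores, "DecoyScores"), inherits(decoys, "Ensemble"))
  if (nrow(scores) != length(decoys$models))
    stop("scores and decoys length mismatch")
  imin <- which(scores$total_energy == min(scores$total_energy))
  if (length(imin) > 1L)
    message("tie for minimum energy; using first by tag order: ",
            scores$tag[imin[1L]])
  imin <- imin[1L]
  ref <- decoys$models[[imin]]
  rms <- vapply(seq_along(decoys$models), function(i) {
    if (i == imin) return(0)
    m <- decoys$models[[i]]
    if (!is.null(fit)) m <- apply_transform(m, superpose(m, ref, fit))
    rmsd(m, ref, sel)
  }, numeric(1))
  data.frame(tag = scores$tag, rms = rms, energy = scores$total_energy,
             stringsAsFactors = FALSE)
}

#' Greedy quality-threshold clustering of docking decoys
#'
#' Mirrors post-docking cluster analysis: restrict to the `top_n`
#' lowest-energy decoys, then repeatedly seed a cluster at the unassigned
#' decoy with the most unassigned neighbors within `radius` (RMSD over
#' `selection`), assign those neighbors (truncating to `max_cluster_size`,
#' keeping the lowest energies), and remove them, until `max_clusters`
#' clusters are formed or no decoys remain. Ties in neighbor count are
#' broken by lower energy, then tag order.
#'
#' @param scores `DecoyScores` (one row per decoy, ordered as `decoys`).
#' @param decoys `Ensemble` with shared topology.
#' @param radius cluster radius in Angstrom (default 2.3).
#' @param top_n number of lowest-energy decoys to cluster (default 500;
#'   truncated to the decoy count with a message).
#' @param max_clusters maximum clusters (default 5).
#' @param max_cluster_size maximum members per cluster (default 10).
#' @param selection RMSD selection (default all heavy atoms).
#' @param fit optional fit selection for per-pair superposition; `NULL`
#'   uses the common frame as given.
#' @return list of clusters, each a list with `members` (tags, lowest
#'   energy first), `representative` (lowest-energy member) and `size`.
#' @export
cluster_decoys <- function(scores, decoys, radius = 2.3, top_n = 500,
                           max_clusters = 5, max_cluster_size = 10,
                           selection = NULL, fit = NULL) {
  stopifnot(inherits(scores, "DecoyScores"), inherits(decoys, "Ensemble"))
  if (nrow(scores) != length(decoys$models))
    stop("scores and decoys length mismatch")
  if (top_n > nrow(scores)) {
    message("top_n (", top_n, ") exceeds decoy count (", nrow(scores),
            "); using all decoys")
    top_n <- nrow(scores)
  }
  ord <- order(scores$total_energy)
  keep <- sort(ord[seq_len(top_n)])
  tags <- scores$tag[keep]
  energies <- scores$total_energy[keep]
  models <- decoys$models[keep]
  n <- length(models)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    mi <- models[[i]]
    if (!is.null(fit))
      mi <- apply_transform(mi, superpose(mi, models[[j]], fit))
    dm[i, j] <- dm[j, i] <- rmsd(mi, models[[j]], selection)
  }
  neighbor <- dm <= radius  # includes self
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned) && length(clusters) < max_clusters) {
    counts <- vapply(seq_len(n), function(i)
      if (unassigned[i]) sum(neighbor[i, ] & unassigned) else -1L, numeric(1))
    best <- which(counts == max(counts))
    if (length(best) > 1L) {
      best <- best[order(energies[best], best)]  # lower energy, then tag order
    }
    center <- best[1L]
    members <- which(neighbor[center, ] & unassigned)
    members <- members[order(energies[members], members)]
    if (length(members) > max_cluster_size)
      members <- members[seq_len(max_cluster_size)]
    clusters[[length(clusters) + 1L]] <- list(
      members = tags[members],
      representative = tags[members[1L]],
      center = tags[center],
      size = length(members)
    )
    unassigned[members] <- FALSE
  }
  clusters
}
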