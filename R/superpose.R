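#' Least-squares rigid-body superposition (Kabsch)
#'
#' Computes the optimal proper rotation (determinant +1, reflections
#' corrected via the SVD sign trick) and translation minimizing the RMSD of
#' the fit selection, and the post-fit RMSD over that selection.
#'
#' @param mobile,reference `StructureModel`s containing the fit atoms.
#' @param fit `AtomSelection` applied to both models (they must resolve to
#'   the same number of atoms, >= 3 and non-collinear).
#' @return list of class `superposition` with elements `rotation` (3x3),
#'   `translation` (length 3; transform is `x %*% R + t`), `rmsd` (Angstrom)
#'   and `n_atoms`.
#' @export
superpose <- function(mobile, reference, fit = NULL) {
  im <- select_atoms(mobile, fit)
  ir <- select_atoms(reference, fit)
  if (length(im) != length(ir))
    stop("fit selection resolves to ", length(im), " atoms in mobile but ",
         length(ir), " in reference")
  if (length(im) < 3L) stop("fit selection must contain at least 3 atoms")
  xm <- coords(mobile, im)
  xr <- coords(reference, ir)
  tf <- kabsch(xm, xr)
  fitted <- sweep(xm, 2L, tf$center_mobile) %*% tf$rotation
  fitted <- sweep(fitted, 2L, tf$center_reference, "+")
  structure(list(rotation = tf$rotation,
                 translation = as.numeric(tf$center_reference -
                                            tf$center_mobile %*% tf$rotation),
                 rmsd = rmsd_xyz(fitted, xr),
                 n_atoms = length(im)),
            class = "superposition")
}

kabsch <- function(xm, xr) {
  cm <- colMeans(xm)
  cr <- colMeans(xr)
  a <- sweep(xm, 2L, cm)
  b <- sweep(xr, 2L, cr)
  if (min(svd(b)$d) < 1e-8 && sort(svd(b)$d, decreasing = TRUE)[2L] < 1e-8)
    stop("degenerate (collinear) fit selection")
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, center_mobile = cm, center_reference = cr)
}

#' Apply a superposition transform to a model
#'
#' @param m `StructureModel`.
#' @param tf a `superposition`.
#' @return transformed `StructureModel`.
#' @export
apply_transform <- function(m, tf) {
  set_coords(m, sweep(coords(m) %*% tf$rotation, 2L, tf$translation, "+"))
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Root-mean-square deviation between two models
#'
#' @param a,b `StructureModel`s.
#' @param sel `AtomSelection` defining the reported atoms.
#' @param prefit superpose `a` onto `b` first (on `fit_sel`, which defaults
#'   to `sel`).
#' @param fit_sel optional separate fit selection used when `prefit`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, sel = NULL, prefit = FALSE, fit_sel = NULL) {
  ia <- select_atoms(a, sel)
  ib <- select_atoms(b, sel)
  if (length(ia) == 0L) stop("empty selection")
  if (length(ia) != length(ib)) stop("selection maps to different atom counts")
  if (prefit) a <- apply_transform(a, superpose(a, b, if (is.null(fit_sel)) sel else fit_sel))
  rmsd_xyz(coords(a, ia), coords(b, ib))
}

#' Ensemble RMSD summary relative to the first model
#'
#' Quantifies ensemble definition the way NMR/docking ensembles are usually
#' reported: every non-reference model is superposed on the first
#' (lowest-energy) model over `fit`, then the RMSD over the report scope is
#' computed and averaged. Because deposition conventions differ, a mean
#' pairwise mode is also provided.
#'
#' @param e `Ensemble` (shared topology, >= 2 models).
#' @param fit `AtomSelection` used for superposition (e.g. receptor-groove
#'   backbone).
#' @param report `AtomSelection` giving the reported scope (e.g. the peptide
#'   chain); its backbone (N, CA, C, O) subset yields the backbone RMSD and
#'   its heavy-atom subset the all-atom RMSD.
#' @param mode `"reference"` (default; mean over models 2..n vs model 1) or
#'   `"pairwise"` (mean over all unordered model pairs).
#' @return list with `backbone` and `all_atom` mean RMSDs (Angstrom), plus
#'   `mode` and `n_models`.
#' @export
ensemble_rmsd_summary <- function(e, fit = NULL, report = NULL,
                                  mode = c("reference", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(e, "Ensemble"))
  if (length(e$models) < 2L) stop("ensemble must contain at least 2 models")
  if (is.null(report)) report <- atom_select()
  bb_sel <- report
  bb_sel$class <- "backbone"
  aa_sel <- report
  aa_sel$class <- "all-heavy"
  pair_vals <- function(i, j) {
    mi <- e$models[[i]]
    mj <- e$models[[j]]
    if (!is.null(fit)) mi <- apply_transform(mi, superpose(mi, mj, fit))
    c(bb = rmsd(mi, mj, bb_sel), aa = rmsd(mi, mj, aa_sel))
  }
  pairs <- if (mode == "reference") {
    cbind(seq(2L, length(e$models)), 1L)
  } else {
    t(utils::combn(length(e$models), 2L))
  }
  vals <- t(apply(pairs, 1L, function(p) pair_vals(p[1L], p[2L])))
  list(backbone = mean(vals[, "bb"]), all_atom = mean(vals[, "aa"]),
       mode = mode, n_models = length(e$models))
}

#' Per-atom (and per-residue) root-mean-square fluctuation
#'
#' Each model is first superposed on the first model over `fit`, the
#' coordinate mean is computed, and each model is re-fit once to that mean
#' (a single iteration; deterministic and matching common trajectory-tool
#' behavior). `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` over the report
#' atoms.
#'
#' @param e `Ensemble` with shared topology and >= 2 models.
#' @param fit `AtomSelection` for superposition; `NULL` fits on all heavy
#'   atoms.
#' @param report `AtomSelection` of reported atoms.
#' @return object of class `FluctProfile`: data.frame with atom identity
#'   columns and `rmsf` (Angstrom); per-residue means are available through
#'   [residue_rmsf()].
#' @export
per_atom_rmsf <- function(e, fit = NULL, report = NULL) {
  stopifnot(inherits(e, "Ensemble"), e$shared_topology)
  if (length(e$models) < 2L) stop("need >= 2 models")
  idx <- select_atoms(e$models[[1L]], report)
  if (length(idx) == 0L) stop("empty report selection")
  fit_once <- function(target_xyz_model) {
    lapply(e$models, function(m)
      coords(apply_transform(m, superpose(m, target_xyz_model, fit))))
  }
  xs <- fit_once(e$models[[1L]])
  mean_xyz <- Reduce(`+`, xs) / length(xs)
  mean_model <- set_coords(e$models[[1L]], mean_xyz)
  xs <- fit_once(mean_model)
  mean_xyz <- Reduce(`+`, xs) / length(xs)
  dev2 <- Reduce(`+`, lapply(xs, function(x) rowSums((x - mean_xyz)^2))) /
    length(xs)
  a <- e$models[[1L]]$atoms[idx, c("chain", "resno", "icode", "resname",
                                   "atom"), drop = FALSE]
  a$rmsf <- sqrt(dev2[idx])
  rownames(a) <- NULL
  structure(a, class = c("FluctProfile", "data.frame"))
}

#' Per-residue mean RMSF
#'
#' @param fp `FluctProfile` from [per_atom_rmsf()].
#' @return data.frame with chain, resno, icode, resname and mean `rmsf` over
#'   the residue's selected atoms.
#' @export
residue_rmsf <- function(fp) {
  key <- paste(fp$chain, fp$resno, fp$icode, sep = "|")
  agg <- tapply(fp$rmsf, key, mean)
  first <- fp[!duplicated(key), c("chain", "resno", "icode", "resname")]
  first$rmsf <- as.numeric(agg[paste(first$chain, first$resno, first$icode,
                                     sep = "|")])
  first <- first[order(first$chain, first$resno, first$icode), ]
  rownames(first) <- NULL
  first
}
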