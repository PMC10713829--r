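#' Van der Waals radii (Angstrom) used for clash scoring
#'
#' Bondi-style heavy-atom radii; hydrogens are listed for completeness but
#' clash scoring is heavy-atom only.
#' @export
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
               FE = 2.00, ZN = 1.39, MG = 1.73, "NA" = 2.27, K = 2.75,
               MN = 2.00)

#' Receptor residues contacting a peptide chain
#'
#' A receptor residue is reported iff any of its heavy atoms lies within
#' `cutoff` of any peptide heavy atom (boundary inclusive).
#'
#' @param m `StructureModel`.
#' @param peptide_chain,receptor_chain chain ids.
#' @param cutoff distance cutoff in Angstrom (default 3.5).
#' @return data.frame of contacting receptor residues (`chain`, `resno`,
#'   `icode`, `resname`, `min_dist`), ordered by residue number.
#' @export
contact_residues <- function(m, peptide_chain, receptor_chain, cutoff = 3.5) {
  for (ch in c(peptide_chain, receptor_chain))
    if (!ch %in% m$atoms$chain) stop("unknown chain id: ", ch)
  ip <- select_atoms(m, atom_select(chain = peptide_chain))
  ir <- select_atoms(m, atom_select(chain = receptor_chain))
  if (length(ip) == 0L || length(ir) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      icode = character(), resname = character(),
                      min_dist = numeric()))
  xp <- coords(m, ip)
  xr <- coords(m, ir)
  # receptor-atom x peptide-atom distance matrix (groove scope is small)
  d2 <- outer(rowSums(xr^2), rowSums(xp^2), "+") - 2 * xr %*% t(xp)
  min_d <- sqrt(pmax(apply(d2, 1L, min), 0))
  a <- m$atoms[ir, ]
  key <- paste(a$resno, a$icode, sep = "|")
  res_min <- tapply(min_d, key, min)
  keep_keys <- names(res_min)[res_min <= cutoff]
  first <- a[!duplicated(key) & key %in% keep_keys,
             c("chain", "resno", "icode", "resname")]
  first$min_dist <- as.numeric(res_min[paste(first$resno, first$icode,
                                             sep = "|")])
  first <- first[order(first$resno, first$icode), ]
  rownames(first) <- NULL
  first
}

#' Simplified steric clash score
#'
#' Counts unordered heavy-atom pairs from different residues whose van der
#' Waals overlap `r_i + r_j - d` is at least `overlap_threshold`, excluding
#' pairs of backbone atoms in sequence-adjacent residues of the same chain
#' (the peptide-bond neighborhood), normalized per 1000 atoms. This is a
#' heavy-atom-only approximation to probe-based all-atom clash scores
#' (no hydrogen placement), intended for relative comparisons.
#'
#' @param m `StructureModel`.
#' @param overlap_threshold minimum overlap in Angstrom (default 0.4).
#' @return list with `clashes` (count), `n_atoms` (heavy atoms considered),
#'   `score` (clashes per 1000 atoms) and a data.frame `pairs` of clashing
#'   atom pairs.
#' @export
clash_score <- function(m, overlap_threshold = 0.4) {
  ih <- select_atoms(m, atom_select(class = "all-heavy"))
  a <- m$atoms[ih, ]
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown) > 0L) {
    bad <- which(el %in% unknown)[1L]
    stop("unknown element '", el[bad], "' for atom ", a$atom[bad],
         " in residue ", a$chain[bad], a$resno[bad])
  }
  rad <- VDW_RADII[el]
  n <- nrow(a)
  xyz <- cbind(a$x, a$y, a$z)
  res_id <- paste(a$chain, a$resno, a$icode, sep = "|")
  max_pair <- 2 * max(rad) - overlap_threshold
  hits <- list()
  for (i in seq_len(n - 1L)) {
    j <- seq(i + 1L, n)
    d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    ov <- rad[i] + rad[j] - d
    cand <- j[ov >= overlap_threshold - 1e-9]  # boundary counts as a clash
    if (length(cand) == 0L) next
    cand <- cand[res_id[cand] != res_id[i]]
    # skip backbone-backbone pairs of sequence-adjacent residues (peptide bond)
    adj <- a$chain[cand] == a$chain[i] &
      abs(a$resno[cand] - a$resno[i]) == 1L &
      a$atom[cand] %in% BACKBONE_ATOMS & a$atom[i] %in% BACKBONE_ATOMS
    cand <- cand[!adj]
    if (length(cand) > 0L)
      hits[[length(hits) + 1L]] <- data.frame(
        i = i, j = cand,
        overlap = rad[i] + rad[cand] -
          sqrt(rowSums((xyz[cand, , drop = FALSE] -
                          matrix(xyz[i, ], length(cand), 3L, byrow = TRUE))^2))
      )
  }
  pairs <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(i = integer(), j = integer(), overlap = numeric())
  list(clashes = nrow(pairs), n_atoms = n,
       score = 1000 * nrow(pairs) / n, pairs = pairs)
}
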