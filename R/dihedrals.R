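#' Torsion angle between four points
#'
#' Standard IUPAC sign convention: looking from b to c, the angle from the
#' a-b-c plane to the b-c-d plane, positive clockwise, in (-180, 180].
#'
#' @param a,b,c,d length-3 numeric vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
torsion <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(-atan2(y, x) * 180 / pi)
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Wrap angles into the principal interval (-180, 180]
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w == -180] <- 180
  w
}

# chi1 fourth-atom lookup (N-CA-CB-X); GLY/ALA have no chi1
CHI1_GAMMA <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                TRP = "CG", TYR = "CG", VAL = "CG1")

#' Backbone (and chi1) dihedral angles of one chain
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues yield only the defined angle; residues with missing
#' backbone atoms yield `NA` for the affected angles rather than a
#' fabricated value.
#'
#' @param m `StructureModel`.
#' @param chain chain id.
#' @param angles subset of `c("phi", "psi", "chi1")`.
#' @return data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `phi`, `psi` (and `chi1` when requested), degrees in (-180, 180].
#' @export
backbone_dihedrals <- function(m, chain, angles = c("phi", "psi")) {
  angles <- match.arg(angles, c("phi", "psi", "chi1"), several.ok = TRUE)
  a <- m$atoms[m$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain not found: ", chain)
  res_key <- paste(a$resno, a$icode, sep = "|")
  res_order <- unique(res_key)
  get_atom <- function(key, name) {
    i <- which(res_key == key & a$atom == name)
    if (length(i) != 1L) return(NULL)
    c(a$x[i], a$y[i], a$z[i])
  }
  n_res <- length(res_order)
  out <- data.frame(
    chain = chain,
    resno = a$resno[match(res_order, res_key)],
    icode = a$icode[match(res_order, res_key)],
    resname = a$resname[match(res_order, res_key)],
    stringsAsFactors = FALSE
  )
  safe_torsion <- function(p) {
    if (any(vapply(p, is.null, logical(1)))) return(NA_real_)
    torsion(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
  }
  if ("phi" %in% angles)
    out$phi <- vapply(seq_len(n_res), function(i) {
      if (i == 1L) return(NA_real_)
      safe_torsion(list(get_atom(res_order[i - 1L], "C"),
                        get_atom(res_order[i], "N"),
                        get_atom(res_order[i], "CA"),
                        get_atom(res_order[i], "C")))
    }, numeric(1))
  if ("psi" %in% angles)
    out$psi <- vapply(seq_len(n_res), function(i) {
      if (i == n_res) return(NA_real_)
      safe_torsion(list(get_atom(res_order[i], "N"),
                        get_atom(res_order[i], "CA"),
                        get_atom(res_order[i], "C"),
                        get_atom(res_order[i + 1L], "N")))
    }, numeric(1))
  if ("chi1" %in% angles)
    out$chi1 <- vapply(seq_len(n_res), function(i) {
      gname <- CHI1_GAMMA[out$resname[i]]
      if (is.na(gname)) return(NA_real_)
      safe_torsion(list(get_atom(res_order[i], "N"),
                        get_atom(res_order[i], "CA"),
                        get_atom(res_order[i], "CB"),
                        get_atom(res_order[i], gname)))
    }, numeric(1))
  out
}

#' Extract a dihedral time series from a shared-topology ensemble
#'
#' @param e `Ensemble` with shared topology (trajectory frames).
#' @param chain chain id.
#' @param resno residue number.
#' @param angle one of `"phi"`, `"psi"`, `"chi1"`.
#' @return object of class `DihedralSeries`: list with residue identity,
#'   `angle` name and `values` (degrees, one per frame; `NA` where
#'   undefined).
#' @export
dihedral_series <- function(e, chain, resno, angle = c("phi", "psi", "chi1")) {
  angle <- match.arg(angle)
  stopifnot(inherits(e, "Ensemble"), e$shared_topology)
  values <- vapply(e$models, function(m) {
    d <- backbone_dihedrals(m, chain, angles = angle)
    v <- d[[angle]][d$resno == resno]
    if (length(v) == 0L) NA_real_ else v[1L]
  }, numeric(1))
  structure(list(chain = chain, resno = resno, angle = angle,
                 values = values),
            class = "DihedralSeries")
}
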