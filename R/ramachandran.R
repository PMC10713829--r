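#' Ramachandran region classification
#'
#' Classification uses package-constructed 2 x 2 degree region masks per
#' residue class (general, glycine, proline, pre-proline). The masks are
#' rasterized from coarse analytic regions (unions of ellipses centered on
#' the canonical alpha-helical, beta-sheet and left-handed-alpha basins,
#' with glycine symmetrized about the origin and proline restricted in phi),
#' not from a redistributed MolProbity/RAMPAGE data table; they are
#' deterministic, periodic in both angles, and partition the torus into
#' favored/allowed/outlier.
#'
#' @name ramachandran
NULL

# angular difference respecting 360-degree periodicity
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

in_ellipse <- function(phi, psi, c_phi, c_psi, r_phi, r_psi) {
  (ang_diff(phi, c_phi) / r_phi)^2 + (ang_diff(psi, c_psi) / r_psi)^2 <= 1
}

# region tables: one row per ellipse (center phi/psi, radii phi/psi)
RAMA_REGIONS <- list(
  general = rbind(
    c(-63, -43, 40, 50),    # alpha (right-handed helix)
    c(-115, 130, 60, 55),   # beta / extended
    c(-120, 170, 60, 35),   # upper beta tail (wraps to psi ~ -180)
    c(57, 42, 22, 25)       # left-handed alpha
  ),
  glycine = rbind(
    c(-63, -43, 40, 50), c(63, 43, 40, 50),
    c(-115, 130, 60, 55), c(115, -130, 60, 55),
    c(-120, 170, 60, 35), c(120, -170, 60, 35),
    c(80, 0, 35, 40), c(-80, 0, 35, 40)
  ),
  proline = rbind(
    c(-62, -35, 25, 40),    # alpha
    c(-65, 150, 30, 40)     # polyproline II / beta
  ),
  `pre-proline` = rbind(
    c(-63, -43, 40, 50),
    c(-115, 130, 60, 55),
    c(-120, 170, 60, 35),
    c(-130, 80, 35, 35),    # zeta basin preceding proline
    c(57, 42, 22, 25)
  )
)
ALLOWED_DILATION <- 1.6

classify_point <- function(phi, psi, regions) {
  fav <- FALSE
  alw <- FALSE
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (in_ellipse(phi, psi, r[1L], r[2L], r[3L], r[4L])) fav <- TRUE
    if (in_ellipse(phi, psi, r[1L], r[2L],
                   r[3L] * ALLOWED_DILATION, r[4L] * ALLOWED_DILATION))
      alw <- TRUE
  }
  if (fav) "favored" else if (alw) "allowed" else "outlier"
}

rama_env <- new.env(parent = emptyenv())

rama_mask <- function(class) {
  key <- paste0("mask_", class)
  if (!is.null(rama_env[[key]])) return(rama_env[[key]])
  centers <- seq(-179, 179, by = 2)  # 2-degree bins, centers at odd degrees
  regions <- RAMA_REGIONS[[class]]
  m <- matrix("outlier", length(centers), length(centers))
  for (i in seq_along(centers))
    for (j in seq_along(centers))
      m[i, j] <- classify_point(centers[i], centers[j], regions)
  rama_env[[key]] <- m
  m
}

#' Classify a (phi, psi) pair
#'
#' Deterministic lookup in the shipped 2 x 2 degree masks; any angle pair
#' classifies (the masks tile the torus) and the classification is periodic
#' in 360 degrees.
#'
#' @param phi,psi angles in degrees (vectorized).
#' @param residue_class `"general"`, `"glycine"`, `"proline"` or
#'   `"pre-proline"`.
#' @return character vector in `{"favored", "allowed", "outlier"}`.
#' @export
ramachandran_classify <- function(phi, psi,
                                  residue_class = c("general", "glycine",
                                                    "proline", "pre-proline")) {
  residue_class <- match.arg(residue_class)
  m <- rama_mask(residue_class)
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)
  bin <- function(x) pmin(pmax(floor((x + 180) / 2) + 1L, 1L), 180L)
  m[cbind(bin(phi), bin(psi))]
}

#' Ramachandran classification of every residue in a chain
#'
#' Residue classes are assigned automatically: glycine and proline by
#' residue name, pre-proline for residues immediately preceding a proline,
#' general otherwise. Residues with undefined phi or psi (termini) are
#' returned with `NA` classification.
#'
#' @param m `StructureModel`.
#' @param chain chain id.
#' @return data.frame of residues with `phi`, `psi`, `residue_class` and
#'   `rama` label.
#' @export
ramachandran_chain <- function(m, chain) {
  d <- backbone_dihedrals(m, chain, angles = c("phi", "psi"))
  n <- nrow(d)
  cls <- rep("general", n)
  cls[d$resname == "GLY"] <- "glycine"
  cls[d$resname == "PRO"] <- "proline"
  pre <- which(c(d$resname[-1L] == "PRO", FALSE))
  cls[setdiff(pre, which(d$resname %in% c("GLY", "PRO")))] <- "pre-proline"
  d$residue_class <- cls
  d$rama <- NA_character_
  ok <- !is.na(d$phi) & !is.na(d$psi)
  for (cc in unique(cls[ok]))
    d$rama[ok & cls == cc] <- ramachandran_classify(d$phi[ok & cls == cc],
                                                    d$psi[ok & cls == cc], cc)
  d
}
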