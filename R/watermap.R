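#' Water-occupancy grid over trajectory frames
#'
#' Per frame, water oxygens within `within` Angstrom of the `near`
#' selection mark every voxel whose center lies within `atom_radius`; the
#' voxel occupancy is the fraction of frames in which it was marked. The
#' grid covers the `near` selection's envelope (over all frames) padded by
#' `within + atom_radius`, with voxel centers on a regular lattice of the
#' given spacing. Occupancy grids from disjoint frame subsets combine as
#' the frame-count-weighted mean.
#'
#' @param fe shared-topology `Ensemble` whose models retain solvent atoms
#'   (water residue names `HOH`/`WAT`/`SOL`/`TIP3`).
#' @param near `AtomSelection` defining the region of interest (e.g.
#'   receptor residues 150-155).
#' @param within water inclusion cutoff from the `near` selection
#'   (Angstrom, default 5).
#' @param spacing voxel edge length (Angstrom, default 1).
#' @param atom_radius voxel-marking radius around each water oxygen
#'   (Angstrom, default 1).
#' @return object of class `OccupancyGrid`: list with `origin` (center of
#'   the first voxel), `spacing`, `dim`, `occupancy` (3D array in [0, 1]),
#'   `n_frames` and the parameters used.
#' @export
water_occupancy <- function(fe, near, within = 5, spacing = 1,
                            atom_radius = 1) {
  stopifnot(inherits(fe, "Ensemble"))
  water_resnames <- c("HOH", "WAT", "SOL", "TIP3")
  m1 <- fe$models[[1L]]
  if (!any(m1$atoms$resname %in% water_resnames))
    stop("no solvent atoms (HOH/WAT/SOL/TIP3) in the ensemble")
  near_idx <- select_atoms(m1, near)
  if (length(near_idx) == 0L) stop("empty 'near' selection")
  # envelope of the near selection over all frames, padded
  mins <- rep(Inf, 3L)
  maxs <- rep(-Inf, 3L)
  for (m in fe$models) {
    xyz <- coords(m, near_idx)
    mins <- pmin(mins, apply(xyz, 2L, min))
    maxs <- pmax(maxs, apply(xyz, 2L, max))
  }
  pad <- within + atom_radius
  origin <- mins - pad
  dims <- pmax(ceiling((maxs + pad - origin) / spacing) + 1L, 1L)
  counts <- array(0L, dim = dims)
  wat_o <- which(m1$atoms$resname %in% water_resnames &
                   toupper(m1$atoms$element) == "O")
  if (length(wat_o) == 0L)
    wat_o <- which(m1$atoms$resname %in% water_resnames)
  r_vox <- ceiling(atom_radius / spacing)
  for (m in fe$models) {
    near_xyz <- coords(m, near_idx)
    w_xyz <- coords(m, wat_o)
    d2 <- outer(rowSums(w_xyz^2), rowSums(near_xyz^2), "+") -
      2 * w_xyz %*% t(near_xyz)
    close <- which(apply(d2, 1L, min) <= within^2)
    if (length(close) == 0L) next
    marked <- array(FALSE, dim = dims)
    for (wi in close) {
      p <- w_xyz[wi, ]
      ctr <- round((p - origin) / spacing) + 1L
      lo <- pmax(ctr - r_vox, 1L)
      hi <- pmin(ctr + r_vox, dims)
      if (any(lo > hi)) next
      for (ix in lo[1L]:hi[1L]) for (iy in lo[2L]:hi[2L])
        for (iz in lo[3L]:hi[3L]) {
          cvec <- origin + (c(ix, iy, iz) - 1L) * spacing
          if (sum((cvec - p)^2) <= atom_radius^2)
            marked[ix, iy, iz] <- TRUE
        }
    }
    counts <- counts + marked
  }
  structure(list(origin = origin, spacing = spacing, dim = dims,
                 occupancy = counts / length(fe$models),
                 n_frames = length(fe$models),
                 within = within, atom_radius = atom_radius),
            class = "OccupancyGrid")
}

#' Combine occupancy grids from disjoint frame subsets
#'
#' Frame-count-weighted mean; grids must share origin, spacing and
#' dimensions.
#'
#' @param grids list of `OccupancyGrid`s.
#' @return combined `OccupancyGrid`.
#' @export
combine_occupancy <- function(grids) {
  g1 <- grids[[1L]]
  for (g in grids[-1L])
    if (!isTRUE(all.equal(g$origin, g1$origin)) ||
        g$spacing != g1$spacing || !all(g$dim == g1$dim))
      stop("grids are not commensurate")
  n_tot <- sum(vapply(grids, function(g) g$n_frames, numeric(1)))
  occ <- Reduce(`+`, lapply(grids, function(g) g$occupancy * g$n_frames)) /
    n_tot
  g1$occupancy <- occ
  g1$n_frames <- n_tot
  g1
}

#' Write an occupancy grid as an OpenDX volumetric map
#'
#' The standard text format consumed by molecular viewers, so a chosen
#' isosurface (e.g. 0.2) can be rendered externally.
#'
#' @param grid `OccupancyGrid`.
#' @param path output `.dx` file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dim
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d ",
                   "data follows"), prod(d))
  ), con)
  # dx order: z fastest
  vals <- as.numeric(grid$occupancy[cbind(
    rep(seq_len(d[1]), each = d[2] * d[3]),
    rep(rep(seq_len(d[2]), each = d[3]), times = d[1]),
    rep(seq_len(d[3]), times = d[1] * d[2]))])
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(vals) > n3)
    writeLines(paste(sprintf("%.6f", vals[seq(n3 + 1L, length(vals))]),
                     collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
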