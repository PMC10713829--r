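# Shared fixtures and independent oracles used across the suite.

# simple n-atom model on given coordinates
make_model <- function(xyz, chain = "A", resno = NULL, atom = NULL,
                       resname = "ALA", element = "C") {
  n <- nrow(xyz)
  structure_model(data.frame(
    chain = chain, resno = if (is.null(resno)) seq_len(n) else resno,
    icode = "", resname = resname,
    atom = if (is.null(atom)) paste0("C", seq_len(n)) else atom,
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

euler_rot <- function(a, b, c) {
  # ZYZ Euler angles
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

# independent superposition oracle: numeric search over Euler angles from a
# coarse grid of starts (no SVD anywhere on this path)
oracle_fit_rmsd <- function(xm, xr) {
  a <- sweep(xm, 2, colMeans(xm))
  b <- sweep(xr, 2, colMeans(xr))
  obj <- function(p) {
    r <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((a %*% r - b)^2)))
  }
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 5)[-5]
  for (ga in grid) for (gb in seq(0, pi, length.out = 3)) for (gc in grid) {
    o <- stats::optim(c(ga, gb, gc), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# exhaustive single-linkage clustering oracle (agglomerate closest pair)
oracle_single_linkage <- function(dm, cutoff) {
  clusters <- as.list(seq_len(nrow(dm)))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (j > i) {
      d <- min(dm[clusters[[i]], clusters[[j]], drop = FALSE])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lapply(clusters, sort)
}

# canonical form for comparing cluster partitions
canon_partition <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, numeric(1), 1))]
}

# independent Brown-Forsythe (means version) from the published formulas,
# written without reference to the package implementation
oracle_brown_forsythe_F <- function(groups) {
  n <- vapply(groups, length, numeric(1))
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  s2 <- vapply(groups, function(g) sum((g - mean(g))^2) / (length(g) - 1),
               numeric(1))
  grand <- sum(unlist(groups)) / N
  sum(n * (m - grand)^2) / sum((1 - n / N) * s2)
}
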