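write_cst <- function(lines) {
  path <- withr::local_tempfile(fileext = ".cst", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("restraint parser handles the AtomPair/BOUNDED dialect", {
  p <- write_cst(c("# intermolecular NOEs",
                   "AtomPair CD1 97 HA 182 BOUNDED 1.5 6.0 0.5 noe1",
                   "",
                   "AtomPair A:CA 140 C:N 181 BOUNDED 2.0 5.5 0.5 noe2"))
  rt <- read_restraints(p)
  expect_length(rt, 2L)
  r1 <- rt$restraints[[1]]
  expect_equal(r1$lower_bound, 1.5)
  expect_equal(r1$upper_bound, 6.0)
  expect_equal(r1$group_a$atom, "CD1")
  expect_equal(rt$restraints[[2]]$group_a$chain, "A")
  # comment-only file -> empty table
  expect_length(read_restraints(write_cst("# nothing")), 0L)
  # malformed line errors carry the line number
  expect_error(read_restraints(write_cst("AtomPair CD1 97 HA BOUNDED 1 6")),
               "line 1")
  expect_error(read_restraints(write_cst(
    c("AtomPair CA 1 CB 2 BOUNDED 1 6 0.5 dup",
      "AtomPair CA 3 CB 4 BOUNDED 1 6 0.5 dup"))), "duplicate")
})

test_that("pseudo-atoms expand to proton groups and round-trip", {
  p <- write_cst("AtomPair MD1 97 HA 182 BOUNDED 1.5 6.0 0.5 methyl")
  rt <- read_restraints(p)
  expect_setequal(rt$restraints[[1]]$group_a$atom, c("HD11", "HD12", "HD13"))
  out <- withr::local_tempfile(fileext = ".cst")
  write_restraints(rt, out)
  rt2 <- read_restraints(out)
  expect_equal(rt2$restraints[[1]]$group_a$atom,
               rt$restraints[[1]]$group_a$atom)
})

test_that("effective distance: r^-6 closed forms and the min bound", {
  mk <- function(xyz, atoms) structure_model(data.frame(
    chain = "A", resno = seq_len(nrow(xyz)), icode = "", resname = "ALA",
    atom = atoms, element = "H", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  # 1x1 at 4 A -> 4
  m <- mk(cbind(c(0, 4), 0, 0), c("HA", "HB"))
  r11 <- noe_restraint(data.frame(chain = NA, resno = 1, atom = "HA"),
                       data.frame(chain = NA, resno = 2, atom = "HB"),
                       0, 6, label = "a")
  expect_equal(effective_distance(m, r11), 4)
  # 1x2, both pairs at 4 A -> 4 * 2^(-1/6)
  m2 <- mk(rbind(c(0, 0, 0), c(4, 0, 0), c(-4, 0, 0)),
           c("HA", "HB1", "HB2"))
  r12 <- noe_restraint(data.frame(chain = NA, resno = 1, atom = "HA"),
                       data.frame(chain = NA, resno = 2:3,
                                  atom = c("HB1", "HB2")),
                       0, 6, label = "b")
  expect_equal(effective_distance(m2, r12), 4 * 2^(-1 / 6))
  expect_equal(effective_distance(m2, r12, method = "min"), 4)
  # d_eff <= min pairwise distance on random geometries
  set.seed(3)
  for (i in 1:10) {
    xyz <- rbind(c(0, 0, 0), matrix(rnorm(6, sd = 3), ncol = 3))
    m3 <- mk(xyz, c("HA", "HB1", "HB2"))
    d_eff <- effective_distance(m3, r12)
    dmin <- min(sqrt(rowSums(sweep(xyz[2:3, ], 2, xyz[1, ])^2)))
    expect_lte(d_eff, dmin + 1e-12)
  }
  # missing atom names the offender
  expect_error(effective_distance(m, noe_restraint(
    data.frame(chain = NA, resno = 1, atom = "HZ9"),
    data.frame(chain = NA, resno = 2, atom = "HB"), 0, 6, label = "zz")),
    "HZ9")
})

test_that("violation evaluation: boundaries, tolerance monotonicity", {
  m <- make_model(cbind(c(0, 6.6), 0, 0), atom = c("CA", "CB"))
  mk_rt <- function(ub) structure(list(restraints = list(
    noe_restraint(data.frame(chain = NA, resno = 1, atom = "CA"),
                  data.frame(chain = NA, resno = 2, atom = "CB"),
                  0, ub, label = "r1")), provenance = "test"),
    class = "RestraintTable")
  rep1 <- evaluate_violations(m, mk_rt(6.0), tolerance = 0.5)
  expect_true(rep1$violated)
  expect_equal(rep1$excess, 0.1, tolerance = 1e-9)
  # excess > 0 iff violated
  expect_true(all((rep1$excess > 0) == rep1$violated))
  rep2 <- evaluate_violations(m, mk_rt(6.2), tolerance = 0.5)
  expect_false(rep2$violated)
  expect_equal(rep2$excess, 0)
  # lowering tolerance never decreases violations
  rt <- mk_rt(6.0)
  tols <- c(1.0, 0.6, 0.5, 0.1, 0)
  n_viol <- vapply(tols, function(tl)
    sum(evaluate_violations(m, rt, tolerance = tl)$violated), numeric(1))
  expect_true(all(diff(n_viol) >= 0))
})

test_that("filter_decoys removes violators, sorts, and is idempotent", {
  g <- gen_decoy_set(seed = 42, n = 100, violation_fraction = 0.37)
  reports <- evaluate_violations(g$decoys, g$restraints, tolerance = 0.5)
  names(reports) <- g$scores$tag
  kept <- filter_decoys(g$scores, reports)
  expect_equal(nrow(kept), 63L)
  expect_false(any(kept$tag %in% g$truth$params$violator_tags))
  expect_true(!is.unsorted(kept$total_energy))
  # idempotent
  again <- filter_decoys(kept, reports)
  expect_equal(again$tag, kept$tag)
  # missing report errors
  expect_error(filter_decoys(g$scores, reports[-1]), "missing violation")
  # zero violators -> identity up to sorting
  g0 <- gen_decoy_set(seed = 1, n = 20, violation_fraction = 0)
  reports0 <- evaluate_violations(g0$decoys, g0$restraints)
  names(reports0) <- g0$scores$tag
  expect_equal(nrow(filter_decoys(g0$scores, reports0)), 20L)
})

test_that("energy landscape references the lowest-energy decoy", {
  g <- gen_decoy_set(seed = 5, n = 20, violation_fraction = 0)
  land <- energy_landscape(g$scores, g$decoys,
                           sel = atom_select(chain = "C", class = "backbone-no-O"))
  expect_equal(nrow(land), 20L)
  imin <- which.min(g$scores$total_energy)
  expect_equal(land$rms[imin], 0)
  expect_equal(land$energy, g$scores$total_energy)
  # rms values match the rmsd op against the same reference
  ref <- g$decoys$models[[imin]]
  j <- if (imin == 1L) 2L else 1L
  expect_equal(land$rms[j],
               rmsd(g$decoys$models[[j]], ref,
                    atom_select(chain = "C", class = "backbone-no-O")))
})

test_that("QT decoy clustering recovers programmed bundles and matches the
           neighbor-count oracle", {
  # two well-separated bundles of 20 + 20
  base <- synth_complex_model()
  shift_pep <- function(m, dy, jitter, seed) {
    set.seed(seed)
    xyz <- coords(m)
    pep <- which(m$atoms$chain == "C")
    xyz[pep, 2] <- xyz[pep, 2] + dy
    xyz[pep, ] <- xyz[pep, ] + matrix(rnorm(length(pep) * 3, 0, jitter),
                                      ncol = 3)
    set_coords(m, xyz)
  }
  models <- c(lapply(1:20, function(i) shift_pep(base, 0, 0.05, i)),
              lapply(1:20, function(i) shift_pep(base, 10, 0.05, 100 + i)))
  decoys <- ensemble(models)
  scores <- decoy_scores(sprintf("d%02d", 1:40), seq(-300, -261))
  sel <- atom_select(chain = "C")
  cl <- cluster_decoys(scores, decoys, radius = 2.3, top_n = 40,
                       max_clusters = 5, max_cluster_size = 20,
                       selection = sel)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]]$members, sprintf("d%02d", 1:20))
  expect_setequal(cl[[2]]$members, sprintf("d%02d", 21:40))
  # members within radius of their center; disjoint memberships
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0L)
  for (clu in cl) {
    ci <- match(clu$center, scores$tag)
    for (tg in clu$members)
      expect_lte(rmsd(models[[match(tg, scores$tag)]], models[[ci]], sel),
                 2.3)
  }
  # representative is the lowest-energy member
  expect_equal(cl[[1]]$representative, "d01")
  # oracle check on a <= 25-decoy instance: first center has the maximal
  # brute-force neighbor count
  small <- ensemble(models[1:24])
  ssc <- decoy_scores(sprintf("s%02d", 1:24), seq(-100, -77))
  dm <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24) if (j > i)
    dm[i, j] <- dm[j, i] <- rmsd(models[[i]], models[[j]], sel)
  counts <- rowSums(dm <= 2.3)  # includes self via diagonal zeros
  cls <- cluster_decoys(ssc, small, radius = 2.3, top_n = 24,
                        max_clusters = 3, max_cluster_size = 24,
                        selection = sel)
  expect_equal(match(cls[[1]]$center, ssc$tag),
               which(counts == max(counts))[1])
  expect_setequal(match(cls[[1]]$members, ssc$tag),
                  which(dm[match(cls[[1]]$center, ssc$tag), ] <= 2.3))
})
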