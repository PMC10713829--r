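test_that("dilution fraction and uptake engine analytic cases", {
  expect_identical(hdx_dilution_fraction(5, 20), 0.8)
  cfg <- hdx_config()
  expect_equal(percent_uptake(1000, 1000, 1010, cfg), 0)
  expect_equal(percent_uptake(1010, 1000, 1010, cfg), 100)
  expect_equal(percent_uptake(1005, 1000, 1010, cfg), 50)
  # affine invariance of the span variant
  expect_equal(percent_uptake(1005 + 7.3, 1000 + 7.3, 1010 + 7.3, cfg),
               percent_uptake(1005, 1000, 1010, cfg))
  # d-scaled variant rescales by D_frac
  cfg_d <- hdx_config(correction_variant = "d-scaled")
  expect_equal(percent_uptake(1008, 1000, 1010, cfg_d), 80 / 0.8)
  expect_error(percent_uptake(1, 5, 2, cfg), "m100")
  expect_error(hdx_config(D_frac = 0), "D_frac")
})

test_that("uptake curves: replicate SD, forced zero, plateau recovery", {
  obs <- expand.grid(time_s = c(0, 20, 60, 180, 600), replicate = 1:3)
  obs$m_t <- 1000 + 8 * (1 - exp(-0.02 * obs$time_s))
  fr <- hdx_fragment("p", 1, 10, "AAAAAAAAAA", 1000, 1010.0628, obs)
  cur <- build_uptake_curves(fr)
  expect_true(all(cur$sd_uptake == 0))           # identical replicates
  expect_equal(cur$mean_uptake[cur$time_s == 0], 0)
  expect_true(!is.unsorted(cur$mean_uptake))      # monotone input
  # generator ground truth: saturating exchange plateaus at D_frac * 100
  g <- gen_hdx_dataset(seed = 2, k_exposed = 0.5, protection_factor = 1,
                       noise_sd = 0)
  cur_g <- build_uptake_curves(g$fragments, g$config)
  at600 <- cur_g$mean_uptake[cur_g$time_s == 600]
  expect_equal(at600, rep(80, length(at600)), tolerance = 1e-6)
  # the d-scaled variant reports saturation as 100%
  cfg_d <- hdx_config(D_frac = 0.8, correction_variant = "d-scaled")
  cur_d <- build_uptake_curves(g$fragments, cfg_d)
  expect_equal(cur_d$mean_uptake[cur_d$time_s == 600][1], 100,
               tolerance = 1e-6)
})

test_that("residue resolution: spans, overlap means, order invariance", {
  cur <- data.frame(start = 10, end = 15, time_s = 600, mean_uptake = 60)
  map <- residue_resolve(cur, protein_length = 25)
  expect_equal(map$uptake[10:15], rep(60, 6))
  expect_true(all(!map$covered[c(1:9, 16:25)]))
  expect_true(all(is.na(map$uptake[!map$covered])))
  # information conservation for a single fragment
  expect_equal(mean(map$uptake[map$covered]), 60)
  # overlapping fragments average
  cur2 <- rbind(cur, data.frame(start = 13, end = 20, time_s = 600,
                                mean_uptake = 80))
  map2 <- residue_resolve(cur2, 25)
  expect_equal(map2$uptake[13:15], rep(70, 3))
  expect_equal(map2$uptake[10:12], rep(60, 3))
  expect_equal(map2$uptake[16:20], rep(80, 5))
  expect_equal(map2$coverage[13:15], rep(2L, 3))
  # fragment input order irrelevant
  map2r <- residue_resolve(cur2[2:1, ], 25)
  expect_equal(map2r$uptake, map2$uptake)
  expect_error(residue_resolve(cur, 12), "outside")
  # length weighting mode changes the overlap mean accordingly
  mw <- residue_resolve(cur2, 25, weighting = "length")
  w1 <- 1 / 6; w2 <- 1 / 8
  expect_equal(mw$uptake[13], (w1 * 60 + w2 * 80) / (w1 + w2))
})

test_that("protected span shows reduced resolved uptake at 600 s", {
  hits <- vapply(1:20, function(s) {
    g <- gen_hdx_dataset(seed = s, noise_sd = 0.02)
    cur <- build_uptake_curves(g$fragments, g$config)
    map <- residue_resolve(cur, 30, time_s = 600)
    prot <- 11:20
    expo <- setdiff(which(map$covered), prot)
    mean(map$uptake[prot], na.rm = TRUE) < mean(map$uptake[expo], na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("HDX CSV round trip preserves fragments and references", {
  g <- gen_hdx_dataset(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hdx_table(g$fragments, path)
  back <- read_hdx_table(path)
  expect_length(back, length(g$fragments))
  expect_equal(back[[1]]$m0, g$fragments[[1]]$m0)
  expect_equal(back[[1]]$m100, g$fragments[[1]]$m100)
  expect_equal(back[[2]]$observations$m_t, g$fragments[[2]]$observations$m_t)
  expect_equal(build_uptake_curves(back, g$config),
               build_uptake_curves(g$fragments, g$config))
})

test_that("B-factor painting carries resolved uptake into written PDB", {
  m <- synth_complex_model()
  map <- data.frame(resno = 181:190, uptake = seq(10, 100, 10))
  painted <- paint_bfactor(m, map, chain = "C")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(painted, path)
  lines <- readLines(path)
  b <- as.numeric(substr(lines[startsWith(lines, "ATOM")], 61, 66))
  resno <- as.integer(substr(lines[startsWith(lines, "ATOM")], 23, 26))
  chain <- substr(lines[startsWith(lines, "ATOM")], 22, 22)
  expect_equal(unique(b[chain == "C" & resno == 185]), 50)
  expect_true(all(b[chain == "A"] == 0))
})

test_that("Welch and Brown-Forsythe match reference implementations", {
  # textbook-style 3-group heteroscedastic dataset
  groups <- list(a = c(27.9, 25.1, 26.7, 28.2, 24.9),
                 b = c(23.1, 22.8, 24.9, 21.7),
                 c = c(29.8, 31.2, 28.4, 30.1, 32.0, 29.4))
  w <- welch_anova(groups)
  ref <- stats::oneway.test(y ~ g,
                            data.frame(y = unlist(groups),
                                       g = factor(rep(names(groups),
                                                      lengths(groups)))),
                            var.equal = FALSE)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(w$df2, unname(ref$parameter["denom df"]), tolerance = 1e-8)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-8)
  bf <- brown_forsythe(groups)
  expect_equal(bf$statistic, oracle_brown_forsythe_F(groups),
               tolerance = 1e-10)
  # two groups: Welch F equals the squared Welch t
  g2 <- list(x = c(1.2, 1.9, 2.4, 1.7), y = c(2.8, 3.3, 2.1, 3.9, 2.6))
  w2 <- welch_anova(g2)
  t2 <- stats::t.test(g2$x, g2$y)
  expect_equal(w2$statistic, unname(t2$statistic)^2, tolerance = 1e-10)
  expect_equal(w2$p_value, t2$p.value, tolerance = 1e-10)
  # identical groups: F = 0, exact-equality shortcut
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1))
  expect_equal(welch_anova(same)$statistic, 0)
  expect_equal(welch_anova(same)$p_value, 1)
  expect_equal(compare_states(same)$p_value, c(1, 1))
  expect_error(welch_anova(list(1:3)), ">= 2 groups")
})

test_that("null p-values are uniform (KS over seeded simulations)", {
  # null world: equal means, moderate heteroscedasticity (the Satterthwaite
  # approximation behind both tests is asymptotic; extreme variance ratios
  # at n = 10 visibly distort the Brown-Forsythe null, see the vignette)
  set.seed(20240601)
  p_w <- numeric(1000)
  p_b <- numeric(1000)
  for (i in 1:1000) {
    gr <- list(rnorm(10), rnorm(10, sd = 1.5), rnorm(10, sd = 0.75))
    p_w[i] <- welch_anova(gr)$p_value
    p_b[i] <- brown_forsythe(gr)$p_value
  }
  expect_gt(stats::ks.test(p_w, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(p_b, "punif")$p.value, 0.01)
})
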