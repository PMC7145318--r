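test_that("gas generator is deterministic and respects steric limits", {
  bx <- box(c(30, 30, 30))
  a <- generate_gas_configuration(n_water = 20, box = bx, seed = 5)
  b <- generate_gas_configuration(n_water = 20, box = bx, seed = 5)
  expect_identical(a$coords, b$coords)
  c_ <- generate_gas_configuration(n_water = 20, box = bx, seed = 6)
  expect_false(identical(a$coords, c_$coords))
  # empty request -> empty frame
  e <- generate_gas_configuration(box = bx, seed = 1)
  expect_equal(n_atoms(e), 0)
  expect_equal(n_frames(e), 1)
  # heavy-atom clash distance respected
  g <- generate_gas_configuration(n_water = 40, box = box(c(22, 22, 22)), seed = 2)
  xyz <- g$coords[, , 1]
  heavy <- which(g$topology$element != "H")
  dmin <- Inf
  for (i in heavy) for (j in heavy) {
    if (g$topology$molecule_id[i] >= g$topology$molecule_id[j]) next
    dmin <- min(dmin, oracle_min_dist(xyz[i, ], xyz[j, ], c(22, 22, 22)))
  }
  expect_gte(dmin, 2.0)
  # impossible packing errors out
  expect_error(generate_gas_configuration(n_water = 500, box = box(c(8, 8, 8)),
                                          seed = 1, max_retries = 20),
               "larger box")
})

test_that("hydrated fixture realizes exact solvation counts", {
  bx <- box(c(60, 60, 60))
  for (ws in 0:2) {
    h <- generate_hydrated_trehalose(2, waters_per_site = ws, d_hb = 2.8,
                                     box = bx, seed = 3)
    hb <- detect_hbonds(get_frame(h, 1), h$topology)
    wt <- sum(hb$class %in% c("WT", "TW"))
    expect_equal(wt, 8 * 2 * ws)
    if (ws > 0) expect_true(all(hb$class[hb$class != "WW"] == "WT"))
  }
  expect_error(generate_hydrated_trehalose(2, 2, d_hb = 3.6, box = bx, seed = 1),
               "d_hb")
})

test_that("clustered generator builds the requested component structure", {
  bx <- box(c(60, 60, 60))
  tr <- generate_clustered_configuration(c(3), box = bx, seed = 1)
  cs <- find_clusters(build_adjacency(get_frame(tr, 1), tr$topology))
  expect_equal(sort(cs$sizes), 3)
  tr <- generate_clustered_configuration(c(5, 2, 1), box = bx, seed = 1)
  cs <- find_clusters(build_adjacency(get_frame(tr, 1), tr$topology))
  expect_equal(sort(cs$sizes), c(1, 2, 5))
  expect_false(any(cs$percolating))
  expect_error(generate_clustered_configuration(c(40), box = bx, seed = 1),
               "fit")
})

test_that("Brownian generator: zero diffusion is static, seeds reproduce", {
  bx <- box(c(30, 30, 30))
  tr <- generate_brownian_trajectory(c(OTHER = 10), c(OTHER = 0), dt = 0.1,
                                     n_steps = 20, box = bx, seed = 4)
  expect_false(is.null(tr$unwrapped))
  expect_equal(max(abs(sweep(tr$unwrapped, c(1, 2), tr$unwrapped[, , 1]))), 0)
  msd <- compute_msd(tr, "OTHER", n_lags = 15)
  expect_true(all(msd$msd == 0))
  a <- generate_brownian_trajectory(c(OTHER = 5), c(OTHER = 0.2), dt = 0.05,
                                    n_steps = 50, box = bx, seed = 9)
  b <- generate_brownian_trajectory(c(OTHER = 5), c(OTHER = 0.2), dt = 0.05,
                                    n_steps = 50, box = bx, seed = 9)
  expect_identical(a$unwrapped, b$unwrapped)
  # wrapped stays in the box even when unwrapped leaves it
  expect_true(all(a$coords >= 0 & a$coords <= 30))
})

test_that("telegraph fixtures have the prescribed stationary statistics", {
  sp <- telegraph_spec(0.5, 0.25, n_pairs = 2000, dt = 0.02, n_steps = 1000)
  s1 <- telegraph_population_series(sp, seed = 11)
  s2 <- telegraph_population_series(sp, seed = 11)
  expect_identical(s1$h, s2$h)
  p <- 0.25 / 0.75
  frac <- mean(s1$h)
  se <- sqrt(p * (1 - p) / (sp$n_pairs))  # conservative: pairs independent
  expect_lt(abs(frac - p), 3 * max(se, 0.01))
  # near-zero forward rate: bonds essentially never break
  slow <- telegraph_spec(1e-6, 5, n_pairs = 200, dt = 0.02, n_steps = 500)
  expect_gt(mean(telegraph_population_series(slow, seed = 2)$h), 0.99)
  expect_error(telegraph_spec(0.5, 0.25, 10, 0.02, 100, d_broken = 3.6),
               "3.5")
})

test_that("telegraph geometry realizes the hidden states", {
  sp <- telegraph_spec(0.5, 0.25, n_pairs = 25, dt = 0.02, n_steps = 200)
  tr <- generate_telegraph_hbond_trajectory(sp, seed = 5)
  truth <- attr(tr, "bond_states")
  pa <- attr(tr, "pair_atoms")
  for (f in c(1, 50, 200)) {
    hb <- detect_hbonds(get_frame(tr, f), tr$topology)
    bonded_pairs <- sort(hb$donor_o)
    expect_equal(bonded_pairs, sort(pa[truth[f, ] == 1, "donor_o"]))
  }
})

test_that("density-curve generator places maxima at the prescribed Tg", {
  d <- generate_density_curves(c("0.2" = 230, "0.6" = 310), noise_sd = 0, seed = 1)
  for (w in c(0.2, 0.6)) {
    sub <- d[d$omega == w, ]
    tg_true <- if (w == 0.2) 230 else 310
    expect_equal(sub$T[which.max(sub$rho)], tg_true)  # on-grid maxima
  }
  # ordering of prescribed maxima is preserved under noise
  d2 <- generate_density_curves(c("0.1" = 180, "0.8" = 350), noise_sd = 0.001,
                                seed = 2)
  t1 <- estimate_tg_from_density(d2[d2$omega == 0.1, c("T", "rho")])$tg
  t2 <- estimate_tg_from_density(d2[d2$omega == 0.8, c("T", "rho")])$tg
  expect_lt(t1, t2)
  expect_error(generate_density_curves(c("0.5" = 90), noise_sd = 0),
               "bracket")
})

test_that("generator outputs satisfy topology invariants and round-trip I/O", {
  gens <- list(
    generate_gas_configuration(n_thal = 1, n_water = 3, box = box(c(30, 30, 30)),
                               seed = 1),
    generate_hydrated_trehalose(1, 1, box = box(c(30, 30, 30)), seed = 1),
    generate_clustered_configuration(c(2, 1), box = box(c(60, 60, 60)), seed = 1),
    generate_telegraph_hbond_trajectory(
      telegraph_spec(0.5, 0.5, n_pairs = 4, dt = 0.1, n_steps = 3), seed = 1)
  )
  for (tr in gens) {
    expect_silent(validate_topology(tr$topology))
    path <- tempfile(fileext = ".xyz")
    write_trajectory(tr, path)
    back <- read_trajectory(path, tr$topology)
    expect_equal(back$coords, tr$coords, tolerance = 1e-6)
  }
})
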