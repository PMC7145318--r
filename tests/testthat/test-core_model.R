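test_that("minimum-image displacement handles wrap, identity and random pairs", {
  bx <- box(c(20, 20, 20))
  # wrap case: 0.1L vs 0.9L -> separation 0.2L
  d <- minimum_image_displacement(c(2, 0, 0), c(18, 0, 0), bx)
  expect_equal(sqrt(sum(d^2)), 4)
  expect_equal(minimum_image_displacement(c(5, 5, 5), c(5, 5, 5), bx), c(0, 0, 0))
  expect_error(minimum_image_displacement(c(NA, 0, 0), c(0, 0, 0), bx),
               "non-finite")
  # components always in [-L/2, L/2)
  set.seed(42)
  for (rep_ in 1:5) {
    L <- runif(3, 4, 30)
    a <- matrix(runif(300) * 3 * rep(L, each = 100) - rep(L, each = 100), 100, 3)
    b <- matrix(runif(300) * 3 * rep(L, each = 100) - rep(L, each = 100), 100, 3)
    d <- minimum_image_displacement(a, b, box(L))
    expect_true(all(d >= rep(-L / 2, each = 100) - 1e-12))
    expect_true(all(d < rep(L / 2, each = 100) + 1e-12))
  }
})

test_that("minimum image equals 27-image brute force on random pairs", {
  set.seed(7)
  L <- c(20, 20, 20)
  for (i in 1:1000) {
    a <- runif(3, 0, L); b <- runif(3, 0, L)
    expect_equal(as.numeric(minimum_image_displacement(a, b, box(L))),
                 oracle_min_image(a, b, L), tolerance = 1e-12)
  }
  # anisotropic box
  L <- c(7, 13, 29)
  for (i in 1:200) {
    a <- runif(3, 0, L); b <- runif(3, 0, L)
    expect_equal(as.numeric(minimum_image_displacement(a, b, box(L))),
                 oracle_min_image(a, b, L), tolerance = 1e-12)
  }
  # invariance under lattice translations of either argument
  for (i in 1:50) {
    a <- runif(3, 0, L); b <- runif(3, 0, L)
    k <- sample(-3:3, 3, replace = TRUE)
    expect_equal(
      as.numeric(minimum_image_displacement(a + k * L, b, box(L))),
      as.numeric(minimum_image_displacement(a, b, box(L))), tolerance = 1e-9)
  }
})

test_that("composition arithmetic reproduces the mixture grid", {
  expect_equal(composition_builder(1500, 0)$n_thal, 0)
  expect_equal(composition_builder(1500, 0)$omega, 0)
  top_grid <- composition_builder(1500, 0.760)
  expect_equal(top_grid$n_thal, 250)
  expect_equal(top_grid$omega, 0.760, tolerance = 1e-3)
  expect_equal(composition_builder(1500, 0.112)$n_thal, 10)
  expect_error(composition_builder(1500, 1), "omega_target")
  # monotone in the target
  targets <- seq(0, 0.95, by = 0.01)
  counts <- vapply(targets, function(w) composition_builder(1500, w)$n_thal, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("site selection filters by type and label", {
  top <- water_topology(25)
  expect_length(select_sites(top, "WATER", "Ow"), 25)
  expect_length(select_sites(top, "WATER", "Hw"), 50)
  top10 <- thal_topology(10)
  expect_length(select_sites(top10, "THAL", "O1"), 20)  # two rings each
  expect_length(select_sites(top10, "THAL", "Ob"), 10)
  expect_length(select_sites(top10, "WATER", "Ow"), 0)
  expect_error(select_sites(top10, "THAL", "Zz"), "valid tokens")
  expect_error(select_sites(top10, "GAS", "Ob"), "molecule type")
  # selections come back sorted
  s <- select_sites(top10, "THAL", c("O1", "O2", "Ob"))
  expect_true(all(diff(s) > 0))
})

test_that("topology invariants are enforced", {
  expect_error(topology("O", "Ow", 0L, "THAL"), "WATER")
  expect_error(topology("O", "O1", 0L, "WATER"), "THAL")
  expect_error(topology("O", "Qq", 0L, "OTHER"), "site label")
  expect_error(topology("O", "X", 0L, "OTHER", mass = -1), "mass")
  # a THAL molecule missing its bridging oxygen
  tt <- thal_template()
  drop <- which(tt$site_label == "Ob")
  expect_error(topology(tt$element[-drop], tt$site_label[-drop], 0L, "THAL",
                        ring = tt$ring[-drop]),
               "multiplicities")
})

test_that("trajectory XYZ and PDB round trips preserve order, boxes, coords", {
  g <- generate_gas_configuration(n_thal = 1, n_water = 5, n_particles = 3,
                                  box = box(c(25, 30, 35)), seed = 10)
  for (fmt in c("xyz", "pdb")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_trajectory(g, path)
    g2 <- read_trajectory(path, g$topology)
    tol <- if (fmt == "xyz") 1e-6 else 1e-3
    expect_equal(g2$coords, g$coords, tolerance = tol)
    expect_equal(g2$boxes, g$boxes, tolerance = 1e-3)
    expect_equal(n_frames(g2), 1)
  }
  # multi-frame round trip
  multi <- stack_frames(lapply(1:4, function(s)
    generate_gas_configuration(n_water = 4, box = box(c(20, 20, 20)), seed = s)))
  path <- tempfile(fileext = ".xyz")
  write_trajectory(multi, path)
  m2 <- read_trajectory(path, multi$topology)
  expect_equal(m2$coords, multi$coords, tolerance = 1e-6)
  expect_equal(m2$times, multi$times)
})

test_that("trajectory parsing errors name the offending frame", {
  g <- generate_gas_configuration(n_water = 2, box = box(c(20, 20, 20)), seed = 1)
  path <- tempfile(fileext = ".xyz")
  write_trajectory(g, path)
  expect_error(read_trajectory(path, water_topology(3)), "frame 1")
  # box record stripped from the comment line
  lines <- readLines(path)
  lines[2] <- "no box here"
  writeLines(lines, path)
  expect_error(read_trajectory(path, g$topology), "box")
  expect_error(read_trajectory("/nonexistent/file.xyz", g$topology), "no such")
})

test_that("empty trajectories write and read back as zero frames", {
  top <- water_topology(2)
  empty <- trajectory(top, array(0, c(6, 3, 0)), numeric(0), matrix(1, 0, 3))
  path <- tempfile(fileext = ".xyz")
  write_trajectory(empty, path)
  back <- read_trajectory(path, top)
  expect_equal(n_frames(back), 0)
})

test_that("PDB CRYST1 carries the box", {
  g <- generate_gas_configuration(n_water = 2, box = box(c(30, 30, 30)), seed = 1)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(g, path)
  expect_true(any(grepl("^CRYST1   30.000   30.000   30.000", readLines(path))))
  g2 <- read_trajectory(path, g$topology)
  expect_equal(g2$boxes[1, ], c(30, 30, 30))
})

test_that("topology sidecar round-trips", {
  top <- thal_topology(2)
  path <- tempfile(fileext = ".tsv")
  write_topology(top, path)
  top2 <- read_topology(path)
  expect_equal(as.data.frame(top2), as.data.frame(top))
})
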