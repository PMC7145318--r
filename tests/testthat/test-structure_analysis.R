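test_that("RDF of two fixed particles occupies exactly the right bin", {
  top <- bind_topologies(rep(list(template_topology(particle_template(),
                                                    "OTHER")), 2))
  coords <- rbind(c(10, 10, 10), c(15, 10, 10))
  tr <- trajectory(top, array(coords, c(2, 3, 1)), 0, c(100, 100, 100))
  rdf <- compute_rdf(tr, 0L, 1L, r_max = 10, bin_width = 0.05)
  occ <- which(rdf$g > 0)
  expect_length(occ, 1)
  expect_true(abs(rdf$r[occ] - 5.0) <= 0.025 + 1e-12)
  expect_error(compute_rdf(tr, integer(0), 1L), "empty")
  expect_error(compute_rdf(tr, 0L, 1L, r_max = 80), "half")
})

test_that("ideal-gas RDF normalizes to one and N(r) matches uniform density", {
  frames <- lapply(1:12, function(s)
    generate_gas_configuration(n_particles = 1200, box = box(c(30, 30, 30)),
                               seed = 100 + s, min_dist = 0))
  tr <- stack_frames(frames)
  sel <- select_sites(tr$topology, "OTHER", "X")
  rdf <- compute_rdf(tr, sel, sel, r_max = 10, bin_width = 0.1)
  far <- rdf$r >= 3
  expect_lt(mean(abs(rdf$g[far] - 1)), 0.02)
  # invariant: mean g over [3, r_max] within 3 standard errors of 1
  expect_lt(abs(mean(rdf$g[far]) - 1), 3 * stats::sd(rdf$g[far]) /
              sqrt(sum(far)))
  # running integral against the analytic uniform expectation
  rho <- 1200 / 30^3
  for (rc in c(4, 6, 8)) {
    expect_equal(compute_running_integral(rdf, rc),
                 rho * 4 / 3 * pi * rc^3, tolerance = 0.02)
  }
  expect_equal(compute_running_integral(rdf, 0), 0)
  expect_error(compute_running_integral(rdf, 12), "range")
})

test_that("hydrated-fixture running integrals equal the construction truth", {
  h <- generate_hydrated_trehalose(2, 2, d_hb = 2.8, box = box(c(60, 60, 60)),
                                   seed = 3)
  ow <- select_sites(h$topology, "WATER", "Ow")
  xyz <- h$coords[, , 1]
  for (lab in c("O1", "O2", "O3", "O4")) {
    sa <- select_sites(h$topology, "THAL", lab)
    rdf <- compute_rdf(h, sa, ow, r_max = 6, bin_width = 0.05)
    n35 <- compute_running_integral(rdf, 3.5)
    expect_equal(n35, 2.0, tolerance = 0.01)
    # brute-force neighbour count oracle, within 1%
    direct <- mean(vapply(sa + 1L, function(i) {
      sum(vapply(ow + 1L, function(j)
        oracle_min_dist(xyz[i, ], xyz[j, ], c(60, 60, 60)) <= 3.5,
        logical(1)))
    }, numeric(1)))
    expect_equal(n35, direct, tolerance = 0.01)
  }
})

test_that("CDF: aligned molecules pile into the 0-degree bin, mass is unit", {
  tt <- thal_template(140)
  top <- thal_topology(6)
  set.seed(1)
  coords <- do.call(rbind, lapply(1:6, function(i)
    sweep(tt$coords, 2, runif(3) * 40 + 10, "+")))
  tr <- trajectory(top, array(coords, c(nrow(coords), 3, 1)), 0, c(60, 60, 60))
  cdf <- compute_cdf_distance_angle(tr, r_max = 25)
  expect_equal(sum(cdf$mass), 1, tolerance = 1e-9)
  phi_marginal <- colSums(cdf$mass)
  expect_equal(phi_marginal[[1]], 1, tolerance = 1e-9)
})

test_that("CDF: isotropic orientations follow the sine law", {
  g <- generate_gas_configuration(n_thal = 50, box = box(c(110, 110, 110)),
                                  seed = 8)
  cdf <- compute_cdf_distance_angle(g, r_max = 50, keep_samples = TRUE)
  expect_equal(sum(cdf$mass), 1, tolerance = 1e-9)
  phi <- cdf$samples$phi
  expect_gt(length(phi), 300)
  ks <- suppressWarnings(stats::ks.test(phi, function(q)
    1 - cos(pmin(pmax(q, 0), 90) * pi / 180)))
  expect_gt(ks$p.value, 0.01)
})

test_that("CDF r-marginal peaks where the site-site RDF peaks", {
  tr <- generate_clustered_configuration(c(8, 8), link_distance = 5.5,
                                         box = box(c(70, 70, 70)), seed = 6)
  cdf <- compute_cdf_distance_angle(tr, r_max = 8, bins = c(32, 18))
  ob <- select_sites(tr$topology, "THAL", "Ob")
  rdf <- compute_rdf(tr, ob, ob, r_max = 8, bin_width = 0.25)
  r_cdf <- cdf$r[which.max(rowSums(cdf$mass))]
  r_rdf <- rdf$r[which.max(rdf$g)]
  expect_lt(abs(r_cdf - r_rdf), 0.5)
})

test_that("dihedral distribution recovers the template inter-ring angle", {
  for (target in c(60, 140, -100)) {
    g <- generate_gas_configuration(n_thal = 4, box = box(c(80, 80, 80)),
                                    seed = 21, dihedral = target)
    dh <- compute_dihedral_distribution(g, bin_width = 2)
    mode_angle <- dh$angle[which.max(dh$density)]
    expect_lt(abs(ang_diff_deg(mode_angle, target)), 2.01)
    # every sample equals the construction angle (rigid molecules)
    expect_true(all(abs(ang_diff_deg(dh$samples, target)) < 1e-6))
    # and matches the independent dihedral formula
    top <- g$topology
    xyz <- g$coords[, , 1]
    quad_idx <- vapply(c("Oe/1", "C1/1", "Ob", "C1/2"), function(tok) {
      which(top$molecule_id == 0 &
              top$site_label == sub("/.*", "", tok) &
              (if (grepl("/", tok)) top$ring == as.integer(sub(".*/", "", tok))
               else TRUE))[1]
    }, 0L)
    expect_equal(oracle_dihedral(xyz[quad_idx[1], ], xyz[quad_idx[2], ],
                                 xyz[quad_idx[3], ], xyz[quad_idx[4], ]),
                 dh$samples[1], tolerance = 1e-8)
  }
  # ambiguous label demands ring qualification
  g <- generate_gas_configuration(n_thal = 2, box = box(c(60, 60, 60)), seed = 1)
  expect_error(compute_dihedral_distribution(g, quad = c("Oe", "C1", "Ob", "C1/2")),
               "ring-qualified")
})

test_that("SDF mass balance and localisation around hydroxyl sites", {
  h <- generate_hydrated_trehalose(1, 1, d_hb = 2.8, box = box(c(30, 30, 30)),
                                   seed = 3)
  align <- c("C1/1", "C3/1", "C5/1", "C1/2", "C3/2", "C5/2")
  ow <- select_sites(h$topology, "WATER", "Ow")
  sdf <- compute_sdf(h, "THAL", align, ow, grid_spacing = 0.5, extent = 12)
  # total mass equals the mean target count inside the extent (all 8 waters)
  expect_equal(sum(sdf$density) * 0.5^3, 8, tolerance = 0.01)
  # occupied voxels sit near hydroxyl-oxygen body-frame positions
  top <- h$topology
  xyz <- h$coords[, , 1]
  align_rows <- sort(unlist(lapply(align, function(s)
    which(top$molecule_id == 0 & top$site_label == sub("/.*", "", s) &
            top$ring == as.integer(sub(".*/", "", s))))))
  oh_rows <- which(top$molecule_id == 0 & top$site_label %in%
                     c("O1", "O2", "O3", "O4"))
  # body frame equals the canonical frame here (single molecule, one frame)
  can <- sdf$reference_frame
  centroid <- colMeans(xyz[align_rows, ])
  occ <- which(sdf$density > 0, arr.ind = TRUE)
  centers <- (occ - 0.5) * sdf$spacing + matrix(sdf$origin, nrow(occ), 3,
                                                byrow = TRUE)
  oh_body <- sweep(xyz[oh_rows, ], 2, centroid)
  # rotation is identity up to the Kabsch fit of the molecule onto itself
  dmin <- vapply(seq_len(nrow(centers)), function(i)
    min(sqrt(rowSums(sweep(oh_body, 2, centers[i, ])^2))), numeric(1))
  expect_true(all(dmin < 3.5 + sdf$spacing))
  # empty target selection gives a zero grid
  sdf0 <- compute_sdf(h, "THAL", align, integer(0), grid_spacing = 1, extent = 6)
  expect_equal(sum(sdf0$density), 0)
  # collinear alignment atoms are rejected
  lin_top <- topology(element = rep("X", 3), site_label = "X",
                      molecule_id = 0L, molecule_type = "OTHER")
  lin <- trajectory(lin_top, array(cbind(0:2, 0, 0), c(3, 3, 1)), 0,
                    c(20, 20, 20))
  expect_error(compute_sdf(lin, "OTHER", c("X", "X", "X"), integer(0)),
               "collinear")
})
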