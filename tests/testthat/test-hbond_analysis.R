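# hand-built pair of waters with controllable O...O distance and donor angle
water_pair_frame <- function(d, angle_deg) {
  top <- water_topology(2)
  roh <- 0.9572
  a <- angle_deg * pi / 180
  coords <- rbind(
    c(0, 0, 0),                                   # donor Ow
    roh * c(cos(a), sin(a), 0),                   # donor H at the given angle
    roh * c(cos(2.2), sin(2.2), 0),               # second H, far off axis
    c(d, 0, 0),                                   # acceptor Ow
    c(d + roh, 0, 0), c(d + roh * 0.3, roh, 0))   # acceptor H's point away
  trajectory(top, array(coords, c(6, 3, 1)), 0, c(50, 50, 50))
}

test_that("geometric criteria gate detection, boundaries inclusive", {
  crit <- hbond_criteria(3.5, 60)
  cases <- list(list(2.8, 10, TRUE), list(3.6, 10, FALSE), list(3.0, 75, FALSE),
                list(3.5, 10, TRUE),    # distance boundary inclusive
                list(2.8, 60, TRUE),    # angle boundary inclusive
                list(2.8, 60.5, FALSE))
  for (cs in cases) {
    tr <- water_pair_frame(cs[[1]], cs[[2]])
    hb <- detect_hbonds(get_frame(tr, 1), tr$topology, crit)
    expect_equal(nrow(hb) == 1, cs[[3]],
                 info = sprintf("d=%.1f angle=%.1f", cs[[1]], cs[[2]]))
    if (nrow(hb)) {
      expect_equal(hb$class, "WW")
      expect_equal(hb$d, cs[[1]], tolerance = 1e-9)
      expect_equal(hb$angle, cs[[2]], tolerance = 1e-6)
    }
  }
})

test_that("criteria constructor and donor-topology errors", {
  expect_error(hbond_criteria(-1, 60), "d_max")
  expect_error(hbond_criteria(3.5, 200), "d_max|angle")
  # hydroxyl oxygen without its hydrogen is rejected
  top <- topology(element = c("O", "H", "O"), site_label = c("Ow", "Hw", "Ow"),
                  molecule_id = c(0L, 0L, 1L), molecule_type = "WATER")
  tr <- trajectory(top, array(rbind(c(0, 0, 0), c(0.96, 0, 0), c(3, 0, 0)),
                              c(3, 3, 1)), 0, c(20, 20, 20))
  expect_error(detect_hbonds(get_frame(tr, 1), top), "without attached")
})

test_that("detection equals the brute-force triple-loop oracle", {
  set.seed(31)
  for (rep_ in 1:4) {
    L <- c(24, 24, 24)
    g <- generate_gas_configuration(n_thal = rep_ %% 2, n_water = 40 + 5 * rep_,
                                    box = box(L), seed = 300 + rep_,
                                    min_dist = 2.4)
    xyz <- g$coords[, , 1]
    for (ua in c(TRUE, FALSE)) {
      hb <- detect_hbonds(get_frame(g, 1), g$topology, unique_acceptor = ua)
      hb <- hb[order(hb$donor_o, hb$hydrogen, hb$acceptor_o), ]
      or <- oracle_hbonds(xyz, g$topology, L, unique_acceptor = ua)
      expect_equal(nrow(hb), nrow(or))
      if (nrow(hb)) {
        expect_equal(hb$donor_o, or$donor_o)
        expect_equal(hb$hydrogen, or$hydrogen)
        expect_equal(hb$acceptor_o, or$acceptor_o)
        expect_equal(hb$d, or$d, tolerance = 1e-9)
      }
    }
  }
})

test_that("enlarging the cutoffs never loses bonds; Ob/Oe excluded by default", {
  g <- generate_gas_configuration(n_thal = 2, n_water = 30,
                                  box = box(c(26, 26, 26)), seed = 77,
                                  min_dist = 2.4)
  fr <- get_frame(g, 1)
  n_base <- nrow(detect_hbonds(fr, g$topology, hbond_criteria(3.0, 40),
                               unique_acceptor = FALSE))
  for (crit in list(hbond_criteria(3.2, 40), hbond_criteria(3.0, 70),
                    hbond_criteria(3.5, 60))) {
    expect_gte(nrow(detect_hbonds(fr, g$topology, crit,
                                  unique_acceptor = FALSE)), n_base)
  }
  # re-enabling ring oxygens can only add acceptors
  a <- nrow(detect_hbonds(fr, g$topology))
  b <- nrow(detect_hbonds(fr, g$topology, include_ring_oxygens = TRUE))
  expect_gte(b, a)
  expect_false(any(detect_hbonds(fr, g$topology)$acceptor_o %in%
                     select_sites(g$topology, "THAL", c("Ob", "Oe"))))
})

test_that("census totals and per-molecule averages follow the class rules", {
  # hydrated fixture: 10 THAL, 2 waters per hydroxyl -> WT total 160
  h <- generate_hydrated_trehalose(10, 2, d_hb = 2.8, box = box(c(80, 80, 80)),
                                   seed = 13)
  cen <- census(h)
  wt_tw <- sum(cen$summary$mean_total[cen$summary$class %in% c("WT", "TW")])
  expect_equal(wt_tw, 160)
  expect_equal(cen$summary$per_molecule[cen$summary$class == "WT"], 16)
  # pure gas with no contacts: all classes zero
  far <- generate_gas_configuration(n_water = 8, box = box(c(60, 60, 60)),
                                    seed = 2, min_dist = 6)
  cen0 <- census(far)
  expect_true(all(cen0$summary$mean_total == 0))
  # no THAL present: THAL classes reported absent rather than zero-divided
  expect_false(any(c("WT", "TW", "TT") %in% cen0$summary$class))
  # bonded water dimer: WW per-molecule average 1.0 (1 bond x 2 / 2 molecules)
  dim_ <- water_pair_frame(2.9, 5)
  cw <- census(dim_)
  expect_equal(cw$summary$per_molecule[cw$summary$class == "WW"], 1.0)
  # THAL-THAL stacked dimer: every hydroxyl donates to its translated twin
  tt <- thal_template(140)
  top2 <- thal_topology(2)
  coords <- rbind(sweep(tt$coords, 2, c(30, 30, 30), "+"),
                  sweep(tt$coords, 2, c(30, 30, 32.9), "+"))
  trj <- trajectory(top2, array(coords, c(62, 3, 1)), 0, c(60, 60, 60))
  ct <- census(trj)
  expect_equal(ct$summary$mean_total[ct$summary$class == "TT"], 8)
  expect_equal(ct$summary$per_molecule[ct$summary$class == "TT"], 8)
})

test_that("census is invariant under molecule relabelling", {
  g <- generate_gas_configuration(n_water = 30, box = box(c(22, 22, 22)),
                                  seed = 55, min_dist = 2.4)
  cen <- census(g)
  # reverse the molecule order (atoms permuted consistently)
  top <- g$topology
  perm <- order(-top$molecule_id, top$atom_index)
  top2 <- top[perm, ]
  top2$molecule_id <- max(top$molecule_id) - top2$molecule_id
  top2$atom_index <- seq_len(nrow(top2)) - 1L
  class(top2) <- class(top)
  tr2 <- trajectory(top2, array(g$coords[perm, , 1], c(nrow(top2), 3, 1)),
                    0, c(22, 22, 22))
  cen2 <- census(tr2)
  expect_equal(cen2$summary$mean_total, cen$summary$mean_total)
})
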