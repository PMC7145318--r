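#' Random gas-phase configuration
#'
#' Places rigid molecules with centres uniform in the box and orientations
#' uniform over rotations, resampling on steric clash (minimum intermolecular
#' heavy-atom distance below `min_dist`). Molecules are kept whole: the
#' centre is wrapped into the box, atoms may protrude; all analyses use
#' minimum-image geometry.
#'
#' @param n_thal,n_water,n_particles molecule counts per type (particles are
#'   single-site OTHER molecules).
#' @param box a [box()].
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @param min_dist minimum intermolecular heavy-atom distance (Angstrom).
#' @param max_retries placement attempts per molecule before giving up.
#' @param dihedral inter-ring dihedral for disaccharide templates (degrees).
#' @return a single-frame [trajectory()].
#' @export
generate_gas_configuration <- function(n_thal = 0, n_water = 0, n_particles = 0,
                                       box, seed = NULL, min_dist = 2.0,
                                       max_retries = 500, dihedral = 140) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.numeric(box)
  tmpls <- c(rep(list(list(t = thal_template(dihedral), type = "THAL")), n_thal),
             rep(list(list(t = water_template(), type = "WATER")), n_water),
             rep(list(list(t = particle_template(), type = "OTHER")), n_particles))
  tops <- lapply(tmpls, function(m) template_topology(m$t, m$type))
  top <- bind_topologies(tops)
  if (!length(tmpls)) {
    return(trajectory(top, array(0, c(0, 3, 1)), 0, matrix(L, 1, 3)))
  }
  placed <- matrix(numeric(0), 0, 3)  # heavy atoms already placed
  coords <- vector("list", length(tmpls))
  for (i in seq_along(tmpls)) {
    tm <- tmpls[[i]]$t
    heavy <- tm$element != "H"
    ok <- FALSE
    for (try_ in seq_len(max_retries)) {
      center <- stats::runif(3) * L
      xyz <- sweep(tm$coords %*% t(random_rotation()), 2, center, "+")
      if (nrow(placed)) {
        dmin <- min(mic_distance_matrix(xyz[heavy, , drop = FALSE], placed, L))
        if (dmin < min_dist) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("packing failed after ", max_retries,
           " retries; use a larger box or fewer molecules", call. = FALSE)
    }
    coords[[i]] <- xyz
    placed <- rbind(placed, xyz[heavy, , drop = FALSE])
  }
  xyz <- do.call(rbind, coords)
  trajectory(top, array(xyz, c(nrow(xyz), 3, 1)), 0, matrix(L, 1, 3))
}

#' Hydrated-disaccharide fixture with exact solvation counts
#'
#' Builds `n_thal` rigid pseudo-disaccharides on a lattice and decorates
#' every hydroxyl oxygen (O1-O4, both rings) with exactly `waters_per_site`
#' water molecules at donor distance `d_hb`, oriented so that the water
#' donates a hydrogen bond satisfying the geometric criteria (O...O <= 3.5
#' Angstrom, donor angle <= 60 degrees). The construction is verified: each
#' hydroxyl oxygen must end up with exactly `waters_per_site` water oxygens
#' within 3.5 Angstrom, and an error is raised otherwise.
#'
#' @param n_thal number of disaccharide molecules.
#' @param waters_per_site waters placed per hydroxyl oxygen (0-3).
#' @param d_hb donor-acceptor oxygen distance (Angstrom), in (2.4, 3.5).
#' @param box a [box()].
#' @param seed integer RNG seed.
#' @param n_extra_water additional waters placed as gas, kept >= 4 Angstrom
#'   from everything.
#' @param dihedral template inter-ring dihedral (degrees).
#' @return a single-frame [trajectory()].
#' @export
generate_hydrated_trehalose <- function(n_thal, waters_per_site = 2, d_hb = 2.8,
                                        box, seed = NULL, n_extra_water = 0,
                                        dihedral = 140) {
  if (!is.null(seed)) set.seed(seed)
  if (d_hb <= 2.4 || d_hb >= 3.5) stop("d_hb must lie in (2.4, 3.5)", call. = FALSE)
  if (waters_per_site < 0 || waters_per_site > 3) {
    stop("waters_per_site must be 0-3", call. = FALSE)
  }
  L <- as.numeric(box)
  tmpl <- thal_template(dihedral)
  clearance <- 2 * (max(sqrt(rowSums(tmpl$coords^2))) + d_hb + 2) + 2
  per_axis <- pmax(1L, floor(L / clearance))
  if (prod(per_axis) < n_thal) {
    stop("box too small for ", n_thal, " well-separated molecules ",
         "(need spacing ", round(clearance, 1), " Angstrom)", call. = FALSE)
  }
  wt <- water_template()
  roh <- sqrt(sum(wt$coords[2, ]^2))
  # candidate directions per site: a cone around the outward radial vector
  # (tilt beta, azimuth gamma); a greedy pass keeps, per site, the placements
  # clearest of every other disaccharide oxygen and previously placed waters
  cone_angles <- expand.grid(beta = c(0, 20, 35, 50, 65, 80),
                             gamma = seq(0, 330, by = 30))
  cone_angles <- cone_angles[!(cone_angles$beta == 0 & cone_angles$gamma > 0), ]

  slots <- as.matrix(expand.grid(x = seq_len(per_axis[1]), y = seq_len(per_axis[2]),
                                 z = seq_len(per_axis[3])))[seq_len(n_thal), , drop = FALSE]
  centers <- sweep(slots - 0.5, 2, L / per_axis, "*")

  tops <- list(); coords <- list(); k <- 0L
  ring_centers <- rbind(colMeans(tmpl$coords[tmpl$ring == 1L, ][1:6, ]),
                        colMeans(tmpl$coords[tmpl$ring == 2L, ][1:6, ]))
  ring_normals <- local({
    nrm <- matrix(0, 2, 3)
    for (r in 1:2) {
      cs <- tmpl$coords[tmpl$ring == r, ][1:3, ]
      v1 <- cs[2, ] - cs[1, ]; v2 <- cs[3, ] - cs[1, ]
      n_ <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      nrm[r, ] <- n_ / sqrt(sum(n_^2))
    }
    nrm
  })

  oh_idx <- which(tmpl$site_label %in% HYDROXYL_LABELS)
  ox_idx <- which(tmpl$element == "O")
  # choose, once per site, the water directions in the template frame
  site_dirs <- vector("list", length(oh_idx))
  placed_local <- matrix(numeric(0), 0, 3)
  for (jj in seq_along(oh_idx)) {
    j <- oh_idx[jj]
    r_ <- tmpl$ring[j]
    u <- tmpl$coords[j, ] - ring_centers[r_, ]
    u <- u / sqrt(sum(u^2))
    nrm <- ring_normals[r_, ]
    tang <- c(u[2] * nrm[3] - u[3] * nrm[2], u[3] * nrm[1] - u[1] * nrm[3],
              u[1] * nrm[2] - u[2] * nrm[1])
    tang <- tang / sqrt(sum(tang^2))
    cand <- t(apply(cone_angles, 1, function(a) {
      b <- a[["beta"]] * pi / 180; g <- a[["gamma"]] * pi / 180
      cos(b) * u + sin(b) * (cos(g) * nrm + sin(g) * tang)
    }))
    ow_cand <- sweep(cand * d_hb, 2, tmpl$coords[j, ], "+")
    other_ox <- tmpl$coords[setdiff(ox_idx, j), , drop = FALSE]
    # per-candidate static feasibility: clear of every other sugar oxygen,
    # clear of waters already assigned to earlier sites, and outside the
    # site's own Ho donor cone (60 deg plus margin)
    d_ox <- vapply(seq_len(nrow(ow_cand)), function(ci)
      min(sqrt(rowSums(sweep(other_ox, 2, ow_cand[ci, ])^2))), numeric(1))
    d_prev <- if (nrow(placed_local)) {
      vapply(seq_len(nrow(ow_cand)), function(ci)
        min(sqrt(rowSums(sweep(placed_local, 2, ow_cand[ci, ])^2))),
        numeric(1))
    } else rep(Inf, nrow(ow_cand))
    ho_j <- which(tmpl$site_label == "Ho" & tmpl$ring == r_)
    ho_near <- ho_j[which.min(rowSums(sweep(tmpl$coords[ho_j, , drop = FALSE],
                                            2, tmpl$coords[j, ])^2))]
    ho_dir <- tmpl$coords[ho_near, ] - tmpl$coords[j, ]
    ho_dir <- ho_dir / sqrt(sum(ho_dir^2))
    own_angle_ok <- as.numeric(cand %*% ho_dir) < cos(62 * pi / 180)
    feas <- which(d_ox >= 3.55 & d_prev >= 2.2 & own_angle_ok)
    feas <- feas[order(-d_ox[feas])]
    # backtracking pick of waters_per_site mutually separated candidates
    pick <- function(sel, remaining) {
      if (length(sel) == waters_per_site) return(sel)
      for (ci in remaining) {
        if (length(sel) &&
            min(sqrt(rowSums(sweep(ow_cand[sel, , drop = FALSE], 2,
                                   ow_cand[ci, ])^2))) < 2.2) next
        res <- pick(c(sel, ci), setdiff(remaining, ci))
        if (!is.null(res)) return(res)
      }
      NULL
    }
    sel <- pick(integer(0), feas)
    if (is.null(sel)) {
      stop("steric failure: cannot place ", waters_per_site,
           " waters at site ", tmpl$site_label[j],
           " clear of other oxygens", call. = FALSE)
    }
    placed_local <- rbind(placed_local, ow_cand[sel, , drop = FALSE])
    site_dirs[[jj]] <- cand[sel, , drop = FALSE]
  }

  for (i in seq_len(n_thal)) {
    rot <- random_rotation()
    mol_xyz <- sweep(tmpl$coords %*% t(rot), 2, centers[i, ], "+")
    k <- k + 1L; tops[[k]] <- template_topology(tmpl, "THAL"); coords[[k]] <- mol_xyz
    for (jj in seq_along(oh_idx)) {
      j <- oh_idx[jj]
      r_ <- tmpl$ring[j]
      nrm <- ring_normals[r_, ]
      dirs <- site_dirs[[jj]]
      for (s in seq_len(nrow(dirs))) {
        v <- dirs[s, ]
        ow_local <- tmpl$coords[j, ] + d_hb * v
        hw1_local <- ow_local - roh * v                 # points back at the site O
        # second H: perpendicular to v, opened to the H-O-H angle
        perp <- nrm - sum(nrm * v) * v
        if (sqrt(sum(perp^2)) < 1e-8) {
          u0 <- tmpl$coords[j, ] - ring_centers[r_, ]
          perp <- u0 - sum(u0 * v) * v
        }
        perp <- perp / sqrt(sum(perp^2))
        ang <- 104.52 * pi / 180
        hw2_local <- ow_local + roh * (cos(ang) * (-v) + sin(ang) * perp)
        wat_local <- rbind(ow_local, hw1_local, hw2_local)
        wat_xyz <- sweep(wat_local %*% t(rot), 2, centers[i, ], "+")
        k <- k + 1L
        tops[[k]] <- template_topology(wt, "WATER")
        coords[[k]] <- wat_xyz
      }
    }
  }

  top <- bind_topologies(tops)
  xyz <- do.call(rbind, coords)

  if (n_extra_water > 0) {
    for (e in seq_len(n_extra_water)) {
      ok <- FALSE
      for (try_ in 1:500) {
        center <- stats::runif(3) * L
        wxyz <- sweep(wt$coords %*% t(random_rotation()), 2, center, "+")
        if (min(mic_distance_matrix(wxyz, xyz, L)) >= 4.0) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place extra waters >= 4 Angstrom from solute",
                    call. = FALSE)
      top <- bind_topologies(list(top, template_topology(wt, "WATER")))
      xyz <- rbind(xyz, wxyz)
    }
  }

  traj <- trajectory(top, array(xyz, c(nrow(xyz), 3, 1)), 0, matrix(L, 1, 3))
  # construction check: exact solvation counts
  oh <- select_sites(top, "THAL", HYDROXYL_LABELS)
  ow <- select_sites(top, "WATER", "Ow")
  if (length(oh) && length(ow)) {
    dm <- mic_distance_matrix(xyz[oh + 1L, , drop = FALSE],
                              xyz[ow + 1L, , drop = FALSE], L)
    cnt <- rowSums(dm <= 3.5)
    if (any(cnt != waters_per_site)) {
      stop("steric failure: hydroxyl solvation counts are not exact; ",
           "use a larger box", call. = FALSE)
    }
  }
  traj
}

#' Clustered / percolating disaccharide configuration
#'
#' Arranges molecules in chains whose consecutive bridging oxygens (Ob) are
#' `spacing` apart (below `link_distance`) while distinct chains stay more
#' than `2 * link_distance` apart. With `percolating = TRUE` the first
#' cluster is a chain whose Ob sites are equally spaced across the full box
#' x-length, so its ends connect through the periodic boundary.
#'
#' @param cluster_sizes integer vector of cluster sizes.
#' @param link_distance adjacency cutoff the construction targets (Angstrom).
#' @param box a [box()].
#' @param percolating logical; make the first cluster span the box in x.
#' @param seed integer RNG seed.
#' @return a single-frame [trajectory()] of THAL molecules.
#' @export
generate_clustered_configuration <- function(cluster_sizes, link_distance = 5.5,
                                             box, percolating = FALSE,
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(cluster_sizes) || any(cluster_sizes < 1)) {
    stop("cluster_sizes must be positive", call. = FALSE)
  }
  L <- as.numeric(box)
  tmpl <- thal_template()
  ob_local <- tmpl$coords[tmpl$site_label == "Ob", ]
  spacing <- 0.9 * link_distance
  sep <- 2 * link_distance + 2

  ob_positions <- list()
  row_y <- sep
  for (ci in seq_along(cluster_sizes)) {
    n <- cluster_sizes[ci]
    if (percolating && ci == 1L) {
      s <- L[1] / n
      if (s > link_distance) {
        stop("percolating chain needs ", n, " members with spacing <= ",
             link_distance, " over Lx = ", L[1], call. = FALSE)
      }
      ob_positions[[ci]] <- cbind((seq_len(n) - 1) * s, 2.0, 2.0)
    } else {
      if ((n - 1) * spacing + sep > L[1]) {
        stop("cluster of ", n, " does not fit the box x-length", call. = FALSE)
      }
      if (row_y + sep > L[2]) stop("too many clusters for the box y-length",
                                   call. = FALSE)
      ob_positions[[ci]] <- cbind(2.0 + (seq_len(n) - 1) * spacing, row_y, 2.0)
      row_y <- row_y + sep
    }
  }
  ob_all <- do.call(rbind, ob_positions)
  n_mol <- nrow(ob_all)
  tops <- vector("list", n_mol); coords <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    rot <- random_rotation()
    xyz <- sweep(sweep(tmpl$coords, 2, ob_local) %*% t(rot), 2, ob_all[i, ], "+")
    tops[[i]] <- template_topology(tmpl, "THAL")
    coords[[i]] <- xyz
  }
  top <- bind_topologies(tops)
  xyz <- do.call(rbind, coords)
  trajectory(top, array(xyz, c(nrow(xyz), 3, 1)), 0, matrix(L, 1, 3))
}

#' Brownian (overdamped) trajectories with known diffusion coefficients
#'
#' Each molecule performs independent Gaussian steps with per-axis variance
#' `2 * D * dt`. Unwrapped positions are retained in the trajectory's
#' `unwrapped` channel; mean-square displacements must be computed from it.
#' WATER and OTHER species are single-site molecules; THAL molecules are
#' full rigid templates translated as a unit.
#'
#' @param n_by_species named integer vector, e.g. `c(WATER = 200, THAL = 20)`.
#' @param D_by_species named numeric vector of diffusion coefficients
#'   (Angstrom^2/ps) with the same names.
#' @param dt time step (ps).
#' @param n_steps number of steps (trajectory has `n_steps + 1` frames).
#' @param box a [box()].
#' @param seed integer RNG seed.
#' @return a [trajectory()] with `unwrapped` coordinates attached.
#' @export
generate_brownian_trajectory <- function(n_by_species, D_by_species, dt, n_steps,
                                         box, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dt <= 0 || n_steps < 1) stop("dt and n_steps must be positive", call. = FALSE)
  if (is.null(names(n_by_species)) ||
      !all(names(n_by_species) %in% MOLECULE_TYPES)) {
    stop("n_by_species must be named with molecule types ",
         paste(MOLECULE_TYPES, collapse = "/"), call. = FALSE)
  }
  if (any(is.na(D_by_species[names(n_by_species)])) ||
      any(D_by_species < 0)) {
    stop("D_by_species must supply a non-negative D for every species",
         call. = FALSE)
  }
  L <- as.numeric(box)
  tops <- list(); locals <- list(); dvec <- numeric(0); k <- 0L
  for (sp in names(n_by_species)) {
    tmpl <- if (sp == "THAL") thal_template() else {
      t_ <- particle_template()
      if (sp == "WATER") t_$site_label <- "X"
      t_
    }
    for (i in seq_len(n_by_species[[sp]])) {
      k <- k + 1L
      tops[[k]] <- template_topology(tmpl, sp)
      locals[[k]] <- tmpl$coords
      dvec[k] <- D_by_species[[sp]]
    }
  }
  top <- bind_topologies(tops)
  n_mol <- k
  n_fr <- n_steps + 1L
  centers0 <- matrix(stats::runif(n_mol * 3), n_mol, 3) %*% diag(L)
  sd_step <- sqrt(2 * dvec * dt)
  local_all <- do.call(rbind, locals)
  mol_of_atom <- top$molecule_id + 1L
  # cumulative Gaussian steps, frames x (molecule, axis) columns
  m <- matrix(stats::rnorm(n_fr * n_mol * 3), n_fr, n_mol * 3)
  m[1, ] <- 0
  m <- sweep(m, 2, rep(sd_step, 3), "*")
  m <- apply(m, 2, cumsum)
  m <- m + rep(as.vector(centers0), each = n_fr)
  centers <- aperm(array(m, c(n_fr, n_mol, 3)), c(2, 3, 1))
  rm(m)
  l_arr <- rep(L, each = n_mol)
  wrap_off <- array(0, dim(centers))
  for (f in seq_len(n_fr)) {
    wrap_off[, , f] <- floor(centers[, , f] / l_arr) * l_arr
  }
  unwrapped <- centers[mol_of_atom, , , drop = FALSE] + as.vector(local_all)
  wrapped <- unwrapped - wrap_off[mol_of_atom, , , drop = FALSE]
  rm(centers, wrap_off)
  trajectory(top, wrapped, times = (seq_len(n_fr) - 1) * dt, boxes = L,
             unwrapped = unwrapped)
}

#' Two-state (telegraph) hydrogen-bond kinetics fixtures
#'
#' `telegraph_spec()` describes independent donor-acceptor pairs switching
#' between a bonded geometry (O...O distance `d_bond`, donor angle 0) and a
#' broken geometry (`d_broken`, donor angle 90 degrees, still within the
#' reformation cutoff) as a two-state Markov chain sampled on the frame grid
#' with per-step switching probabilities `1 - exp(-k * dt)`.
#'
#' @param k_forward bond-breaking rate (1/ps).
#' @param k_backward bond-reformation rate (1/ps).
#' @param n_pairs number of independent pairs.
#' @param dt frame spacing (ps).
#' @param n_steps number of frames.
#' @param d_bond,d_broken bonded / broken O...O distances (Angstrom).
#' @return `telegraph_spec`: a list of class `TelegraphSpec`.
#' @export
telegraph_spec <- function(k_forward, k_backward, n_pairs, dt, n_steps,
                           d_bond = 2.8, d_broken = 3.2) {
  if (k_forward <= 0 || k_backward <= 0) stop("rates must be > 0", call. = FALSE)
  if (dt <= 0 || n_steps < 2 || n_pairs < 1) {
    stop("need dt > 0, n_steps >= 2, n_pairs >= 1", call. = FALSE)
  }
  if (d_broken > 3.5 || d_broken <= d_bond) {
    stop("broken geometry must keep the pair within the 3.5 Angstrom cutoff",
         call. = FALSE)
  }
  structure(list(k_forward = k_forward, k_backward = k_backward,
                 n_pairs = as.integer(n_pairs), dt = dt,
                 n_steps = as.integer(n_steps),
                 d_bond = d_bond, d_broken = d_broken),
            class = "TelegraphSpec")
}

# simulate the hidden 0/1 state series: n_steps x n_pairs matrix
telegraph_states <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_stat <- spec$k_backward / (spec$k_forward + spec$k_backward)
  q_f <- 1 - exp(-spec$k_forward * spec$dt)
  q_b <- 1 - exp(-spec$k_backward * spec$dt)
  h <- matrix(0L, spec$n_steps, spec$n_pairs)
  s <- as.integer(stats::runif(spec$n_pairs) < p_stat)
  h[1, ] <- s
  for (t_ in 2:spec$n_steps) {
    u <- stats::runif(spec$n_pairs)
    s <- ifelse(s == 1L, as.integer(u >= q_f), as.integer(u < q_b))
    h[t_, ] <- s
  }
  h
}

#' @rdname telegraph_spec
#' @param spec a `TelegraphSpec`.
#' @param seed integer RNG seed.
#' @return `telegraph_population_series`: a [bond_population_series()] built
#'   directly from the hidden states (all pairs always within the reformation
#'   cutoff).
#' @export
telegraph_population_series <- function(spec, seed = NULL) {
  h <- telegraph_states(spec, seed)
  bond_population_series(h = h, present = NULL, dt = spec$dt, class = "WW")
}

#' @rdname telegraph_spec
#' @return `generate_telegraph_hbond_trajectory`: a [trajectory()] of water
#'   pairs whose geometry realizes the states; the hidden state matrix is
#'   attached as attribute `bond_states` and the donor-O/H/acceptor-O atom
#'   indices (0-based) as attribute `pair_atoms`.
#' @export
generate_telegraph_hbond_trajectory <- function(spec, seed = NULL) {
  h <- telegraph_states(spec, seed)
  wt <- water_template()
  roh <- sqrt(sum(wt$coords[2, ]^2))
  n_pairs <- spec$n_pairs
  # lattice of pairs, 10 Angstrom apart; box grows with pair count
  per_axis <- ceiling(n_pairs^(1 / 3))
  L <- rep(10 * per_axis + 10, 3)
  slots <- as.matrix(expand.grid(x = seq_len(per_axis), y = seq_len(per_axis),
                                 z = seq_len(per_axis)))[seq_len(n_pairs), , drop = FALSE]
  origins <- (slots - 0.5) * 10

  top <- bind_topologies(rep(list(template_topology(wt, "WATER")), 2L * n_pairs))
  n_at <- nrow(top)
  n_fr <- spec$n_steps
  coords <- array(0, c(n_at, 3, n_fr))
  # per pair: donor water atoms rows 1:3, acceptor water rows 4:6
  base_idx <- (seq_len(n_pairs) - 1L) * 6L
  for (f in seq_len(n_fr)) {
    bonded <- h[f, ] == 1L
    d_oo <- ifelse(bonded, spec$d_bond, spec$d_broken)
    # donor Ow at origin; acceptor Ow at +x, d_oo away
    xyz <- matrix(0, n_at, 3)
    xyz[base_idx + 1L, ] <- origins
    # donor H1: along +x when bonded (angle 0), along +y when broken (90 deg)
    h1_off <- cbind(ifelse(bonded, roh, 0), ifelse(bonded, 0, roh), 0)
    xyz[base_idx + 2L, ] <- origins + h1_off
    xyz[base_idx + 3L, ] <- origins + matrix(rep(c(-roh * 0.5, -roh * 0.866, 0),
                                                 each = n_pairs), ncol = 3)
    xyz[base_idx + 4L, ] <- origins + cbind(d_oo, 0, 0)
    # acceptor hydrogens point away from the donor
    xyz[base_idx + 5L, ] <- origins + cbind(d_oo + roh, 0, 0)
    xyz[base_idx + 6L, ] <- origins + cbind(d_oo + roh * 0.5, roh * 0.866, 0)
    coords[, , f] <- xyz
  }
  traj <- trajectory(top, coords, times = (seq_len(n_fr) - 1) * spec$dt,
                     boxes = L)
  attr(traj, "bond_states") <- h
  attr(traj, "pair_atoms") <- cbind(donor_o = base_idx, hydrogen = base_idx + 1L,
                                    acceptor_o = base_idx + 3L)
  traj
}

#' Synthetic density-temperature curves with prescribed maxima
#'
#' Generates, per composition, \eqn{\rho(T) = \rho_0(\omega) - c (T -
#' T_g(\omega))^2 + \epsilon} with Gaussian noise, so that the noiseless
#' maximum sits exactly at the prescribed glass-transition temperature.
#'
#' @param tg_by_omega named numeric vector: names are THAL mass fractions,
#'   values the prescribed Tg (K).
#' @param temperatures temperature grid (K); must bracket every Tg with at
#'   least two points on each side.
#' @param curvature quadratic coefficient (g/cm^3/K^2).
#' @param noise_sd Gaussian noise s.d. (g/cm^3).
#' @param seed integer RNG seed.
#' @param rho0 function omega -> peak density (g/cm^3).
#' @return data.frame with columns `omega`, `T`, `rho`.
#' @export
generate_density_curves <- function(tg_by_omega,
                                    temperatures = standard_temperature_grid(),
                                    curvature = 5e-6, noise_sd = 0.001,
                                    seed = NULL,
                                    rho0 = function(w) 1.0 + 0.58 * w) {
  if (!is.null(seed)) set.seed(seed)
  omegas <- as.numeric(names(tg_by_omega))
  if (any(is.na(omegas))) stop("tg_by_omega must be named by omega", call. = FALSE)
  temperatures <- sort(temperatures)
  out <- vector("list", length(tg_by_omega))
  for (i in seq_along(tg_by_omega)) {
    tg <- tg_by_omega[[i]]
    if (sum(temperatures < tg) < 2 || sum(temperatures > tg) < 2) {
      stop("temperature grid must bracket Tg = ", tg,
           " with >= 2 points on each side", call. = FALSE)
    }
    rho <- rho0(omegas[i]) - curvature * (temperatures - tg)^2 +
      stats::rnorm(length(temperatures), sd = noise_sd)
    out[[i]] <- data.frame(omega = omegas[i], T = temperatures, rho = rho)
  }
  do.call(rbind, out)
}

#' Simulation temperature grid
#'
#' The ten production temperatures used for the density / Tg analyses.
#' @return numeric vector of temperatures (K).
#' @export
standard_temperature_grid <- function() {
  c(100, 150, 180, 200, 230, 270, 310, 340, 370, 400)
}
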