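# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops, explicit image enumeration, direct
# formulas. They are the reference the implementation is checked against.

# minimum-image displacement by enumerating all 27 image translations
oracle_min_image <- function(a, b, L) {
  best <- NULL; best_d <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    v <- a - b + c(ix, iy, iz) * L
    if (sqrt(sum(v^2)) < best_d) { best_d <- sqrt(sum(v^2)); best <- v }
  }
  best
}

oracle_min_dist <- function(a, b, L) sqrt(sum(oracle_min_image(a, b, L)^2))

# minimum-image displacements from one point to many, by enumerating the 27
# image translations explicitly (independent of the analytic fold)
oracle_min_image_many <- function(targets, origin, L) {
  shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  best <- sweep(targets, 2, origin)
  best_d <- rowSums(best^2)
  for (s in seq_len(nrow(shifts))) {
    v <- sweep(sweep(targets, 2, shifts[s, ] * L, "+"), 2, origin)
    d2 <- rowSums(v^2)
    imp <- d2 < best_d
    best[imp, ] <- v[imp, , drop = FALSE]
    best_d[imp] <- d2[imp]
  }
  best
}

# H-bond detection: explicit loop over donor hydrogens x acceptor oxygens
oracle_hbonds <- function(xyz, top, L, d_max = 3.5, angle_max = 60,
                          include_ring_oxygens = FALSE,
                          unique_acceptor = TRUE) {
  hs <- which(top$site_label %in% c("Ho", "Hw"))
  acc_labels <- c("Ow", "O1", "O2", "O3", "O4",
                  if (include_ring_oxygens) c("Ob", "Oe"))
  acc <- which(top$site_label %in% acc_labels)
  recs <- list()
  for (h in hs) {
    # attached donor oxygen: nearest intramolecular O
    cand <- which(top$element == "O" & top$molecule_id == top$molecule_id[h])
    dd <- vapply(cand, function(o) oracle_min_dist(xyz[h, ], xyz[o, ], L), 0)
    o_d <- cand[which.min(dd)]
    ok_acc <- acc[top$molecule_id[acc] != top$molecule_id[o_d]]
    if (!length(ok_acc)) next
    v2 <- oracle_min_image_many(xyz[ok_acc, , drop = FALSE], xyz[o_d, ], L)
    d_oo <- sqrt(rowSums(v2^2))
    v1 <- oracle_min_image(xyz[h, ], xyz[o_d, ], L)
    ct <- as.numeric(v2 %*% v1) / (d_oo * sqrt(sum(v1^2)))
    ang <- acos(pmax(-1, pmin(1, ct))) * 180 / pi
    hit <- which(d_oo <= d_max & ang <= angle_max)
    if (!length(hit)) next
    df <- data.frame(donor_o = o_d - 1L, hydrogen = h - 1L,
                     acceptor_o = ok_acc[hit] - 1L,
                     d = d_oo[hit], angle = ang[hit])
    if (unique_acceptor) df <- df[which.min(df$d), , drop = FALSE]
    recs[[length(recs) + 1L]] <- df
  }
  if (!length(recs)) {
    return(data.frame(donor_o = integer(0), hydrogen = integer(0),
                      acceptor_o = integer(0)))
  }
  out <- do.call(rbind, recs)
  out[order(out$donor_o, out$hydrogen, out$acceptor_o), ]
}

# cluster partition + percolation on a 3x3x3 replicated supercell (igraph)
oracle_clusters <- function(site_pos, L, cutoff) {
  n <- nrow(site_pos)
  shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  rep_pos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    sweep(site_pos, 2, shifts[s, ] * L, "+")))
  rep_mol <- rep(seq_len(n), times = nrow(shifts))
  d <- as.matrix(stats::dist(rep_pos))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # two molecules cluster together iff any of their images share a component
  part <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(part[i])) next
    cl <- cl + 1L
    comps_i <- unique(comp[rep_mol == i])
    members <- unique(rep_mol[comp %in% comps_i])
    # expand transitively
    repeat {
      comps2 <- unique(comp[rep_mol %in% members])
      members2 <- unique(rep_mol[comp %in% comps2])
      if (length(members2) == length(members)) break
      members <- members2
    }
    part[members] <- cl
  }
  # a cluster percolates iff two distinct images of one molecule connect
  perc <- vapply(seq_len(max(part)), function(cl_id) {
    mols <- which(part == cl_id)
    any(vapply(mols, function(m) {
      any(duplicated(comp[rep_mol == m]))
    }, logical(1)))
  }, logical(1))
  list(partition = part, percolating = perc)
}

# naive double-loop MSD over all origins for a lag set
oracle_msd <- function(pos, lags) {
  # pos: n_mol x 3 x n_frames
  nf <- dim(pos)[3]; nm <- dim(pos)[1]
  vapply(lags, function(lag) {
    tot <- 0; cnt <- 0
    for (t0 in seq_len(nf - lag)) {
      for (m in seq_len(nm)) {
        tot <- tot + sum((pos[m, , t0 + lag] - pos[m, , t0])^2)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }, numeric(1))
}

# plain double-loop energy decomposition
oracle_energy <- function(xyz, top, L, cutoff) {
  f_c <- 1.602176634e-19^2 * 6.02214076e23 /
    (4 * pi * 8.8541878128e-12 * 1e-10) / 1000
  e <- c(E_ww = 0, E_wt = 0, E_tt = 0, E_other = 0)
  n <- nrow(top)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (top$molecule_id[i] == top$molecule_id[j]) next
    r <- oracle_min_dist(xyz[i, ], xyz[j, ], L)
    if (r > cutoff) next
    sij <- (top$lj_sigma[i] + top$lj_sigma[j]) / 2
    eij <- sqrt(top$lj_epsilon[i] * top$lj_epsilon[j])
    u <- if (eij > 0) 4 * eij * ((sij / r)^12 - (sij / r)^6) else 0
    u <- u + f_c * top$charge[i] * top$charge[j] / r
    ti <- top$molecule_type[i]; tj <- top$molecule_type[j]
    cl <- if (ti == "WATER" && tj == "WATER") "E_ww"
    else if (ti == "THAL" && tj == "THAL") "E_tt"
    else if ((ti == "WATER" && tj == "THAL") ||
             (ti == "THAL" && tj == "WATER")) "E_wt"
    else "E_other"
    e[cl] <- e[cl] + u
  }
  e
}

# independent dihedral: angle between half-plane projections about the axis
oracle_dihedral <- function(p1, p2, p3, p4) {
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  w1 <- (p1 - p2) - sum((p1 - p2) * axis) * axis
  w2 <- (p4 - p3) - sum((p4 - p3) * axis) * axis
  ang <- acos(max(-1, min(1, sum(w1 * w2) /
                            sqrt(sum(w1^2) * sum(w2^2))))) * 180 / pi
  s <- sum(axis * c(w1[2] * w2[3] - w1[3] * w2[2],
                    w1[3] * w2[1] - w1[1] * w2[3],
                    w1[1] * w2[2] - w1[2] * w2[1]))
  if (s < 0) -ang else ang
}

# smallest signed angular difference in degrees
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# stack single-frame configurations (same topology) into one trajectory
stack_frames <- function(trajs) {
  coords <- array(0, c(n_atoms(trajs[[1]]), 3, length(trajs)))
  for (i in seq_along(trajs)) coords[, , i] <- trajs[[i]]$coords[, , 1]
  trajectory(trajs[[1]]$topology, coords, times = seq_along(trajs) - 1,
             boxes = trajs[[1]]$boxes[rep(1, length(trajs)), , drop = FALSE])
}
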