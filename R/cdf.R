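#' Combined distance-angle distribution function
#'
#' For every ordered intermolecular pair of molecules of `molecule_type`
#' whose `dist_sites` minimum-image separation is at most `r_max`,
#' accumulates the joint histogram of that distance and the acute angle
#' (0-90 degrees) between the two molecules' internal vectors. Used to
#' detect relative orientation, e.g. ring stacking: the vector joining two
#' opposite ring carbons against the bridging-oxygen separation.
#'
#' @param traj a [trajectory()].
#' @param dist_sites length-2 character vector of site labels for the
#'   distance (one per molecule of the pair), e.g. `c("Ob", "Ob")`.
#' @param vec_a,vec_b length-2 character vectors naming the atom pair whose
#'   difference defines each molecule's vector (labels may be
#'   ring-qualified, e.g. `c("C1/1", "C4/1")`).
#' @param molecule_type molecule type of the pairs (default THAL).
#' @param r_max distance range (Angstrom).
#' @param bins length-2 integer vector `(n_r, n_phi)`.
#' @param keep_samples also return the raw `(r, phi)` samples (for
#'   distributional tests).
#' @return list of class `CDFResult`: `r` and `phi` bin centres, `mass`
#'   matrix (n_r x n_phi) normalized to unit total mass, sample count, and
#'   (optionally) a `samples` data.frame.
#' @export
compute_cdf_distance_angle <- function(traj, dist_sites = c("Ob", "Ob"),
                                       vec_a = c("C1/1", "C4/1"),
                                       vec_b = c("C1/1", "C4/1"),
                                       molecule_type = "THAL",
                                       r_max = 12, bins = c(60, 45),
                                       keep_samples = FALSE) {
  top <- traj$topology
  mols <- unique(top$molecule_id[top$molecule_type == molecule_type])
  if (length(mols) < 2) stop("need at least two molecules of type ",
                             molecule_type, call. = FALSE)
  resolve1 <- function(m, token) {
    idx <- resolve_label_in_molecule(top, m, token)
    if (length(idx) != 1) {
      stop("label '", token, "' matches ", length(idx), " atoms in molecule ",
           m, "; use ring-qualified labels like 'C1/1'", call. = FALSE)
    }
    idx + 1L
  }
  ds_a <- vapply(mols, resolve1, 0L, token = dist_sites[1])
  ds_b <- vapply(mols, resolve1, 0L, token = dist_sites[2])
  va <- cbind(vapply(mols, resolve1, 0L, token = vec_a[1]),
              vapply(mols, resolve1, 0L, token = vec_a[2]))
  vb <- cbind(vapply(mols, resolve1, 0L, token = vec_b[1]),
              vapply(mols, resolve1, 0L, token = vec_b[2]))
  n_r <- bins[1]; n_phi <- bins[2]
  mass <- matrix(0, n_r, n_phi)
  r_edges <- seq(0, r_max, length.out = n_r + 1)
  phi_edges <- seq(0, 90, length.out = n_phi + 1)
  n_mol <- length(mols)
  dropped <- 0L
  samples <- if (keep_samples) list() else NULL
  for (f in seq_len(n_frames(traj))) {
    L <- traj$boxes[f, ]
    xyz <- traj$coords[, , f, drop = TRUE]
    uvec_a <- minimum_image_displacement(xyz[va[, 2], , drop = FALSE],
                                         xyz[va[, 1], , drop = FALSE], L)
    uvec_b <- minimum_image_displacement(xyz[vb[, 2], , drop = FALSE],
                                         xyz[vb[, 1], , drop = FALSE], L)
    na_ <- sqrt(rowSums(uvec_a^2)); nb_ <- sqrt(rowSums(uvec_b^2))
    if (any(na_ < 1e-9) || any(nb_ < 1e-9)) {
      dropped <- dropped + sum(na_ < 1e-9 | nb_ < 1e-9)
    }
    dm <- mic_distance_matrix(xyz[ds_a, , drop = FALSE],
                              xyz[ds_b, , drop = FALSE], L)
    diag(dm) <- Inf
    hit <- which(dm <= r_max, arr.ind = TRUE)
    if (!nrow(hit)) next
    ok <- na_[hit[, 1]] >= 1e-9 & nb_[hit[, 2]] >= 1e-9
    hit <- hit[ok, , drop = FALSE]
    if (!nrow(hit)) next
    ct <- abs(rowSums(uvec_a[hit[, 1], , drop = FALSE] *
                        uvec_b[hit[, 2], , drop = FALSE])) /
      (na_[hit[, 1]] * nb_[hit[, 2]])
    phi <- acos(pmin(1, ct)) * 180 / pi
    if (keep_samples) samples[[length(samples) + 1L]] <-
      data.frame(r = dm[hit], phi = phi)
    ir <- pmin(n_r, pmax(1L, findInterval(dm[hit], r_edges,
                                          rightmost.closed = TRUE)))
    ip <- pmin(n_phi, pmax(1L, findInterval(phi, phi_edges,
                                            rightmost.closed = TRUE)))
    inc <- table(factor(ir, levels = seq_len(n_r)),
                 factor(ip, levels = seq_len(n_phi)))
    mass <- mass + unclass(inc)
  }
  if (dropped) warning(dropped, " molecule vectors had near-zero length and were skipped")
  total <- sum(mass)
  if (total > 0) mass <- mass / total
  structure(list(r = (r_edges[-1] + r_edges[-(n_r + 1)]) / 2,
                 phi = (phi_edges[-1] + phi_edges[-(n_phi + 1)]) / 2,
                 mass = mass, n_pairs_binned = total,
                 samples = if (keep_samples) do.call(rbind, samples)),
            class = "CDFResult")
}

#' Dihedral angle distribution over a trajectory
#'
#' Computes the standard signed dihedral of four labelled sites in every
#' molecule of `molecule_type` in every frame (minimum-image consistent
#' within the molecule) and histograms it over (-180, 180] degrees. Labels
#' duplicated across the two rings must be ring-qualified ("Oe/1", "C1/2");
#' an ambiguous label raises an error.
#'
#' @param traj a [trajectory()].
#' @param quad four site labels, e.g. `c("Oe/1", "C1/1", "Ob", "C1/2")` --
#'   the torsion around the glycosidic bridge.
#' @param bin_width bin width in degrees.
#' @param molecule_type molecule type carrying the sites.
#' @return list of class `DihedralResult`: `angle` bin centres, `density`
#'   (probability density per degree), `samples` (all dihedrals, degrees),
#'   `mean` and `circular_sd` (degrees).
#' @export
compute_dihedral_distribution <- function(traj,
                                          quad = c("Oe/1", "C1/1", "Ob", "C1/2"),
                                          bin_width = 2,
                                          molecule_type = "THAL") {
  if (length(quad) != 4) stop("quad must name four sites", call. = FALSE)
  top <- traj$topology
  mols <- unique(top$molecule_id[top$molecule_type == molecule_type])
  if (!length(mols)) stop("no molecules of type ", molecule_type, call. = FALSE)
  rows <- t(vapply(mols, function(m) {
    vapply(quad, function(token) {
      idx <- resolve_label_in_molecule(top, m, token)
      if (length(idx) != 1) {
        stop("label '", token, "' matches ", length(idx),
             " atoms in molecule ", m,
             "; use ring-qualified labels like 'C1/1'", call. = FALSE)
      }
      idx + 1L
    }, 0L)
  }, integer(4)))
  samples <- numeric(0)
  for (f in seq_len(n_frames(traj))) {
    L <- traj$boxes[f, ]
    xyz <- traj$coords[, , f, drop = TRUE]
    for (m in seq_len(nrow(rows))) {
      p <- xyz[rows[m, ], , drop = FALSE]
      # rebuild the quad contiguously across the boundary
      for (k in 2:4) {
        p[k, ] <- p[k - 1, ] + minimum_image_displacement(p[k, ], p[k - 1, ], L)
      }
      samples <- c(samples, signed_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]))
    }
  }
  edges <- seq(-180, 180, by = bin_width)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  h <- graphics::hist(samples, breaks = edges, plot = FALSE)
  # circular mean / sd via the mean resultant length
  rad <- samples * pi / 180
  cm <- mean(cos(rad)); sm <- mean(sin(rad))
  rbar <- sqrt(cm^2 + sm^2)
  structure(list(angle = h$mids, density = h$density, samples = samples,
                 mean = atan2(sm, cm) * 180 / pi,
                 circular_sd = sqrt(pmax(0, -2 * log(rbar))) * 180 / pi),
            class = "DihedralResult")
}
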