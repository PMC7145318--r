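#' Spatial distribution function in a reference molecule's body frame
#'
#' For every frame and every molecule of `reference_type`, the atoms named in
#' `align_sites` are superposed (least-squares rigid body, Kabsch) onto the
#' canonical body frame defined by the first reference molecule in the first
#' frame. Target-site positions (taken as the nearest periodic image to the
#' reference molecule) are mapped into that frame and accumulated on a cubic
#' grid; the result is a number density per cubic Angstrom per
#' reference-molecule-frame sample.
#'
#' @param traj a [trajectory()].
#' @param reference_type molecule type of the reference molecules.
#' @param align_sites character vector (>= 3 labels, optionally
#'   ring-qualified like "C1/1") of non-collinear alignment atoms.
#' @param target_sites 0-based atom indices of target sites
#'   (see [select_sites()]).
#' @param grid_spacing voxel edge (Angstrom).
#' @param extent half-width of the cubic grid (Angstrom); grid spans
#'   `[-extent, extent]` per axis.
#' @return list of class `SDFResult`: `density` (3-D array, 1/Angstrom^3),
#'   `origin`, `spacing`, `n_samples`, and `reference_frame` (canonical
#'   align-site coordinates).
#' @export
compute_sdf <- function(traj, reference_type, align_sites, target_sites,
                        grid_spacing = 0.5, extent = 10) {
  top <- traj$topology
  ref_mols <- unique(top$molecule_id[top$molecule_type == reference_type])
  if (!length(ref_mols)) stop("no molecules of type ", reference_type, call. = FALSE)
  if (length(align_sites) < 3) stop("need >= 3 alignment sites", call. = FALSE)
  align_of <- lapply(ref_mols, function(m) {
    idx <- unlist(lapply(align_sites, function(s)
      resolve_label_in_molecule(top, m, s)))
    sort(idx) + 1L
  })
  n_align <- length(align_of[[1]])
  if (n_align < 3 || any(vapply(align_of, length, 0L) != n_align)) {
    stop("alignment sites must resolve to the same >= 3 atoms per molecule",
         call. = FALSE)
  }
  nvox <- max(1L, ceiling(2 * extent / grid_spacing))
  density <- array(0, c(nvox, nvox, nvox))
  origin <- -extent
  tgt <- target_sites + 1L

  # canonical frame: first reference molecule, first frame, made whole and
  # centred on its alignment centroid
  whole <- function(xyz, rows, L) {
    anchor <- xyz[rows[1], ]
    sweep(mic_disp_to_point(xyz[rows, , drop = FALSE], anchor, L), 2, anchor, "+")
  }
  L1 <- traj$boxes[1, ]
  can <- whole(traj$coords[, , 1, drop = TRUE], align_of[[1]], L1)
  can <- sweep(can, 2, colMeans(can))
  sv <- svd(can)$d
  if (sv[2] < 1e-6 * sv[1]) {
    stop("alignment atoms are collinear; pick a non-degenerate site set",
         call. = FALSE)
  }

  n_samples <- 0L
  for (f in seq_len(n_frames(traj))) {
    L <- traj$boxes[f, ]
    xyz <- traj$coords[, , f, drop = TRUE]
    for (mi in seq_along(ref_mols)) {
      rows <- align_of[[mi]]
      mv <- whole(xyz, rows, L)
      fit <- kabsch(mv, can)
      centroid <- colMeans(mv)
      n_samples <- n_samples + 1L
      t_rows <- tgt[top$molecule_id[tgt] != ref_mols[mi]]
      if (!length(t_rows)) next
      rel <- mic_disp_to_point(xyz[t_rows, , drop = FALSE], centroid, L)
      body <- sweep((sweep(rel, 2, centroid, "+")) %*% fit$rotation, 2,
                    fit$translation, "+")
      iv <- floor((body - origin) / grid_spacing) + 1
      keep <- iv[, 1] >= 1 & iv[, 1] <= nvox & iv[, 2] >= 1 & iv[, 2] <= nvox &
        iv[, 3] >= 1 & iv[, 3] <= nvox
      iv <- iv[keep, , drop = FALSE]
      if (nrow(iv)) {
        lin <- (iv[, 3] - 1) * nvox * nvox + (iv[, 2] - 1) * nvox + iv[, 1]
        tab <- tabulate(lin, nbins = nvox^3)
        density <- density + array(tab, dim(density))
      }
    }
  }
  density <- density / (n_samples * grid_spacing^3)
  structure(list(density = density, origin = rep(origin, 3),
                 spacing = grid_spacing, n_samples = n_samples,
                 reference_frame = can),
            class = "SDFResult")
}

#' Write an SDF grid in Gaussian cube format
#'
#' @param sdf an `SDFResult`.
#' @param path output path.
#' @export
write_cube <- function(sdf, path) {
  nv <- dim(sdf$density)[1]
  bohr <- 1 / 0.529177210903
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("sugartraj spatial distribution function",
               "density in 1/Angstrom^3"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 0,
                     sdf$origin[1] * bohr, sdf$origin[2] * bohr,
                     sdf$origin[3] * bohr), con)
  for (k in 1:3) {
    v <- c(0, 0, 0); v[k] <- sdf$spacing * bohr
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nv, v[1], v[2], v[3]), con)
  }
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    vals <- sdf$density[i, j, ]
    writeLines(paste(sprintf("%12.5e", vals), collapse = " "), con)
  }
  invisible(path)
}
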