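#' Geometric hydrogen-bond criteria
#'
#' A donor-H...acceptor triple counts as a hydrogen bond when the
#' donor-oxygen to acceptor-oxygen minimum-image distance is at most `d_max`
#' and the angle at the donor oxygen between its O-H bond and the O...O
#' vector is at most `angle_max` (both inclusive). The simulations these
#' analyses target used 3.5 Angstrom and 60 degrees. The donor-centred angle
#' convention is deliberate: a 60 degree cut is only geometrically sensible
#' for the H-O(donor)-O(acceptor) angle (the D-H...A angle convention is cut
#' near 120-180 degrees); the convention is recorded in results metadata.
#'
#' @param d_max donor-acceptor oxygen distance cutoff (Angstrom).
#' @param angle_max donor-centred angle cutoff (degrees).
#' @return list of class `HBondCriteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_max = 60) {
  if (d_max <= 0 || angle_max <= 0 || angle_max > 180) {
    stop("need d_max > 0 and angle_max in (0, 180]", call. = FALSE)
  }
  structure(list(d_max = d_max, angle_max = angle_max,
                 angle_convention = "H-Odonor-Oacceptor"),
            class = "HBondCriteria")
}

# donor table: one row per (donor O, attached H); attachment by nearest
# intramolecular oxygen within 1.2 Angstrom of each polar hydrogen
donor_table <- function(xyz, top, L) {
  h_idx <- which(top$site_label %in% c("Ho", "Hw"))
  if (!length(h_idx)) {
    return(data.frame(o = integer(0), h = integer(0)))
  }
  o_all <- which(top$element == "O")
  o_owner <- integer(length(h_idx))
  for (i in seq_along(h_idx)) {
    hi <- h_idx[i]
    cand <- o_all[top$molecule_id[o_all] == top$molecule_id[hi]]
    if (!length(cand)) {
      stop("polar hydrogen atom ", top$atom_index[hi],
           " has no oxygen in its molecule", call. = FALSE)
    }
    d <- sqrt(rowSums(mic_disp_to_point(xyz[cand, , drop = FALSE],
                                        xyz[hi, ], L)^2))
    j <- which.min(d)
    if (d[j] > 1.2) {
      stop("polar hydrogen atom ", top$atom_index[hi],
           " has no covalently attached oxygen (nearest O at ",
           round(d[j], 2), " Angstrom)", call. = FALSE)
    }
    o_owner[i] <- cand[j]
  }
  # every hydroxyl oxygen must own at least one hydrogen
  oh_idx <- which(top$site_label %in% c(HYDROXYL_LABELS, "Ow"))
  orphan <- setdiff(oh_idx, o_owner)
  if (length(orphan)) {
    stop("hydroxyl/water oxygen(s) without attached hydrogen: atom index ",
         paste(top$atom_index[orphan], collapse = ", "), call. = FALSE)
  }
  data.frame(o = o_owner, h = h_idx)
}

#' Detect hydrogen bonds in one frame
#'
#' Donors are oxygens carrying a polar hydrogen (water Ow, hydroxyl O1-O4);
#' acceptors are water and hydroxyl oxygens. The bridging (Ob) and ring (Oe)
#' oxygens are excluded as acceptors by default, reflecting their steric
#' hindrance in the disaccharide; set `include_ring_oxygens = TRUE` to count
#' them. Only intermolecular triples are reported. Each donor hydrogen is
#' matched to at most one acceptor per frame (nearest acceptor wins); set
#' `unique_acceptor = FALSE` to report every qualifying triple.
#'
#' @param frame a `Frame` from [get_frame()].
#' @param top the [topology()].
#' @param criteria an [hbond_criteria()].
#' @param include_ring_oxygens allow Ob/Oe as acceptors.
#' @param unique_acceptor one acceptor per hydrogen (nearest-distance
#'   tie-break).
#' @return data.frame with columns `donor_o`, `hydrogen`, `acceptor_o`
#'   (0-based atom indices), `d` (Angstrom), `angle` (degrees) and `class`
#'   (WW, WT = water donor to THAL, TW = THAL donor to water, TT).
#' @export
detect_hbonds <- function(frame, top, criteria = hbond_criteria(),
                          include_ring_oxygens = FALSE,
                          unique_acceptor = TRUE) {
  xyz <- frame$coordinates
  L <- as.numeric(frame$box)
  don <- donor_table(xyz, top, L)
  acc_labels <- c("Ow", HYDROXYL_LABELS, if (include_ring_oxygens) c("Ob", "Oe"))
  acc <- which(top$site_label %in% acc_labels)
  empty <- data.frame(donor_o = integer(0), hydrogen = integer(0),
                      acceptor_o = integer(0), d = numeric(0),
                      angle = numeric(0), class = character(0))
  if (!nrow(don) || !length(acc)) return(empty)

  d_oo <- mic_distance_matrix(xyz[don$o, , drop = FALSE],
                              xyz[acc, , drop = FALSE], L)
  inter <- outer(top$molecule_id[don$o], top$molecule_id[acc], "!=")
  hits <- which(d_oo <= criteria$d_max & inter, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)

  res <- data.frame(donor_o = don$o[hits[, 1]], hydrogen = don$h[hits[, 1]],
                    acceptor_o = acc[hits[, 2]], d = d_oo[hits])
  res$angle <- vapply(seq_len(nrow(res)), function(i) {
    vertex_angle(xyz[res$hydrogen[i], ], xyz[res$donor_o[i], ],
                 xyz[res$acceptor_o[i], ], L)
  }, numeric(1))
  res <- res[res$angle <= criteria$angle_max, , drop = FALSE]
  if (nrow(res) && unique_acceptor) {
    res <- res[order(res$hydrogen, res$d), , drop = FALSE]
    res <- res[!duplicated(res$hydrogen), , drop = FALSE]
  }
  if (!nrow(res)) return(empty)
  dt_ <- top$molecule_type[res$donor_o]
  at_ <- top$molecule_type[res$acceptor_o]
  res$class <- ifelse(dt_ == "WATER" & at_ == "WATER", "WW",
               ifelse(dt_ == "WATER" & at_ == "THAL", "WT",
               ifelse(dt_ == "THAL" & at_ == "WATER", "TW",
               ifelse(dt_ == "THAL" & at_ == "THAL", "TT", "XX"))))
  res$donor_o <- res$donor_o - 1L
  res$hydrogen <- res$hydrogen - 1L
  res$acceptor_o <- res$acceptor_o - 1L
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond census over a trajectory
#'
#' Counts hydrogen bonds per interacting class and frame, then reports
#' frame-averaged totals (mean and s.d.) and per-molecule averages: WT, TW
#' and TT are normalized per THAL molecule, WW per water. A TT bond is
#' counted once in the totals but contributes to both partners in the
#' per-molecule average (factor 2 / n_THAL); the same symmetric convention
#' applies to WW.
#'
#' @param traj a [trajectory()].
#' @param criteria an [hbond_criteria()].
#' @param ... passed to [detect_hbonds()].
#' @return list of class `HBondCensus`: data.frame `summary` with one row
#'   per class (`class`, `mean_total`, `sd_total`, `per_molecule`) and the
#'   per-frame count matrix `per_frame`.
#' @export
census <- function(traj, criteria = hbond_criteria(), ...) {
  if (n_frames(traj) < 1) stop("need at least one frame", call. = FALSE)
  classes <- c("WW", "WT", "TW", "TT")
  counts <- matrix(0, n_frames(traj), 4, dimnames = list(NULL, classes))
  for (f in seq_len(n_frames(traj))) {
    hb <- detect_hbonds(get_frame(traj, f), traj$topology, criteria, ...)
    if (nrow(hb)) {
      tb <- table(factor(hb$class, levels = classes))
      counts[f, ] <- as.numeric(tb)
    }
  }
  top <- traj$topology
  n_thal <- length(unique(top$molecule_id[top$molecule_type == "THAL"]))
  n_water <- length(unique(top$molecule_id[top$molecule_type == "WATER"]))
  mean_total <- colMeans(counts)
  sd_total <- apply(counts, 2, stats::sd)
  per_mol <- c(
    WW = if (n_water) 2 * mean_total[["WW"]] / n_water else NA_real_,
    WT = if (n_thal) mean_total[["WT"]] / n_thal else NA_real_,
    TW = if (n_thal) mean_total[["TW"]] / n_thal else NA_real_,
    TT = if (n_thal) 2 * mean_total[["TT"]] / n_thal else NA_real_
  )
  present <- c(WW = n_water > 0, WT = n_thal > 0 && n_water > 0,
               TW = n_thal > 0 && n_water > 0, TT = n_thal > 0)
  summary <- data.frame(class = classes, mean_total = mean_total,
                        sd_total = sd_total, per_molecule = per_mol[classes],
                        row.names = NULL)
  summary <- summary[present[summary$class], , drop = FALSE]
  structure(list(summary = summary, per_frame = counts,
                 n_thal = n_thal, n_water = n_water,
                 criteria = criteria),
            class = "HBondCensus")
}

#' @export
print.HBondCensus <- function(x, ...) {
  cat(sprintf("Hydrogen-bond census (%d frames; d <= %.2f A, angle <= %.0f deg)\n",
              nrow(x$per_frame), x$criteria$d_max, x$criteria$angle_max))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
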