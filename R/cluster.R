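#' Adjacency criteria for molecular clustering
#'
#' `site_distance_criterion` links two molecules when designated sites are
#' within a cutoff (default: bridging-oxygen Ob-Ob within 6 Angstrom, the
#' first-peak range of the Ob-Ob centre-of-mass proxy RDF).
#' `hbond_criterion` links molecules joined by a hydrogen bond.
#'
#' @param site site label present exactly once per molecule.
#' @param cutoff distance cutoff (Angstrom).
#' @return criterion object for [build_adjacency()].
#' @export
site_distance_criterion <- function(site = "Ob", cutoff = 6.0) {
  structure(list(type = "site_distance", site = site, cutoff = cutoff),
            class = "ClusterCriterion")
}

#' @rdname site_distance_criterion
#' @param criteria an [hbond_criteria()].
#' @export
hbond_criterion <- function(criteria = hbond_criteria()) {
  structure(list(type = "hbond", criteria = criteria),
            class = "ClusterCriterion")
}

#' Build the molecule adjacency list of one frame
#'
#' Emits one edge per molecule pair whose criterion holds under the minimum
#' image, together with the integer image shift realizing the contact: the
#' edge `(i, j, shift)` states that molecule j's image translated by
#' `shift * L` touches molecule i.
#'
#' @param frame a `Frame` from [get_frame()].
#' @param top the [topology()].
#' @param criterion a [site_distance_criterion()] or [hbond_criterion()].
#' @param molecule_type molecules considered (default THAL).
#' @return data.frame with columns `i`, `j` (0-based molecule ids) and
#'   `sx`, `sy`, `sz` (image shift), plus attribute `molecules` listing the
#'   selected molecule ids.
#' @export
build_adjacency <- function(frame, top, criterion = site_distance_criterion(),
                            molecule_type = "THAL") {
  mols <- sort(unique(top$molecule_id[top$molecule_type == molecule_type]))
  L <- as.numeric(frame$box)
  xyz <- frame$coordinates
  empty <- data.frame(i = integer(0), j = integer(0), sx = integer(0),
                      sy = integer(0), sz = integer(0))
  attr(empty, "molecules") <- mols
  if (length(mols) < 2) return(empty)
  if (criterion$type == "site_distance") {
    rows <- vapply(mols, function(m) {
      idx <- resolve_label_in_molecule(top, m, criterion$site)
      if (length(idx) != 1) {
        stop("site '", criterion$site, "' must occur exactly once per molecule",
             call. = FALSE)
      }
      idx + 1L
    }, 0L)
    pos <- xyz[rows, , drop = FALSE]
    dm <- mic_distance_matrix(pos, pos, L)
    dm[lower.tri(dm, diag = TRUE)] <- Inf
    hit <- which(dm <= criterion$cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(empty)
    sh <- mic_image_shift(pos[hit[, 1], , drop = FALSE],
                          pos[hit[, 2], , drop = FALSE], L)
    out <- data.frame(i = mols[hit[, 1]], j = mols[hit[, 2]],
                      sx = sh[, 1], sy = sh[, 2], sz = sh[, 3])
  } else if (criterion$type == "hbond") {
    hb <- detect_hbonds(frame, top, criterion$criteria)
    if (!nrow(hb)) return(empty)
    mi <- top$molecule_id[hb$donor_o + 1L]
    mj <- top$molecule_id[hb$acceptor_o + 1L]
    keep <- mi %in% mols & mj %in% mols & mi != mj
    hb <- hb[keep, , drop = FALSE]; mi <- mi[keep]; mj <- mj[keep]
    if (!nrow(hb)) return(empty)
    sh <- mic_image_shift(xyz[hb$donor_o + 1L, , drop = FALSE],
                          xyz[hb$acceptor_o + 1L, , drop = FALSE], L)
    out <- unique(data.frame(i = mi, j = mj, sx = sh[, 1], sy = sh[, 2],
                             sz = sh[, 3]))
  } else stop("unknown criterion type", call. = FALSE)
  attr(out, "molecules") <- mols
  rownames(out) <- NULL
  out
}

#' Connected components with periodic-image offset propagation
#'
#' Union-find over the adjacency edges, propagating the integer image offset
#' of every molecule relative to its cluster root. A cluster percolates
#' along an axis when some edge closes a cycle whose summed image shifts are
#' non-zero on that axis -- i.e. the aggregate connects to its own periodic
#' image and spans the cell.
#'
#' @param edges edge data.frame from [build_adjacency()].
#' @param molecules integer vector of molecule ids partitioned (defaults to
#'   the `molecules` attribute of `edges`).
#' @return list of class `ClusterSet`: `membership` (data.frame molecule ->
#'   cluster id with image offsets), `clusters` (list of member vectors),
#'   `percolating` (logical matrix clusters x axes), `sizes`.
#' @export
find_clusters <- function(edges, molecules = attr(edges, "molecules")) {
  if (is.null(molecules)) {
    stop("supply the molecule id set (attribute lost?)", call. = FALSE)
  }
  n <- length(molecules)
  parent <- seq_len(n)
  offset <- matrix(0L, n, 3)   # offset of node relative to its parent
  perc <- matrix(FALSE, n, 3)  # percolation flags keyed by root
  find <- function(x) {
    path <- integer(0)
    while (parent[x] != x) { path <- c(path, x); x <- parent[x] }
    acc <- c(0L, 0L, 0L)
    for (p in rev(path)) {
      acc <- acc + offset[p, ]
      offset[p, ] <<- acc
      parent[p] <<- x
    }
    x
  }
  if (nrow(edges)) {
    ei <- match(edges$i, molecules); ej <- match(edges$j, molecules)
    sh <- as.matrix(edges[, c("sx", "sy", "sz")])
    for (e in seq_len(nrow(edges))) {
      ri <- find(ei[e]); rj <- find(ej[e])
      oi <- offset[ei[e], ]; oj <- offset[ej[e], ]
      # edge constraint: o_j - o_i = shift
      if (ri != rj) {
        parent[rj] <- ri
        offset[rj, ] <- oi + sh[e, ] - oj
        perc[ri, ] <- perc[ri, ] | perc[rj, ]
      } else {
        mismatch <- (oi + sh[e, ] - oj) != 0L
        perc[ri, ] <- perc[ri, ] | mismatch
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  cluster_id <- match(root, unique(root))
  membership <- data.frame(molecule = molecules, cluster = cluster_id,
                           ox = offset[, 1], oy = offset[, 2], oz = offset[, 3])
  clusters <- split(molecules, cluster_id)
  perc_by_cluster <- perc[unique(root), , drop = FALSE]
  colnames(perc_by_cluster) <- c("x", "y", "z")
  structure(list(membership = membership, clusters = clusters,
                 percolating = perc_by_cluster,
                 sizes = unname(vapply(clusters, length, 0L))),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d molecules in %d clusters (largest %d)%s\n",
              nrow(x$membership), length(x$clusters), max(x$sizes),
              if (any(x$percolating)) ", percolating" else ""))
  invisible(x)
}

#' Cluster every frame of a trajectory
#'
#' @param traj a [trajectory()].
#' @param criterion a clustering criterion.
#' @param molecule_type molecules considered.
#' @return list of `ClusterSet`, one per frame.
#' @export
cluster_trajectory <- function(traj, criterion = site_distance_criterion(),
                               molecule_type = "THAL") {
  lapply(seq_len(n_frames(traj)), function(f) {
    find_clusters(build_adjacency(get_frame(traj, f), traj$topology,
                                  criterion, molecule_type))
  })
}

#' Cluster-size and percolation statistics
#'
#' @param cs a `ClusterSet` or list of them (one per frame).
#' @return list with `per_frame` data.frame (`frame`, `n_clusters`,
#'   `mean_size`, `largest`, `fraction_largest`, `percolating`) and
#'   trajectory-averaged `summary`.
#' @export
cluster_statistics <- function(cs) {
  if (inherits(cs, "ClusterSet")) cs <- list(cs)
  if (!length(cs)) stop("need at least one frame", call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(cs), function(f) {
    x <- cs[[f]]
    data.frame(frame = f, n_clusters = length(x$clusters),
               mean_size = mean(x$sizes), largest = max(x$sizes),
               fraction_largest = max(x$sizes) / sum(x$sizes),
               percolating = any(x$percolating))
  }))
  summary <- data.frame(
    n_clusters = mean(per$n_clusters), mean_size = mean(per$mean_size),
    largest = mean(per$largest),
    fraction_largest = mean(per$fraction_largest),
    percolation_frequency = mean(per$percolating)
  )
  list(per_frame = per, summary = summary)
}
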