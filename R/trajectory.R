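#' Trajectory container
#'
#' Holds a topology plus an ordered sequence of frames. Coordinates are
#' stored as an `n_atoms x 3 x n_frames` array in Angstrom, box lengths as an
#' `n_frames x 3` matrix and times (ps) as a strictly increasing vector.
#' Generators that know image-consistent positions (Brownian dynamics) attach
#' an `unwrapped` array of the same shape; mean-square displacements must be
#' computed from it, never from wrapped coordinates.
#'
#' @param topology a [topology()].
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single `n x 3`
#'   matrix is promoted to one frame).
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param boxes [box()] object, length-3 vector (constant box) or
#'   `n_frames x 3` matrix.
#' @param unwrapped optional array like `coords` with image-consistent
#'   (unwrapped) positions.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, times, boxes, unwrapped = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array", call. = FALSE)
  }
  n_at <- dim(coords)[1]; n_fr <- dim(coords)[3]
  if (n_at != nrow(topology)) {
    stop(sprintf("coordinate count (%d) does not match topology atom count (%d)",
                 n_at, nrow(topology)), call. = FALSE)
  }
  if (length(times) != n_fr || any(!is.finite(times))) {
    stop("times must be finite, one per frame", call. = FALSE)
  }
  if (n_fr > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (!is.matrix(boxes)) boxes <- matrix(as.numeric(boxes), n_fr, 3, byrow = TRUE)
  if (nrow(boxes) != n_fr || any(boxes <= 0)) {
    stop("boxes must be positive, one row per frame", call. = FALSE)
  }
  if (!is.null(unwrapped) && !identical(dim(unwrapped), dim(coords))) {
    stop("unwrapped array must match coords dimensions", call. = FALSE)
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times),
                 boxes = boxes, unwrapped = unwrapped),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames (%.4g - %.4g ps)%s\n",
              n_atoms(x), n_frames(x),
              if (n_frames(x)) x$times[1] else NA,
              if (n_frames(x)) x$times[n_frames(x)] else NA,
              if (is.null(x$unwrapped)) "" else ", unwrapped coordinates attached"))
  tab <- table(x$topology$molecule_type[!duplicated(x$topology$molecule_id)])
  cat("Molecules:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame
#'
#' @param traj a [trajectory()].
#' @param i frame number (1-based).
#' @return object of class `Frame`: list with `time` (ps), `box` ([box()])
#'   and `coordinates` (`n x 3` matrix, Angstrom).
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range", call. = FALSE)
  structure(list(time = traj$times[i], box = box(traj$boxes[i, ]),
                 coordinates = traj$coords[, , i, drop = TRUE]),
            class = "Frame")
}

format_tag <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("xyz", "pdb")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "pdb")) ext else
    stop("cannot infer format from extension '", ext, "'; pass format=",
         call. = FALSE)
}

#' Read a trajectory from XYZ or PDB
#'
#' XYZ frames use an extended comment line carrying the box and time, e.g.
#' `Lattice="30 0 0 0 30 0 0 0 30" Time=1.5` (a bare `box="Lx Ly Lz"` key is
#' also accepted). PDB boxes come from CRYST1 records; MODEL/ENDMDL delimit
#' frames and times are taken as 1 ps per model unless a `REMARK TIME=` is
#' present.
#'
#' @param path input file.
#' @param topology a [topology()]; atom counts per frame must match.
#' @param format "xyz" or "pdb"; inferred from the extension when `NULL`.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format_tag(path, format)
  lines <- readLines(path)
  if (format == "xyz") read_xyz_lines(lines, topology, path)
  else read_pdb_lines(lines, topology, path)
}

parse_xyz_comment <- function(comment, frame, path) {
  lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
  if (length(lat) == 2) {
    v <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    if (length(v) == 9) bx <- v[c(1, 5, 9)] else if (length(v) == 3) bx <- v
    else bx <- NULL
  } else {
    bq <- regmatches(comment, regexec('box="([^"]+)"', comment))[[1]]
    bx <- if (length(bq) == 2) as.numeric(strsplit(trimws(bq[2]), "\\s+")[[1]]) else NULL
  }
  if (is.null(bx) || length(bx) != 3 || any(!is.finite(bx)) || any(bx <= 0)) {
    stop(sprintf("%s: frame %d: missing or malformed box record in comment line",
                 path, frame), call. = FALSE)
  }
  tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
  tval <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
  list(box = bx, time = tval)
}

read_xyz_lines <- function(lines, topology, path) {
  n_top <- nrow(topology)
  i <- 1L; frame <- 0L
  coords <- list(); boxes <- list(); times <- numeric()
  n_lines <- length(lines)
  while (i <= n_lines && nzchar(trimws(lines[i]))) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) {
      stop(sprintf("%s: frame %d, line %d: malformed atom-count line",
                   path, frame, i), call. = FALSE)
    }
    if (nat != n_top) {
      stop(sprintf("%s: frame %d: %d atoms in file but topology has %d",
                   path, frame, nat, n_top), call. = FALSE)
    }
    meta <- parse_xyz_comment(lines[i + 1L], frame, path)
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4)
    if (length(bad)) {
      stop(sprintf("%s: frame %d, line %d: malformed atom line",
                   path, frame, i + 1L + bad[1]), call. = FALSE)
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop(sprintf("%s: frame %d: non-numeric coordinates", path, frame),
           call. = FALSE)
    }
    coords[[frame]] <- xyz
    boxes[[frame]] <- meta$box
    times[frame] <- if (is.na(meta$time)) frame - 1 else meta$time
    i <- i + 2L + nat
  }
  if (frame == 0L) {
    return(trajectory(topology, array(0, c(n_top, 3, 0)), numeric(0),
                      matrix(1, 0, 3)))
  }
  trajectory(topology,
             array(unlist(coords), c(n_top, 3, frame)),
             times, do.call(rbind, boxes))
}

read_pdb_lines <- function(lines, topology, path) {
  n_top <- nrow(topology)
  rec <- substr(lines, 1, 6)
  cryst_lines <- which(rec == "CRYST1")
  atom_mask <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(rec == "MODEL ")
  if (!length(model_starts)) model_starts <- 1L
  model_ends <- c(model_starts[-1] - 1L, length(lines))
  coords <- list(); boxes <- list(); times <- numeric(); frame <- 0L
  default_box <- NULL
  if (length(cryst_lines)) {
    cl <- lines[cryst_lines[1]]
    default_box <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                                substr(cl, 25, 33)))
  }
  for (m in seq_along(model_starts)) {
    rng <- model_starts[m]:model_ends[m]
    at <- rng[atom_mask[rng]]
    if (!length(at)) next
    frame <- frame + 1L
    cr <- cryst_lines[cryst_lines <= max(at)]
    bx <- if (length(cr)) {
      cl <- lines[max(cr)]
      as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33)))
    } else default_box
    if (is.null(bx) || any(!is.finite(bx))) {
      stop(sprintf("%s: frame %d: missing CRYST1 box record", path, frame),
           call. = FALSE)
    }
    if (length(at) != n_top) {
      stop(sprintf("%s: frame %d: %d atoms in file but topology has %d",
                   path, frame, length(at), n_top), call. = FALSE)
    }
    al <- lines[at]
    xyz <- cbind(as.numeric(substr(al, 31, 38)),
                 as.numeric(substr(al, 39, 46)),
                 as.numeric(substr(al, 47, 54)))
    if (any(!is.finite(xyz))) {
      stop(sprintf("%s: frame %d: malformed ATOM coordinates", path, frame),
           call. = FALSE)
    }
    tm_line <- grep("^REMARK\\s+TIME=", lines[rng], value = TRUE)
    times[frame] <- if (length(tm_line)) {
      as.numeric(sub("^REMARK\\s+TIME=\\s*", "", tm_line[1]))
    } else frame - 1
    coords[[frame]] <- xyz
    boxes[[frame]] <- bx
  }
  if (frame == 0L) {
    return(trajectory(topology, array(0, c(n_top, 3, 0)), numeric(0),
                      matrix(1, 0, 3)))
  }
  trajectory(topology, array(unlist(coords), c(n_top, 3, frame)),
             times, do.call(rbind, boxes))
}

#' Write a trajectory to XYZ or PDB
#'
#' Output round-trips through [read_trajectory()] with identical atom order
#' and boxes; coordinates are printed with 6 (XYZ) or 3 (PDB) decimals.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format "xyz" or "pdb"; inferred from the extension when `NULL`.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  format <- format_tag(path, format)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  top <- traj$topology
  if (format == "xyz") {
    for (f in seq_len(n_frames(traj))) {
      bx <- traj$boxes[f, ]
      writeLines(as.character(nrow(top)), con)
      writeLines(sprintf(
        'Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" Time=%.6f Properties=species:S:1:pos:R:3',
        bx[1], bx[2], bx[3], traj$times[f]), con)
      xyz <- traj$coords[, , f, drop = TRUE]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", top$element,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  } else {
    res_name <- c(THAL = "THL", WATER = "HOH", OTHER = "OTH")[top$molecule_type]
    for (f in seq_len(n_frames(traj))) {
      bx <- traj$boxes[f, ]
      writeLines(sprintf("MODEL %8d", f), con)
      writeLines(sprintf("REMARK TIME= %.6f", traj$times[f]), con)
      writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                         bx[1], bx[2], bx[3]), con)
      xyz <- traj$coords[, , f, drop = TRUE]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      serial <- ((seq_len(nrow(top)) - 1L) %% 99999L) + 1L
      writeLines(sprintf("ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         serial, substr(top$site_label, 1, 4), res_name,
                         (top$molecule_id %% 9999L) + 1L,
                         xyz[, 1], xyz[, 2], xyz[, 3],
                         substr(top$element, 1, 2)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}
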