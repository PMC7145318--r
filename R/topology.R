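#' Build a topology table
#'
#' A topology is a data.frame with one row per atom carrying identity,
#' site label, molecule membership, mass, partial charge and Lennard-Jones
#' parameters. Trajectory file formats (XYZ/PDB) cannot carry charges or LJ
#' terms, so the topology lives in a sidecar table.
#'
#' @param element character vector of element symbols.
#' @param site_label character vector of site tokens (O1-O4, Oe, Ob, C1-C6,
#'   Ho, Ow, Hw, X).
#' @param molecule_id integer vector, 0-based molecule ids.
#' @param molecule_type character vector, one of THAL, WATER, OTHER.
#' @param mass numeric, g/mol (default: looked up from element).
#' @param charge numeric, elementary charges (default 0).
#' @param lj_sigma,lj_epsilon numeric LJ parameters, Angstrom and kJ/mol.
#' @param ring integer ring index for disaccharide sites (1 or 2; 0 when not
#'   applicable). Used to disambiguate duplicated ring labels.
#' @return data.frame of class `Topology` with 0-based `atom_index` column.
#' @export
topology <- function(element, site_label, molecule_id, molecule_type,
                     mass = NULL, charge = 0, lj_sigma = 0, lj_epsilon = 0,
                     ring = 0L) {
  n <- length(element)
  if (is.null(mass)) {
    mass <- ELEMENT_MASSES[element]
    if (any(is.na(mass))) {
      stop("no default mass for element(s): ",
           paste(unique(element[is.na(mass)]), collapse = ", "), call. = FALSE)
    }
  }
  top <- data.frame(
    atom_index = seq_len(n) - 1L,
    element = as.character(element),
    site_label = as.character(site_label),
    molecule_id = as.integer(molecule_id),
    molecule_type = as.character(molecule_type),
    mass = rep_len(as.numeric(mass), n),
    charge = rep_len(as.numeric(charge), n),
    lj_sigma = rep_len(as.numeric(lj_sigma), n),
    lj_epsilon = rep_len(as.numeric(lj_epsilon), n),
    ring = rep_len(as.integer(ring), n),
    stringsAsFactors = FALSE
  )
  class(top) <- c("Topology", "data.frame")
  validate_topology(top)
  top
}

#' Validate topology invariants
#'
#' Checks label tokens, label/molecule-type consistency (Ow/Hw only on WATER,
#' O1-O4/Ob/Oe only on THAL), per-molecule site multiplicities for
#' disaccharides (one Ob, two Oe, two each of O1-O4), and positivity of
#' masses and LJ parameters.
#'
#' @param top a [topology()] data.frame.
#' @return the topology, invisibly; stops on violation.
#' @export
validate_topology <- function(top) {
  bad <- setdiff(unique(top$site_label), SITE_LABELS)
  if (length(bad)) {
    stop("unknown site label(s) ", paste(bad, collapse = ", "),
         "; valid tokens: ", paste(SITE_LABELS, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(top$molecule_type), MOLECULE_TYPES)
  if (length(bad_type)) {
    stop("unknown molecule type(s) ", paste(bad_type, collapse = ", "),
         "; valid: ", paste(MOLECULE_TYPES, collapse = ", "), call. = FALSE)
  }
  if (any(top$mass <= 0)) stop("atom masses must be > 0", call. = FALSE)
  if (any(top$lj_sigma < 0) || any(top$lj_epsilon < 0)) {
    stop("LJ parameters must be >= 0", call. = FALSE)
  }
  water_only <- top$site_label %in% c("Ow", "Hw")
  if (any(water_only & top$molecule_type != "WATER")) {
    stop("Ow/Hw labels allowed only on WATER molecules", call. = FALSE)
  }
  thal_only <- top$site_label %in% c("O1", "O2", "O3", "O4", "Ob", "Oe")
  if (any(thal_only & top$molecule_type != "THAL")) {
    stop("O1-O4/Ob/Oe labels allowed only on THAL molecules", call. = FALSE)
  }
  thal_ids <- unique(top$molecule_id[top$molecule_type == "THAL"])
  for (id in thal_ids) {
    lab <- top$site_label[top$molecule_id == id]
    counts <- table(factor(lab, levels = SITE_LABELS))
    if (counts[["Ob"]] != 1 || counts[["Oe"]] != 2 ||
        any(counts[c("O1", "O2", "O3", "O4")] != 2)) {
      stop(sprintf(paste0("THAL molecule %d violates site multiplicities ",
                          "(need 1 Ob, 2 Oe, 2 each of O1-O4)"), id),
           call. = FALSE)
    }
  }
  invisible(top)
}

#' Select atoms by molecule type and site labels
#'
#' @param top a [topology()].
#' @param molecule_type one of THAL, WATER, OTHER.
#' @param site_labels character vector of site tokens to match.
#' @return sorted integer vector of 0-based atom indices (possibly empty).
#' @examples
#' top <- water_topology(3)
#' select_sites(top, "WATER", "Ow")
#' @export
select_sites <- function(top, molecule_type, site_labels) {
  if (!molecule_type %in% MOLECULE_TYPES) {
    stop("unknown molecule type '", molecule_type, "'; valid: ",
         paste(MOLECULE_TYPES, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(site_labels, SITE_LABELS)
  if (length(bad)) {
    stop("unknown site label(s) ", paste(bad, collapse = ", "),
         "; valid tokens: ", paste(SITE_LABELS, collapse = ", "), call. = FALSE)
  }
  idx <- top$atom_index[top$molecule_type == molecule_type &
                        top$site_label %in% site_labels]
  sort(as.integer(idx))
}

# resolve a possibly ring-qualified label ("O1", "Oe/1", "C1/2") within one
# molecule; returns 0-based atom indices matching
resolve_label_in_molecule <- function(top, mol_id, token) {
  parts <- strsplit(token, "/", fixed = TRUE)[[1]]
  lab <- parts[1]
  ring <- if (length(parts) > 1) as.integer(parts[2]) else NA_integer_
  sel <- top$molecule_id == mol_id & top$site_label == lab
  if (!is.na(ring)) sel <- sel & top$ring == ring
  top$atom_index[sel]
}

#' Read / write a topology sidecar table
#'
#' Plain tab-separated text with a header row; columns atom_index, element,
#' site_label, molecule_id, molecule_type, mass, charge, lj_sigma,
#' lj_epsilon, ring.
#'
#' @param path file path.
#' @return `read_topology`: a validated [topology()].
#' @export
read_topology <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("atom_index", "element", "site_label", "molecule_id",
            "molecule_type", "mass", "charge", "lj_sigma", "lj_epsilon")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("topology file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"ring" %in% names(df)) df$ring <- 0L
  df <- df[order(df$atom_index), need_cols <- c(need, "ring")]
  class(df) <- c("Topology", "data.frame")
  validate_topology(df)
  df
}

#' @param top a [topology()] to write.
#' @rdname read_topology
#' @export
write_topology <- function(top, path) {
  utils::write.table(as.data.frame(top), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stack per-molecule topologies, renumbering molecule ids
#'
#' @param tops list of [topology()] objects (typically one molecule each).
#' @return a combined `Topology` with consecutive 0-based molecule ids and
#'   atom indices.
#' @export
bind_topologies <- function(tops) {
  tops <- tops[vapply(tops, nrow, 0L) > 0]
  if (!length(tops)) {
    return(topology(character(), character(), integer(), character()))
  }
  offset <- 0L
  out <- vector("list", length(tops))
  for (i in seq_along(tops)) {
    t_i <- as.data.frame(tops[[i]])
    ids <- t_i$molecule_id
    t_i$molecule_id <- as.integer(match(ids, sort(unique(ids))) - 1L + offset)
    offset <- offset + length(unique(ids))
    out[[i]] <- t_i
  }
  df <- do.call(rbind, out)
  df$atom_index <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  class(df) <- c("Topology", "data.frame")
  df
}
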