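#' Lennard-Jones pair energy with Lorentz-Berthelot mixing
#'
#' Cross parameters are sigma_ij = (sigma_i + sigma_j)/2 and
#' eps_ij = sqrt(eps_i eps_j); the energy is
#' 4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6) in kJ/mol. Vectorized over r.
#'
#' @param r separation (Angstrom), > 0.
#' @param sigma_i,sigma_j site LJ diameters (Angstrom).
#' @param eps_i,eps_j site LJ well depths (kJ/mol).
#' @return energy (kJ/mol).
#' @export
lj_pair_energy <- function(r, sigma_i, sigma_j, eps_i, eps_j) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  sij <- (sigma_i + sigma_j) / 2
  eij <- sqrt(eps_i * eps_j)
  sr6 <- (sij / r)^6
  4 * eij * (sr6^2 - sr6)
}

#' Coulomb pair energy
#'
#' f q_i q_j / r with f the conversion constant in kJ Angstrom / (mol e^2)
#' derived from CODATA constants (about 1389.35). Vectorized over r.
#'
#' @param r separation (Angstrom), > 0.
#' @param q_i,q_j partial charges (e).
#' @return energy (kJ/mol).
#' @export
coulomb_pair_energy <- function(r, q_i, q_j) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  COULOMB_KJ_A * q_i * q_j / r
}

#' Intermolecular interaction-energy decomposition by molecule-pair class
#'
#' Sums Lennard-Jones plus Coulomb energies over every intermolecular atom
#' pair within the minimum-image cutoff, split into water-water (E_ww),
#' water-THAL (E_wt) and THAL-THAL (E_tt) class sums per simulation cell,
#' frame-averaged. Intramolecular pairs are excluded entirely; the Coulomb
#' part uses real-space truncation at the same cutoff (a per-class Ewald
#' decomposition is not well defined), optionally shifted to vanish at the
#' cutoff.
#'
#' @param traj a [trajectory()] whose topology carries charges and LJ
#'   parameters.
#' @param cutoff pair cutoff (Angstrom), at most half the smallest box
#'   length. The production simulations used 15.
#' @param shift_potential subtract the cutoff value of each pair potential
#'   (reduces truncation artifacts; default FALSE).
#' @return list of class `EnergyBreakdown`: `summary` (frame-averaged E_ww,
#'   E_wt, E_tt, E_other, total, kJ/mol) and `per_frame` data.frame.
#' @export
class_interaction_energies <- function(traj, cutoff = 15,
                                       shift_potential = FALSE) {
  top <- traj$topology
  if (any(!is.finite(top$charge)) || any(!is.finite(top$lj_sigma)) ||
      any(!is.finite(top$lj_epsilon))) {
    bad <- which(!is.finite(top$charge) | !is.finite(top$lj_sigma) |
                   !is.finite(top$lj_epsilon))[1]
    stop("atom index ", top$atom_index[bad],
         " is missing charge/LJ parameters", call. = FALSE)
  }
  if (cutoff > min(traj$boxes) / 2 + 1e-9) {
    stop("cutoff exceeds half the smallest box length", call. = FALSE)
  }
  n <- nrow(top)
  type_code <- c(WATER = 1L, THAL = 2L, OTHER = 3L)[top$molecule_type]
  class_of <- function(ta, tb) {
    ifelse(ta == 1L & tb == 1L, "E_ww",
    ifelse((ta == 1L & tb == 2L) | (ta == 2L & tb == 1L), "E_wt",
    ifelse(ta == 2L & tb == 2L, "E_tt", "E_other")))
  }
  cls <- c("E_ww", "E_wt", "E_tt", "E_other")
  per_frame <- matrix(0, n_frames(traj), 4, dimnames = list(NULL, cls))
  ut <- which(upper.tri(matrix(0, n, n)))
  pr <- arrayInd(ut, c(n, n))
  ii <- pr[, 1]; jj <- pr[, 2]
  inter <- top$molecule_id[ii] != top$molecule_id[jj]
  ii <- ii[inter]; jj <- jj[inter]
  pair_class <- class_of(type_code[ii], type_code[jj])
  sij <- (top$lj_sigma[ii] + top$lj_sigma[jj]) / 2
  eij <- sqrt(top$lj_epsilon[ii] * top$lj_epsilon[jj])
  qq <- COULOMB_KJ_A * top$charge[ii] * top$charge[jj]
  for (f in seq_len(n_frames(traj))) {
    L <- traj$boxes[f, ]
    xyz <- traj$coords[, , f, drop = TRUE]
    d <- sqrt(rowSums(minimum_image_displacement(xyz[ii, , drop = FALSE],
                                                 xyz[jj, , drop = FALSE], L)^2))
    keep <- d <= cutoff
    sr6 <- ifelse(eij[keep] > 0, (sij[keep] / d[keep])^6, 0)
    e <- 4 * eij[keep] * (sr6^2 - sr6) + qq[keep] / d[keep]
    if (shift_potential) {
      src6 <- ifelse(eij[keep] > 0, (sij[keep] / cutoff)^6, 0)
      e <- e - (4 * eij[keep] * (src6^2 - src6) + qq[keep] / cutoff)
    }
    per_frame[f, ] <- vapply(cls, function(cl) sum(e[pair_class[keep] == cl]),
                             numeric(1))
  }
  pf <- as.data.frame(per_frame)
  pf$total <- rowSums(per_frame)
  pf <- cbind(frame = seq_len(nrow(pf)), pf)
  summary <- colMeans(pf[, -1, drop = FALSE])
  structure(list(summary = summary, per_frame = pf, cutoff = cutoff,
                 shifted = shift_potential),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf("Intermolecular energies (cutoff %.1f A%s), kJ/mol per cell:\n",
              x$cutoff, if (x$shifted) ", shifted" else ""))
  print(round(x$summary, 4))
  invisible(x)
}
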