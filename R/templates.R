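#' Rigid molecule templates
#'
#' Coarse rigid templates used by the synthetic-trajectory generators. The
#' pseudo-disaccharide carries the standard site labelling of an
#' alpha,alpha-1,1 disaccharide: two hexose rings of carbons C1-C6
#' (C-C 1.54 Angstrom), per ring four hydroxyl oxygens O1-O4 each with a
#' hydroxyl hydrogen Ho (O-H 0.96 Angstrom) and one ring-oxygen analogue Oe,
#' plus a single bridging (glycosidic) oxygen Ob shared by the rings. The
#' template is a geometric stand-in, not a chemically accurate conformer:
#' analyses only require correct labels, multiplicities and controllable
#' geometry.
#'
#' @param dihedral inter-ring dihedral in degrees, measured as the signed
#'   dihedral Oe(ring 1)-C1(ring 1)-Ob-C1(ring 2).
#' @return list with `coords` (n x 3 local coordinates, Angstrom), and the
#'   topology columns `element`, `site_label`, `ring`, `charge`,
#'   `lj_sigma`, `lj_epsilon`.
#' @export
thal_template <- function(dihedral = 140) {
  cc <- 1.54; co <- 1.43; oh <- 0.96
  half <- 33 * pi / 180                      # half of (180 - 114) glycosidic angle
  u1 <- c(-cos(half), sin(half), 0)
  u2 <- c(cos(half), sin(half), 0)

  build_ring <- function(u) {
    c1 <- co * u
    center <- c1 + cc * u
    th0 <- atan2(-u[2], -u[1])               # vertex C1 points back toward Ob
    ang <- th0 + (0:5) * pi / 3
    carbons <- cbind(center[1] + cc * cos(ang), center[2] + cc * sin(ang), 0)
    subst_dir <- cbind(cos(ang), sin(ang), 0) # radially outward
    # substituents on C2..C6: O1..O4 (with Ho) then Oe
    ox <- carbons[2:6, ] + co * subst_dir[2:6, ]
    # hydroxyl hydrogens point out of the ring plane so the radial approach
    # of an accepting partner stays outside the donor cone
    ho <- sweep(ox[1:4, ], 2, c(0, 0, oh), "+")
    coords <- rbind(carbons, ox[1:4, ], ho, ox[5, ])
    labels <- c(paste0("C", 1:6), paste0("O", 1:4), rep("Ho", 4), "Oe")
    elements <- c(rep("C", 6), rep("O", 4), rep("H", 4), "O")
    list(coords = coords, labels = labels, elements = elements)
  }

  ra <- build_ring(u1)
  rb <- build_ring(u2)
  coords <- rbind(ra$coords, rb$coords, c(0, 0, 0))
  labels <- c(ra$labels, rb$labels, "Ob")
  elements <- c(ra$elements, rb$elements, "O")
  ring <- c(rep(1L, 15), rep(2L, 15), 0L)

  # rotate ring 2 about the C1(ring1)-Ob axis until the measured dihedral
  # Oe/1-C1/1-Ob-C1/2 equals the requested value
  i_oe1 <- which(labels == "Oe" & ring == 1L)
  i_c11 <- which(labels == "C1" & ring == 1L)
  i_c12 <- which(labels == "C1" & ring == 2L)
  i_ob <- which(labels == "Ob")
  axis <- coords[i_ob, ] - coords[i_c11, ]
  rotate_ring2 <- function(coords, delta) {
    r <- rotation_about_axis(axis, delta)
    idx <- which(ring == 2L)
    coords[idx, ] <- sweep(sweep(coords[idx, , drop = FALSE], 2,
                                 coords[i_ob, ]) %*% t(r),
                           2, coords[i_ob, ], "+")
    coords
  }
  measure <- function(coords) signed_dihedral(coords[i_oe1, ], coords[i_c11, ],
                                              coords[i_ob, ], coords[i_c12, ])
  d0 <- measure(coords)
  cand <- rotate_ring2(coords, dihedral - d0)
  if (abs(ang_diff(measure(cand), dihedral)) > 1e-6) {
    cand <- rotate_ring2(coords, -(dihedral - d0))
  }
  coords <- cand

  q <- c(C = 0.175, O_hydroxyl = -0.5, Ho = 0.35, O_ring = -0.3)
  charge <- ifelse(elements == "C", q[["C"]],
            ifelse(labels %in% c("Ob", "Oe"), q[["O_ring"]],
            ifelse(labels == "Ho", q[["Ho"]], q[["O_hydroxyl"]])))
  lj_sigma <- ifelse(elements == "C", 3.4, ifelse(elements == "O", 3.0, 0))
  lj_epsilon <- ifelse(elements == "C", 0.3,
                ifelse(labels %in% c("Ob", "Oe"), 0.4,
                ifelse(elements == "O", 0.5, 0)))
  list(coords = coords, element = elements, site_label = labels, ring = ring,
       charge = charge, lj_sigma = lj_sigma, lj_epsilon = lj_epsilon)
}

# smallest signed angular difference a-b in degrees
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @rdname thal_template
#' @details The 3-site water template uses an SPC-like geometry (O-H 0.9572
#'   Angstrom, H-O-H 104.52 degrees) and SPC charges/LJ parameters:
#'   q(Ow) = -0.8476 e, q(Hw) = +0.4238 e, sigma(Ow) = 3.166 Angstrom,
#'   epsilon(Ow) = 0.650 kJ/mol. These are generator fixtures, not
#'   force-field claims.
#' @export
water_template <- function() {
  roh <- 0.9572; theta <- 104.52 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  roh * c(1, 0, 0),
                  roh * c(cos(theta), sin(theta), 0))
  list(coords = coords, element = c("O", "H", "H"),
       site_label = c("Ow", "Hw", "Hw"), ring = c(0L, 0L, 0L),
       charge = c(-0.8476, 0.4238, 0.4238),
       lj_sigma = c(3.166, 0, 0), lj_epsilon = c(0.650, 0, 0))
}

#' @rdname thal_template
#' @export
particle_template <- function() {
  list(coords = matrix(0, 1, 3), element = "X", site_label = "X", ring = 0L,
       charge = 0, lj_sigma = 3.4, lj_epsilon = 1.0)
}

#' Topology for one molecule built from a template
#'
#' @param tmpl a template list from [thal_template()], [water_template()] or
#'   [particle_template()].
#' @param molecule_type molecule type token (THAL, WATER, OTHER).
#' @return a single-molecule [topology()].
#' @export
template_topology <- function(tmpl, molecule_type) {
  topology(element = tmpl$element, site_label = tmpl$site_label,
           molecule_id = 0L, molecule_type = molecule_type,
           charge = tmpl$charge, lj_sigma = tmpl$lj_sigma,
           lj_epsilon = tmpl$lj_epsilon, ring = tmpl$ring)
}

#' Topology for n identical water molecules
#'
#' @param n number of molecules.
#' @return a [topology()].
#' @export
water_topology <- function(n) {
  t1 <- template_topology(water_template(), "WATER")
  bind_topologies(rep(list(t1), n))
}

#' @rdname water_topology
#' @param dihedral inter-ring dihedral (degrees) of the template.
#' @export
thal_topology <- function(n, dihedral = 140) {
  t1 <- template_topology(thal_template(dihedral), "THAL")
  bind_topologies(rep(list(t1), n))
}
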