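#' Orthorhombic periodic box
#'
#' @param lengths numeric vector of three positive box edge lengths (Angstrom).
#' @return An object of class `Box` (named numeric length 3).
#' @examples
#' box(c(30, 30, 30))
#' @export
box <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3 || any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("box lengths must be three finite positive numbers", call. = FALSE)
  }
  structure(stats::setNames(lengths, c("Lx", "Ly", "Lz")), class = "Box")
}

#' @export
print.Box <- function(x, ...) {
  cat(sprintf("Orthorhombic box: %.4f x %.4f x %.4f Angstrom\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Minimum-image displacement between positions
#'
#' Computes a - b folded into the primary image of an orthorhombic periodic
#' box, so that each component lies in [-L/2, L/2) and the vector magnitude
#' is the minimum over all periodic images.
#'
#' @param a,b numeric position vectors (length 3) or n x 3 matrices (Angstrom).
#' @param box a [box()] object (or numeric length-3 vector of box lengths).
#' @return displacement vector (or matrix) with components in [-L/2, L/2).
#' @examples
#' minimum_image_displacement(c(1, 0, 0), c(19, 0, 0), box(c(20, 20, 20)))
#' @export
minimum_image_displacement <- function(a, b, box) {
  L <- as.numeric(box)
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    if (!all(is.finite(a)) || !all(is.finite(b))) {
      stop("non-finite coordinates in minimum_image_displacement", call. = FALSE)
    }
    d <- a - b
    for (k in 1:3) d[, k] <- d[, k] - L[k] * floor(d[, k] / L[k] + 0.5)
    return(d)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite coordinates in minimum_image_displacement", call. = FALSE)
  }
  d <- a - b
  d - L * floor(d / L + 0.5)
}

# displacement matrix from each row of `from` to a single point `to`
# (vectorised minimum image); returns n x 3 matrix
mic_disp_to_point <- function(coords, point, L) {
  d <- sweep(coords, 2, point)
  for (k in 1:3) d[, k] <- d[, k] - L[k] * floor(d[, k] / L[k] + 0.5)
  d
}

# full minimum-image distance matrix between two coordinate sets (na x nb)
mic_distance_matrix <- function(ca, cb, L) {
  na_ <- nrow(ca); nb_ <- nrow(cb)
  out <- matrix(0, na_, nb_)
  for (k in 1:3) {
    d <- outer(ca[, k], cb[, k], "-")
    d <- d - L[k] * floor(d / L[k] + 0.5)
    out <- out + d * d
  }
  sqrt(out)
}

# integer image shift s such that b + s*L is the nearest image of b to a;
# i.e. a - (b + s*L) is the minimum-image displacement. Rows = pairs.
mic_image_shift <- function(a, b, L) {
  a <- rbind(a); b <- rbind(b)
  d <- a - b
  s <- matrix(0L, nrow(d), 3)
  for (k in 1:3) s[, k] <- as.integer(-floor(d[, k] / L[k] + 0.5))
  s
}

# angle at vertex `v` between directions to p and q, degrees in [0, 180]
vertex_angle <- function(p, v, q, L = NULL) {
  u1 <- if (is.null(L)) p - v else minimum_image_displacement(p, v, L)
  u2 <- if (is.null(L)) q - v else minimum_image_displacement(q, v, L)
  ct <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# standard signed dihedral of four points, degrees in (-180, 180]
signed_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(-y, x) * 180 / pi   # sign matches the common MD convention
  if (ang <= -180) ang <- ang + 360
  ang
}

# rotation matrix about a unit axis by angle (degrees), Rodrigues form
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

# uniform random rotation matrix (via QR of Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Kabsch superposition: rotation R and translation t minimising
# || (moving %*% R + t) - target ||^2 ; rows are points
kabsch <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  a <- sweep(moving, 2, cm); b <- sweep(target, 2, ct)
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = r, translation = as.numeric(ct - cm %*% r))
}
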