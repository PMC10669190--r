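#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalised", call. = FALSE)
  v / n
}

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Given three previously placed atoms `a`, `b`, `c`, returns the position of a
#' fourth atom `d` such that the bond length |c-d|, the bond angle b-c-d and
#' the dihedral a-b-c-d take the requested values.
#'
#' @param a,b,c numeric(3) coordinates in Angstrom.
#' @param bond bond length |c-d| in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return numeric(3) position of the new atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m - d[3] * n
}

#' Measure a torsion angle
#'
#' @param p1,p2,p3,p4 numeric(3) atom coordinates.
#' @return dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Standard backbone internal-geometry constants (Angstrom / degrees).
# Textbook peptide values; the builder is idealised, not force-field derived.
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.229,
  b_n_h = 1.01, b_ca_cb = 1.53, b_cb_sg = 1.81,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
  a_ca_c_o = 120.5, a_n_ca_cb = 110.5, a_ca_cb_sg = 114.4,
  omega = 180
)
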