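#' Exact geometric measurements on coordinates
#'
#' Computes a distance (Angstrom), a bond angle (degrees, at the middle
#' atom, in \[0, 180\]) or a torsion/dihedral angle (degrees, signed, in
#' (-180, 180\], IUPAC convention: cis/eclipsed = 0, positive = clockwise
#' rotation of the far bond when sighting from the second to the third atom).
#'
#' Degenerate geometry (coincident atoms for distance/angle, collinear
#' middle bond for a dihedral) raises an error rather than returning NaN.
#'
#' @param s a [Structure], [Trajectory] frame, or bare n x 3 coordinate matrix
#' @param kind one of `"distance"`, `"angle"`, `"dihedral"`
#' @param idx 2, 3 or 4 distinct atom indices (1-based)
#' @return numeric scalar (Angstrom or degrees)
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(0, 0, 1))
#' measure(xyz, "distance", c(1, 2))
#' @export
measure <- function(s, kind = c("distance", "angle", "dihedral"), idx) {
  kind <- match.arg(kind)
  xyz <- if (inherits(s, "Structure")) s$coords else as.matrix(s)
  need <- switch(kind, distance = 2L, angle = 3L, dihedral = 4L)
  idx <- as.integer(idx)
  if (length(idx) != need)
    stop(kind, " needs ", need, " atom indices, got ", length(idx))
  if (anyDuplicated(idx)) stop("atom indices must be distinct")
  if (any(idx < 1L | idx > nrow(xyz))) stop("atom index out of range")
  p <- xyz[idx, , drop = FALSE]
  switch(kind,
    distance = vnorm(p[2L, ] - p[1L, ]),
    angle = {
      v1 <- p[1L, ] - p[2L, ]; v2 <- p[3L, ] - p[2L, ]
      n1 <- vnorm(v1); n2 <- vnorm(v2)
      if (n1 < 1e-9 || n2 < 1e-9) stop("coincident atoms: angle undefined")
      cth <- sum(v1 * v2) / (n1 * n2)
      acos(max(-1, min(1, cth))) * 180 / pi
    },
    dihedral = {
      b1 <- p[2L, ] - p[1L, ]; b2 <- p[3L, ] - p[2L, ]; b3 <- p[4L, ] - p[3L, ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
        stop("collinear atoms: torsion undefined")
      phi <- atan2(sum(cross3(n1, n2) * unitv(b2)), sum(n1 * n2)) * 180 / pi
      if (phi <= -180) phi <- phi + 360
      phi
    })
}

## Natural extension reference frame (NeRF) placement: position a new atom at
## bond length r from C, bond angle theta (B-C-new, degrees) and dihedral phi
## (A-B-C-new, degrees, same sign convention as measure()).
place_internal <- function(A, B, C, r, theta, phi) {
  th <- (180 - theta) * pi / 180
  ph <- phi * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- r * c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}
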