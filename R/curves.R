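# Lagrangian boundary curves: closed elastic polylines with zero rest-length
# springs (the Hookean tension T = c |dX/ds| of the stretching-energy model),
# plus the geometric utilities the immersed-boundary coupling needs.

#' Create a closed Lagrangian boundary curve
#'
#' A closed polyline of M nodes with a reference arclength increment \code{ds}
#' and elastic stiffness \code{c}. The stretching energy is
#' E = (c/2) integral |dX/ds|^2 ds, i.e. zero rest-length springs: closed
#' curves are pre-tensioned and their tendency to contract is balanced by
#' tethering and fluid incompressibility.
#'
#' Counter-clockwise orientation (positive shoelace area) is enforced.
#'
#' @param X M x 2 matrix of node positions (cm), ordered along the curve.
#' @param ds reference arclength increment per node (cm). Defaults to the
#'   mean current spacing.
#' @param c elastic stiffness coefficient (g cm/s^2).
#' @return an object of class \code{boundary_curve}.
#' @export
boundary_curve <- function(X, ds = NULL, c = 0) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 2, nrow(X) >= 8, all(is.finite(X)), c >= 0)
  if (.shoelace_signed(X) < 0) X <- X[nrow(X):1, , drop = FALSE]
  if (is.null(ds)) {
    seg <- sqrt(rowSums((X[c(2:nrow(X), 1), ] - X)^2))
    ds <- mean(seg)
  }
  stopifnot(ds > 0)
  structure(list(X = X, ds = ds, c = c, closed = TRUE),
            class = "boundary_curve")
}

#' Sample a circle as a boundary curve
#'
#' @param center length-2 center (cm).
#' @param radius radius (cm).
#' @param M number of nodes; if NULL, chosen so node spacing is about
#'   \code{target_ds}.
#' @param c elastic stiffness (g cm/s^2).
#' @param target_ds target node spacing (cm) when M is NULL.
#' @return a [boundary_curve()].
#' @export
circle_curve <- function(center, radius, M = NULL, c = 0, target_ds = NULL) {
  stopifnot(radius > 0)
  if (is.null(M)) {
    stopifnot(!is.null(target_ds))
    M <- max(8L, as.integer(round(2 * pi * radius / target_ds)))
  }
  th <- 2 * pi * (0:(M - 1)) / M
  X <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  boundary_curve(X, ds = 2 * pi * radius / M, c = c)
}

.shoelace_signed <- function(X) {
  Xn <- X[c(2:nrow(X), 1), , drop = FALSE]
  0.5 * sum(X[, 1] * Xn[, 2] - Xn[, 1] * X[, 2])
}

#' Enclosed area of a closed curve
#'
#' Shoelace area (absolute value). Serves as the discrete incompressibility
#' diagnostic: a membrane advected by a divergence-free flow should conserve
#' its enclosed area up to immersed-boundary leakage.
#'
#' @param curve a [boundary_curve()] or an M x 2 position matrix.
#' @param warn_self_intersect log a warning when the polygon self-intersects.
#' @return area in cm^2.
#' @export
enclosed_area <- function(curve, warn_self_intersect = FALSE) {
  X <- if (inherits(curve, "boundary_curve")) curve$X else as.matrix(curve)
  if (warn_self_intersect && .self_intersects(X))
    warning("curve self-intersects; enclosed area is signed-sum only")
  abs(.shoelace_signed(X))
}

# O(M^2) segment crossing test; only used for diagnostics on small curves.
.self_intersects <- function(X) {
  M <- nrow(X)
  P <- X; Q <- X[c(2:M, 1), , drop = FALSE]
  for (i in 1:(M - 1)) {
    js <- (i + 2):M
    js <- js[!(i == 1 & js == M)]
    if (!length(js)) next
    if (any(.seg_cross(P[i, ], Q[i, ], P[js, , drop = FALSE],
                       Q[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

.seg_cross <- function(a, b, C, D) {
  cr <- function(o, p, q) (p[, 1] - o[1]) * (q[, 2] - o[2]) -
    (p[, 2] - o[2]) * (q[, 1] - o[1])
  d1 <- cr(a, C, matrix(b, nrow(C), 2, byrow = TRUE))
  d2 <- cr(a, D, matrix(b, nrow(C), 2, byrow = TRUE))
  o <- function(P, A, B) (B[, 1] - A[, 1]) * (P[2] - A[, 2]) -
    (B[, 2] - A[, 2]) * (P[1] - A[, 1])
  d3 <- o(a, C, D); d4 <- o(b, C, D)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Elastic force density of a closed curve
#'
#' Discrete form of F = d/ds (T tau) with Hookean tension T = c |dX/ds|:
#' F_k = c (X_{k+1} - 2 X_k + X_{k-1}) / ds^2, the (negative) gradient of the
#' discrete stretching energy divided by ds. The total force over a closed
#' curve telescopes to zero.
#'
#' @param curve a [boundary_curve()].
#' @param c stiffness override (used when the stiffness is time-varying, as
#'   for the myosin-controlled nucleus); defaults to \code{curve$c}.
#' @return M x 2 matrix of force densities (g/(cm s^2) per unit arclength
#'   convention of the energy).
#' @export
elastic_force <- function(curve, c = curve$c) {
  X <- curve$X
  M <- nrow(X)
  seg <- sqrt(rowSums((X[c(2:M, 1), ] - X)^2))
  if (any(seg < .Machine$double.eps * 100))
    stop("degenerate node spacing: coincident nodes on curve")
  (c / curve$ds^2) * (X[c(2:M, 1), ] - 2 * X + X[c(M, 1:(M - 1)), ])
}

#' Discrete stretching energy of a curve
#'
#' E = (c/2) sum |X_{k+1} - X_k|^2 / ds. [elastic_force()] equals minus its
#' gradient divided by ds; the test suite checks this against a
#' finite-difference gradient oracle.
#'
#' @param curve a [boundary_curve()].
#' @param c stiffness override.
#' @return energy (g cm^2/s^2).
#' @export
elastic_energy <- function(curve, c = curve$c) {
  X <- curve$X
  d <- X[c(2:nrow(X), 1), ] - X
  0.5 * c * sum(d^2) / curve$ds
}

#' Tether (anchor) force density
#'
#' Linear springs to fixed reference positions: F = ct (Z - X). Normal cells
#' are tethered at every node for all time; the glioma membrane is tethered
#' only on its phase-designated rear (elongation) or front (retraction)
#' node subset, with anchors frozen at the phase switch.
#'
#' @param X node positions, m x 2 (cm).
#' @param Z anchor positions, m x 2 (cm).
#' @param ct tether stiffness (g/(cm s^2)).
#' @return m x 2 force densities.
#' @export
tether_force <- function(X, Z, ct) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (!all(dim(X) == dim(Z)))
    stop("tether_force: positions and anchors differ in length")
  ct * (Z - X)
}

#' Resample a curve to uniform node spacing
#'
#' Arclength re-parameterization back to spacing about \code{target_ds}
#' (node count is adjusted). Linear interpolation along the polyline; the
#' enclosed area changes by well under 0.1 percent for resolved curves.
#'
#' @param curve a [boundary_curve()].
#' @param target_ds desired spacing (cm); default keeps \code{curve$ds}.
#' @return a new [boundary_curve()].
#' @export
resample_curve <- function(curve, target_ds = curve$ds) {
  X <- curve$X
  M <- nrow(X)
  seg <- sqrt(rowSums((X[c(2:M, 1), ] - X)^2))
  s <- c(0, cumsum(seg))              # arclength at node 1..M, then closure
  Ltot <- s[M + 1]
  Mnew <- max(8L, as.integer(round(Ltot / target_ds)))
  snew <- Ltot * (0:(Mnew - 1)) / Mnew
  Xc <- rbind(X, X[1, , drop = FALSE])
  Xn <- cbind(stats::approx(s, Xc[, 1], xout = snew)$y,
              stats::approx(s, Xc[, 2], xout = snew)$y)
  boundary_curve(Xn, ds = Ltot / Mnew, c = curve$c)
}

#' Point-in-polygon test
#'
#' Even-odd ray casting; used to validate that the nucleus starts strictly
#' inside the glioma membrane.
#'
#' @param pts n x 2 points.
#' @param poly M x 2 closed polygon vertices.
#' @return logical vector of length n.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  M <- nrow(poly)
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- xi[c(M, 1:(M - 1))]; yj <- yi[c(M, 1:(M - 1))]
  apply(pts, 1, function(p) {
    cross <- ((yi > p[2]) != (yj > p[2])) &
      (p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi)
    sum(cross) %% 2 == 1
  })
}
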