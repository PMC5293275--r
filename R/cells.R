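# Cell objects: a glioma cell (elastic membrane + elastic nucleus, with
# phase-dependent tether anchors and deformation-tracking markers) and normal
# glial cells (membrane tethered at every node to fixed tissue anchors).

#' Create a glioma cell
#'
#' Membrane and nucleus are concentric circles at rest. The nucleus radius is
#' not constrained by the tissue geometry here, but scenarios place the cell
#' so that intercellular gaps are narrower than the nuclear diameter. Markers
#' for the lateral deformation ratio are initialized at the nucleus center and
#' at its farthest west/east boundary points.
#'
#' @param center length-2 center (cm).
#' @param radius membrane radius (cm).
#' @param nucleus_radius nucleus radius (cm); default 0.6 * radius.
#' @param ce_m membrane elastic stiffness (g cm/s^2).
#' @param ce_n_b basal nucleus elastic stiffness (g cm/s^2); the live nucleus
#'   stiffness is ce_n_b * fold * r(mb) with r the myosin stiffening rate.
#' @param ct tether stiffness of the glioma membrane (g/(cm s^2)).
#' @param target_ds node spacing (cm), typically h/2.
#' @param fold scenario multiplier on the basal nucleus stiffness.
#' @param front_halfwidth half-angle (degrees) of the front/rear node arcs
#'   about the migration direction.
#' @return an object of class \code{glioma_cell}.
#' @export
glioma_cell <- function(center, radius, nucleus_radius = 0.6 * radius,
                        ce_m, ce_n_b, ct, target_ds,
                        fold = 1, front_halfwidth = 60) {
  stopifnot(nucleus_radius < radius)
  mem <- circle_curve(center, radius, c = ce_m, target_ds = target_ds)
  nuc <- circle_curve(center, nucleus_radius, c = ce_n_b,
                      target_ds = target_ds)
  if (!all(points_in_polygon(nuc$X, mem$X)))
    stop("nucleus is not strictly inside the membrane")
  iw <- which.min(nuc$X[, 1]); ie <- which.max(nuc$X[, 1])
  cell <- list(
    membrane = mem, nucleus = nuc,
    ce_n_b = ce_n_b, fold = fold, ct = ct,
    ce_n = ce_n_b * fold,                 # live (myosin-modulated) stiffness
    front_halfwidth = front_halfwidth,
    front_nodes = integer(0), rear_nodes = integer(0),
    Zr = NULL, Zf = NULL,
    markers = list(Xnc = as.numeric(center),
                   iW = iw, iE = ie,
                   refW = sqrt(sum((nuc$X[iw, ] - center)^2)),
                   refE = sqrt(sum((nuc$X[ie, ] - center)^2)))
  )
  class(cell) <- "glioma_cell"
  cell
}

#' Create a tethered normal glial cell
#'
#' The membrane is anchored node-by-node to its initial configuration; the
#' anchors never move, so the cell passively resists displacement.
#'
#' @param center,radius circle geometry (cm).
#' @param ce elastic stiffness (g cm/s^2).
#' @param ct tether stiffness (g/(cm s^2)).
#' @param target_ds node spacing (cm).
#' @return an object of class \code{normal_cell}.
#' @export
normal_cell <- function(center, radius, ce, ct, target_ds) {
  mem <- circle_curve(center, radius, c = ce, target_ds = target_ds)
  structure(list(membrane = mem, ZN = mem$X, ct = ct),
            class = "normal_cell")
}

#' Select membrane nodes in an angular arc about a direction
#'
#' Nodes whose angular position about the membrane centroid lies within
#' \code{halfwidth} degrees of \code{dir}. Used to pick the front
#' (active-force / retraction-anchor) and rear (elongation-anchor) arcs;
#' they are disjoint whenever halfwidth < 90.
#'
#' @param curve a [boundary_curve()].
#' @param dir length-2 direction (need not be normalized).
#' @param halfwidth half-angle in degrees.
#' @return integer node indices.
#' @export
arc_nodes <- function(curve, dir, halfwidth) {
  X <- curve$X
  ctr <- colMeans(X)
  v <- sweep(X, 2, ctr)
  d <- dir / sqrt(sum(dir^2))
  cosang <- (v %*% d) / sqrt(rowSums(v^2))
  which(cosang >= cos(halfwidth * pi / 180))
}

#' Refresh the front/rear node arcs of a glioma cell
#'
#' Called at every phase switch (and at initialization) with the current
#' migration direction: front nodes face +dir, rear nodes face -dir.
#'
#' @param cell a [glioma_cell()].
#' @param dir migration direction.
#' @return the cell with updated \code{front_nodes}/\code{rear_nodes}.
#' @export
select_front_rear <- function(cell, dir) {
  cell$front_nodes <- arc_nodes(cell$membrane, dir, cell$front_halfwidth)
  cell$rear_nodes <- arc_nodes(cell$membrane, -dir, cell$front_halfwidth)
  cell
}

#' Freeze tether anchors at a phase switch
#'
#' Entering elongation freezes the rear anchors at the current rear-node
#' positions; entering retraction freezes the front anchors at the current
#' front-node positions. The anchors model attachment sites in the
#' surrounding tissue.
#'
#' @param cell a [glioma_cell()].
#' @param phase "elongation" or "retraction".
#' @return the cell with \code{Zr} or \code{Zf} refrozen.
#' @export
freeze_anchors <- function(cell, phase) {
  if (phase == "elongation") {
    cell$Zr <- cell$membrane$X[cell$rear_nodes, , drop = FALSE]
  } else {
    cell$Zf <- cell$membrane$X[cell$front_nodes, , drop = FALSE]
  }
  cell
}
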