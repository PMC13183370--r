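# Geometric quadrant segmentation of the caudoputamen (CP) and
# striosome/matrix compartment quantification.
#
# Landmark-line construction: Line 1 is the tangent through the two dorsal CP
# edge points; Line 2 passes through the anterior commissure parallel to Line
# 1; Line 3 joins the lateral CP boundary to the dorsal tip of the nucleus
# accumbens shell (NAcs); Line 4 passes through the NAcs tip perpendicular to
# Line 1. The two internal dividers run through midpoints of those reference
# lines, each clipped to the CP hull: the divider through the Line-1/Line-2
# chord midpoints runs dorsoventrally and separates medial from lateral
# (ties -> medial); the divider through the Line-3/Line-4 midpoints runs
# mediolaterally and separates dorsal from ventral (ties -> dorsal). Sides are
# identified from the landmarks themselves (medial = NAcs side, dorsal = side
# of the Line-1 chord midpoint), so the construction is rigid-motion
# equivariant and hemisphere-agnostic.

#' Striatal landmark set
#'
#' @param dorsal_edge_left,dorsal_edge_right dorsal CP edge points (um, length-2).
#' @param ac_point anterior-commissure point.
#' @param nacs_tip dorsal tip of the nucleus accumbens shell.
#' @param lateral_boundary lateral CP boundary point.
#' @return object of class `striatal_landmarks`.
#' @export
striatal_landmarks <- function(dorsal_edge_left, dorsal_edge_right,
                               ac_point, nacs_tip, lateral_boundary) {
  pts <- list(dorsal_edge_left = dorsal_edge_left,
              dorsal_edge_right = dorsal_edge_right,
              ac_point = ac_point, nacs_tip = nacs_tip,
              lateral_boundary = lateral_boundary)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2 || any(!is.finite(p))) stop(nm, " must be a finite length-2 point")
    pts[[nm]] <- p
  }
  if (isTRUE(all.equal(pts$dorsal_edge_left, pts$dorsal_edge_right)))
    stop("dorsal edge points must be distinct")
  structure(pts, class = "striatal_landmarks")
}

chord_midpoint <- function(poly, p, d) {
  ch <- line_polygon_chord(poly, p, d)
  if (is.null(ch)) stop("reference line does not intersect the CP polygon")
  colMeans(ch)
}

#' Construct the DM/DL/VM/VL quadrant partition of the CP
#'
#' Splits the CP polygon by the two internal divider lines derived from the
#' landmark construction (see the package vignette for the geometry). Returns
#' the four quadrant polygons together with all six construction lines for
#' audit.
#'
#' @param cp_polygon CP outline polygon (um).
#' @param landmarks a [striatal_landmarks()] object.
#' @return object of class `quadrant_partition`: list with `polygons`
#'   (named dm/dl/vm/vl), `lines` (each a 2 x 2 point matrix), and the
#'   oriented divider half-planes used for point assignment.
#' @export
construct_quadrants <- function(cp_polygon, landmarks) {
  stopifnot(inherits(landmarks, "striatal_landmarks"))
  cp <- as_polygon(cp_polygon)
  unit <- function(v) v / sqrt(sum(v^2))

  d1 <- unit(landmarks$dorsal_edge_right - landmarks$dorsal_edge_left)  # Line 1
  p1 <- landmarks$dorsal_edge_left
  p2 <- landmarks$ac_point; d2 <- d1                                    # Line 2
  l3 <- rbind(landmarks$lateral_boundary, landmarks$nacs_tip)           # Line 3
  p4 <- landmarks$nacs_tip; d4 <- c(-d1[2], d1[1])                      # Line 4

  mid1 <- chord_midpoint(cp, p1, d1)
  mid2 <- chord_midpoint(cp, p2, d2)
  mid3 <- colMeans(l3)
  ch4 <- line_polygon_chord(cp, p4, d4)
  mid4 <- if (is.null(ch4)) p4 else colMeans(ch4)  # Line 4 may run outside CP

  dml <- unit(mid2 - mid1)   # medial/lateral divider (Line 5), dorsoventral
  ddv <- unit(mid4 - mid3)   # dorsal/ventral divider (Line 6), mediolateral
  cross_z <- dml[1] * ddv[2] - dml[2] * ddv[1]
  if (abs(cross_z) < 1e-9) {
    stop("degenerate landmark configuration: divider lines are parallel\n",
         "  Line 5 through (", paste(signif(mid1, 6), collapse = ", "), ") and (",
         paste(signif(mid2, 6), collapse = ", "), ")\n",
         "  Line 6 through (", paste(signif(mid3, 6), collapse = ", "), ") and (",
         paste(signif(mid4, 6), collapse = ", "), ")")
  }

  # Oriented normals: medial side contains the NAcs tip; dorsal side contains
  # the Line-1 chord midpoint.
  orient <- function(p, d, toward) {
    n <- c(-d[2], d[1])
    if (sum((toward - p) * n) < 0) n <- -n
    n
  }
  n_med <- orient(mid1, dml, landmarks$nacs_tip)
  n_dor <- orient(mid3, ddv, mid1)

  quad_poly <- function(med, dor) {
    poly <- clip_halfplane(cp, mid1, if (med) n_med else -n_med)
    if (is.null(poly)) return(NULL)
    clip_halfplane(poly, mid3, if (dor) n_dor else -n_dor)
  }
  polygons <- list(dm = quad_poly(TRUE, TRUE), dl = quad_poly(FALSE, TRUE),
                   vm = quad_poly(TRUE, FALSE), vl = quad_poly(FALSE, FALSE))
  structure(list(
    polygons = polygons,
    cp_polygon = cp,
    lines = list(
      line1 = line_polygon_chord(cp, p1, d1),
      line2 = line_polygon_chord(cp, p2, d2),
      line3 = l3,
      line4 = if (is.null(ch4)) rbind(p4, p4 + 100 * d4) else ch4,
      line5 = rbind(mid1, mid2),
      line6 = rbind(mid3, mid4)),
    divider_ml = list(point = mid1, normal = n_med),  # >= 0 is medial
    divider_dv = list(point = mid3, normal = n_dor)   # >= 0 is dorsal
  ), class = "quadrant_partition")
}

#' @export
print.quadrant_partition <- function(x, ...) {
  a <- vapply(x$polygons, function(p) if (is.null(p)) 0 else polygon_area(p), 0)
  cat("CP quadrant partition (areas, mm^2):\n")
  print(round(a / 1e6, 4))
  invisible(x)
}

#' Assign points to quadrants
#'
#' Total and single-valued over the CP interior: points on a divider go to the
#' medial (mediolateral divider) or dorsal (dorsoventral divider) side; points
#' outside the CP polygon get NA.
#'
#' @param x,y coordinates (um).
#' @param partition a [construct_quadrants()] result.
#' @return character vector with values "DM", "DL", "VM", "VL" or NA.
#' @export
assign_quadrant <- function(x, y, partition) {
  stopifnot(inherits(partition, "quadrant_partition"))
  inside <- points_in_polygon(x, y, partition$cp_polygon)
  s_med <- (x - partition$divider_ml$point[1]) * partition$divider_ml$normal[1] +
           (y - partition$divider_ml$point[2]) * partition$divider_ml$normal[2]
  s_dor <- (x - partition$divider_dv$point[1]) * partition$divider_dv$normal[1] +
           (y - partition$divider_dv$point[2]) * partition$divider_dv$normal[2]
  lab <- ifelse(s_dor >= 0,
                ifelse(s_med >= 0, "DM", "DL"),
                ifelse(s_med >= 0, "VM", "VL"))
  lab[!inside] <- NA_character_
  lab
}

#' Assign cells to striosome or matrix compartments
#'
#' A cell is "striosome" iff its centroid lies inside or on any striosome
#' polygon; otherwise "matrix" if inside the CP; cells outside the CP are NA
#' (excluded).
#'
#' @param cells data.frame with x_um, y_um.
#' @param striosomes list of striosome polygons (MOR1+ patches).
#' @param cp_polygon CP outline.
#' @return `cells` with an added `compartment` column.
#' @export
assign_compartment <- function(cells, striosomes, cp_polygon) {
  in_cp <- points_in_polygon(cells$x_um, cells$y_um, cp_polygon)
  in_strio <- rep(FALSE, nrow(cells))
  for (sp in striosomes)
    in_strio <- in_strio | points_in_polygon(cells$x_um, cells$y_um, sp)
  cells$compartment <- ifelse(!in_cp, NA_character_,
                              ifelse(in_strio, "striosome", "matrix"))
  cells
}

# Area of each striosome clipped to one quadrant's two half-planes (striosomes
# are inside the CP by construction, so no CP clip is needed).
striosome_area_in_quadrant <- function(striosomes, partition, quadrant) {
  med <- quadrant %in% c("DM", "VM"); dor <- quadrant %in% c("DM", "DL")
  ml <- partition$divider_ml; dv <- partition$divider_dv
  total <- 0
  for (sp in striosomes) {
    p <- clip_halfplane(sp, ml$point, if (med) ml$normal else -ml$normal)
    if (is.null(p)) next
    p <- clip_halfplane(p, dv$point, if (dor) dv$normal else -dv$normal)
    if (is.null(p)) next
    total <- total + polygon_area(p)
  }
  total
}

#' Per-quadrant, per-compartment cell densities
#'
#' Counts cells by quadrant and compartment and divides by the corresponding
#' compartment area within the quadrant (polygon intersection), in cells/mm^2.
#'
#' @param cells detection table with x_um, y_um (one channel).
#' @param partition a [construct_quadrants()] result.
#' @param striosomes list of striosome polygons.
#' @return data.frame with quadrant, compartment, n_cells, area_mm2, density.
#' @export
compartment_density <- function(cells, partition, striosomes) {
  quad <- assign_quadrant(cells$x_um, cells$y_um, partition)
  cells <- assign_compartment(cells, striosomes, partition$cp_polygon)
  out <- list()
  for (q in c("DM", "DL", "VM", "VL")) {
    qpoly <- partition$polygons[[tolower(q)]]
    a_quad <- if (is.null(qpoly)) 0 else polygon_area(qpoly)
    a_strio <- striosome_area_in_quadrant(striosomes, partition, q)
    a_mat <- a_quad - a_strio
    for (comp in c("striosome", "matrix")) {
      n <- sum(quad == q & cells$compartment == comp, na.rm = TRUE)
      a <- if (comp == "striosome") a_strio else a_mat
      if (a <= 0 && n > 0)
        stop("geometry inconsistency: ", n, " cells in ", q, "/", comp,
             " but zero intersection area")
      out[[length(out) + 1L]] <- data.frame(
        quadrant = q, compartment = comp, n_cells = n,
        area_mm2 = a / 1e6,
        density = if (a > 0) n / (a / 1e6) else 0)
    }
  }
  do.call(rbind, out)
}

#' Normalize a density to the matched control mean
#'
#' Fold change of a density over the mean of the corresponding compartment
#' within the same quadrant of the no-exposure group.
#'
#' @param density numeric density (cells/mm^2).
#' @param control_mean matched control-group mean density (> 0).
#' @return fold change.
#' @export
normalize_to_control <- function(density, control_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0")
  density / control_mean
}
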