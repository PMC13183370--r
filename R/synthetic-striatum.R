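# Synthetic striatal sections: a convex CP outline with anatomical landmarks,
# disjoint disk-shaped striosome blobs (MOR1+ patches) covering a target area
# fraction, and cells placed with compartment- and quadrant-specific density
# couplings.

default_cp_polygon <- function(rx = 1500, ry = 1100, k = 48L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(rx * cos(th), ry * sin(th))
}

default_striatal_landmarks <- function(rx = 1500, ry = 1100) {
  xd <- 2 / 3 * rx
  ydor <- -ry * sqrt(1 - (xd / rx)^2)
  striatal_landmarks(
    dorsal_edge_left = c(-xd, ydor),
    dorsal_edge_right = c(xd, ydor),
    ac_point = c(-rx * 0.85, ry * 0.8),
    nacs_tip = c(-rx * 0.8, ry * 0.27),
    lateral_boundary = c(rx, 0))
}

#' Striatal section specification
#'
#' Geometry and density model for one synthetic CP section. Couplings are fold
#' changes applied on top of `base_density`; a scalar recycles over the four
#' quadrants, or a named vector (DM/DL/VM/VL) sets them per quadrant.
#'
#' @param cp_polygon CP outline (um); default is a convex ellipse-like outline
#'   of ~5.2 mm^2, the scale of one hemisphere's dorsal CP cross-section.
#' @param landmarks a [striatal_landmarks()]; default matches the default CP.
#' @param striosome_fraction target striosome fraction of CP area (0-0.5;
#'   default 0.12, the classic MOR1+ share of dorsal striatum).
#' @param striosome_blob_radius_um striosome disk radius (default 120).
#' @param striosome_coupling,matrix_coupling density folds per compartment.
#' @param base_density matrix/striosome reference density, cells/mm^2.
#' @return object of class `striatal_section_spec`.
#' @export
striatal_section_spec <- function(cp_polygon = default_cp_polygon(),
                                  landmarks = default_striatal_landmarks(),
                                  striosome_fraction = 0.12,
                                  striosome_blob_radius_um = 120,
                                  striosome_coupling = 1, matrix_coupling = 1,
                                  base_density = 4.5) {
  if (striosome_fraction < 0 || striosome_fraction >= 0.5)
    stop("striosome_fraction must be in [0, 0.5)")
  if (base_density < 0) stop("base_density must be >= 0")
  norm_coupling <- function(x) {
    q <- c("DM", "DL", "VM", "VL")
    if (length(x) == 1) return(stats::setNames(rep(as.numeric(x), 4), q))
    if (!all(q %in% names(x))) stop("per-quadrant couplings need names DM, DL, VM, VL")
    as.numeric(x[q]) -> v; stats::setNames(v, q)
  }
  structure(list(cp_polygon = as_polygon(cp_polygon), landmarks = landmarks,
                 striosome_fraction = striosome_fraction,
                 striosome_blob_radius_um = striosome_blob_radius_um,
                 striosome_coupling = norm_coupling(striosome_coupling),
                 matrix_coupling = norm_coupling(matrix_coupling),
                 base_density = base_density),
            class = "striatal_section_spec")
}

pack_striosome_disks <- function(cp, fraction, radius, k = 24L) {
  if (fraction == 0) return(list())
  a_cp <- polygon_area(cp)
  n_disks <- max(1L, round(fraction * a_cp / (pi * radius^2)))
  centers <- matrix(numeric(0), ncol = 2)
  xr <- range(cp[, 1]); yr <- range(cp[, 2])
  proto <- disk_polygon(c(0, 0), radius, k)
  tries <- 0L; max_tries <- 4000L * n_disks
  while (nrow(centers) < n_disks) {
    # batch of candidate centers; whole-disk containment tested in one
    # point-in-polygon call over all candidate disk vertices
    batch <- 64L
    tries <- tries + batch
    if (tries > max_tries)
      stop("striosome blob packing failed after ", max_tries,
           " attempts; use a smaller striosome_blob_radius_um")
    c0 <- cbind(stats::runif(batch, xr[1], xr[2]),
                stats::runif(batch, yr[1], yr[2]))
    vx <- rep(c0[, 1], each = k) + rep(proto[, 1], batch)
    vy <- rep(c0[, 2], each = k) + rep(proto[, 2], batch)
    ok <- matrix(points_in_polygon(vx, vy, cp), nrow = k)
    for (b in which(colSums(ok) == k)) {
      if (nrow(centers) == n_disks) break
      if (!nrow(centers) ||
          min(sqrt((centers[, 1] - c0[b, 1])^2 +
                   (centers[, 2] - c0[b, 2])^2)) >= 2 * radius + 10)
        centers <- rbind(centers, c0[b, ])
    }
  }
  out <- lapply(seq_len(nrow(centers)), function(i) {
    p <- sweep(proto, 2, centers[i, ], "+")
    attr(p, "center") <- centers[i, ]
    attr(p, "radius") <- radius
    p
  })
  out
}

#' Generate one synthetic striatal section
#'
#' Packs disjoint striosome disks inside the CP to the target area fraction
#' and places tdTomato cells with compartment- and quadrant-specific densities
#' (Poisson counts, uniform within each compartment-quadrant intersection).
#'
#' @param spec a [striatal_section_spec()].
#' @return list with `cp_polygon`, `striosomes` (list of polygons),
#'   `landmarks`, `partition` (a `quadrant_partition`), and `cells`
#'   (data.frame x_um, y_um, channel, with truth columns quadrant and
#'   compartment).
#' @export
generate_striatal_section <- function(spec) {
  stopifnot(inherits(spec, "striatal_section_spec"))
  cp <- spec$cp_polygon
  partition <- construct_quadrants(cp, spec$landmarks)
  striosomes <- pack_striosome_disks(cp, spec$striosome_fraction,
                                     spec$striosome_blob_radius_um)
  cells <- list()
  ml <- partition$divider_ml; dv <- partition$divider_dv
  side <- function(xy, hp) (xy[, 1] - hp$point[1]) * hp$normal[1] +
    (xy[, 2] - hp$point[2]) * hp$normal[2]
  centers <- if (length(striosomes))
    do.call(rbind, lapply(striosomes, attr, "center")) else NULL
  radius <- if (length(striosomes)) attr(striosomes[[1]], "radius") else 0
  for (q in c("DM", "DL", "VM", "VL")) {
    med <- q %in% c("DM", "VM"); dor <- q %in% c("DM", "DL")
    qpoly <- partition$polygons[[tolower(q)]]
    if (is.null(qpoly)) next
    a_quad <- polygon_area(qpoly)
    d_strio <- spec$base_density * spec$striosome_coupling[[q]]
    d_mat <- spec$base_density * spec$matrix_coupling[[q]]
    in_quad <- function(xy) (if (med) side(xy, ml) >= 0 else side(xy, ml) < 0) &
      (if (dor) side(xy, dv) >= 0 else side(xy, dv) < 0)
    a_strio_total <- 0
    for (sp in striosomes) {
      p <- clip_halfplane(sp, ml$point, if (med) ml$normal else -ml$normal)
      if (is.null(p)) next
      p <- clip_halfplane(p, dv$point, if (dor) dv$normal else -dv$normal)
      if (is.null(p)) next
      a <- polygon_area(p)
      a_strio_total <- a_strio_total + a
      n <- stats::rpois(1, d_strio * a / 1e6)
      if (n > 0) {
        # uniform in the clipped piece: analytic disk draws filtered by the
        # quadrant's half-planes
        got <- matrix(numeric(0), ncol = 2)
        guard <- 0L
        while (nrow(got) < n) {
          xy <- sample_in_disk(4L * (n - nrow(got)) + 8L, attr(sp, "center"),
                               attr(sp, "radius"))
          ok <- in_quad(xy) & points_in_polygon(xy[, 1], xy[, 2], sp)
          got <- rbind(got, xy[ok, , drop = FALSE])
          guard <- guard + 1L
          if (guard > 1000L) stop("striosome cell placement failed")
        }
        got <- got[seq_len(n), , drop = FALSE]
        cells[[length(cells) + 1L]] <- data.frame(
          x_um = got[, 1], y_um = got[, 2], quadrant = q,
          compartment = "striosome")
      }
    }
    a_mat <- a_quad - a_strio_total
    n_mat <- stats::rpois(1, d_mat * a_mat / 1e6)
    if (n_mat > 0) {
      got <- matrix(numeric(0), ncol = 2)
      guard <- 0L
      while (nrow(got) < n_mat) {
        xy <- sample_in_polygon(2L * (n_mat - nrow(got)) + 8L, qpoly)
        in_strio <- if (is.null(centers)) rep(FALSE, nrow(xy))
        else {
          d2 <- outer(xy[, 1], centers[, 1], "-")^2 +
            outer(xy[, 2], centers[, 2], "-")^2
          rowSums(d2 <= radius^2) > 0
        }
        got <- rbind(got, xy[!in_strio, , drop = FALSE])
        guard <- guard + 1L
        if (guard > 1000L) stop("matrix cell placement failed")
      }
      got <- got[seq_len(n_mat), , drop = FALSE]
      cells[[length(cells) + 1L]] <- data.frame(
        x_um = got[, 1], y_um = got[, 2], quadrant = q, compartment = "matrix")
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells)
  else data.frame(x_um = numeric(0), y_um = numeric(0),
                  quadrant = character(0), compartment = character(0))
  cells$channel <- rep("tdTomato", nrow(cells))
  rownames(cells) <- NULL
  list(cp_polygon = cp, striosomes = striosomes, landmarks = spec$landmarks,
       partition = partition, cells = cells)
}

#' Generate a striatal cohort with exposure-dependent compartment couplings
#'
#' Simulates the compartment analysis design: unexposed controls at baseline
#' density everywhere; female-exposure mice with per-quadrant striosome and
#' matrix density folds. Defaults reproduce the published fold pattern
#' (striosome enrichment in DM/VM, matrix enrichment in VL). Each mouse
#' contributes `n_sections` sections per hemisphere.
#'
#' @param n_exposed,n_control group sizes.
#' @param exposed_striosome,exposed_matrix named fold vectors (DM/DL/VM/VL)
#'   for the female-exposure group.
#' @param n_sections rostral CP sections per hemisphere per mouse.
#' @param mouse_cv lognormal between-mouse density coefficient of variation.
#' @param spec base [striatal_section_spec()] (couplings are overridden).
#' @return list with `mice` (mouse_id, group) and `sections` (list per mouse
#'   of [generate_striatal_section()] outputs).
#' @export
generate_striatal_cohort <- function(n_exposed = 9, n_control = 7,
                                     exposed_striosome = c(DM = 1.94, DL = 1.20,
                                                           VM = 1.95, VL = 1.19),
                                     exposed_matrix = c(DM = 1.17, DL = 1.30,
                                                        VM = 1.31, VL = 2.06),
                                     n_sections = 3, mouse_cv = 0.2,
                                     spec = striatal_section_spec()) {
  mice <- data.frame(
    mouse_id = c(sprintf("FE%02d", seq_len(n_exposed)),
                 sprintf("NE%02d", seq_len(n_control))),
    group = rep(c("female-exposure", "no-exposure"), c(n_exposed, n_control)),
    stringsAsFactors = FALSE)
  sig <- sqrt(log(1 + mouse_cv^2))
  sections <- list()
  for (i in seq_len(nrow(mice))) {
    exposed <- mice$group[i] == "female-exposure"
    mfx <- stats::rlnorm(1, 0, sig)
    sp <- spec
    sp$base_density <- spec$base_density * mfx
    sp$striosome_coupling <- if (exposed) {
      q <- c("DM", "DL", "VM", "VL")
      stats::setNames(as.numeric(exposed_striosome[q]), q)
    } else spec$striosome_coupling * 0 + 1
    sp$matrix_coupling <- if (exposed) {
      q <- c("DM", "DL", "VM", "VL")
      stats::setNames(as.numeric(exposed_matrix[q]), q)
    } else spec$matrix_coupling * 0 + 1
    sections[[mice$mouse_id[i]]] <-
      lapply(seq_len(2L * n_sections), function(s) generate_striatal_section(sp))
  }
  list(mice = mice, sections = sections)
}

#' Per-mouse compartment densities and control-normalized folds
#'
#' Pools each mouse's sections (counts and intersection areas summed per
#' quadrant x compartment), computes densities, and normalizes every mouse to
#' the no-exposure group mean of the matching quadrant/compartment.
#'
#' @param cohort a [generate_striatal_cohort()] result.
#' @return data.frame: mouse_id, group, quadrant, compartment, n_cells,
#'   area_mm2, density, fold_vs_control.
#' @export
striatal_fold_table <- function(cohort) {
  rows <- list()
  for (i in seq_len(nrow(cohort$mice))) {
    mid <- cohort$mice$mouse_id[i]
    per_sec <- lapply(cohort$sections[[mid]], function(sec)
      compartment_density(sec$cells, sec$partition, sec$striosomes))
    pooled <- do.call(rbind, per_sec)
    agg <- stats::aggregate(cbind(n_cells, area_mm2) ~ quadrant + compartment,
                            data = pooled, FUN = sum)
    agg$density <- ifelse(agg$area_mm2 > 0, agg$n_cells / agg$area_mm2, 0)
    agg$mouse_id <- mid
    agg$group <- cohort$mice$group[i]
    rows[[mid]] <- agg
  }
  tab <- do.call(rbind, rows)
  ctrl <- tab[tab$group == "no-exposure", ]
  cm <- stats::aggregate(density ~ quadrant + compartment, data = ctrl, FUN = mean)
  names(cm)[3] <- "control_mean"
  tab <- merge(tab, cm, by = c("quadrant", "compartment"))
  tab$fold_vs_control <- normalize_to_control(tab$density, tab$control_mean)
  tab$control_mean <- NULL
  rownames(tab) <- NULL
  tab[order(tab$mouse_id, tab$quadrant, tab$compartment),
      c("mouse_id", "group", "quadrant", "compartment",
        "n_cells", "area_mm2", "density", "fold_vs_control")]
}
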