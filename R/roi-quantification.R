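# ROI-based quantification: cell-to-polygon assignment, densities (cells/mm^2),
# mutual-nearest-neighbor double-label matching, bregma-based subregion
# splitting, and per-mouse aggregation.
#
# Conventions (declared in every output file header): coordinates in um,
# origin at the image top-left, y increasing ventrally; bregma in mm, positive
# anterior. Boundary cells count as inside; boundary bregma values go to the
# more rostral subregion; hemispheres are pooled within a section before the
# density is computed.

#' ROI annotation
#'
#' @param region region label.
#' @param hemisphere "left" or "right".
#' @param bregma_mm anteroposterior coordinate, mm, positive anterior.
#' @param polygon simple closed polygon in um (matrix, columns x/y).
#' @return object of class `roi_annotation` with derived `area_mm2`.
#' @export
roi_annotation <- function(region, hemisphere, bregma_mm, polygon) {
  polygon <- as_polygon(polygon)
  area_um2 <- polygon_area(polygon)
  if (area_um2 <= 0) stop("ROI polygon has zero area")
  structure(list(region = region, hemisphere = hemisphere,
                 bregma_mm = bregma_mm, polygon = polygon,
                 area_mm2 = area_um2 / 1e6),
            class = "roi_annotation")
}

#' Keep cells inside an ROI polygon
#'
#' Centroid-in-polygon filter; boundary (including vertices) counts as inside.
#'
#' @param cells data.frame with x_um, y_um.
#' @param roi a [roi_annotation()] or a polygon matrix.
#' @return the subset of `cells` inside the ROI.
#' @export
assign_cells <- function(cells, roi) {
  poly <- if (inherits(roi, "roi_annotation")) roi$polygon else roi
  cells[points_in_polygon(cells$x_um, cells$y_um, poly), , drop = FALSE]
}

#' Cell density within an ROI
#'
#' @param cells detection table already restricted to one channel, or an
#'   integer count.
#' @param roi a [roi_annotation()], or an area in mm^2.
#' @return density in cells/mm^2.
#' @export
cell_density <- function(cells, roi) {
  n <- if (is.data.frame(cells)) nrow(cells) else as.numeric(cells)
  area <- if (inherits(roi, "roi_annotation")) roi$area_mm2 else as.numeric(roi)
  if (area <= 0) stop("ROI area must be > 0")
  n / area
}

#' Match double-labeled (reactivated) cells across channels
#'
#' One-to-one matching of tdTomato and c-Fos centroids: candidate pairs within
#' `tol_um` are accepted greedily by ascending distance (ties broken by
#' ascending tdTomato then c-Fos index), each cell used at most once. The
#' result is symmetric in the two channels.
#'
#' @param td,fos data.frames with x_um, y_um (one channel each).
#' @param tol_um matching tolerance (default 8 um, about a nuclear radius at
#'   the 10-um detection scale).
#' @return data.frame with td_idx, fos_idx, dist_um (zero rows if no match).
#' @export
match_double_labeled <- function(td, fos, tol_um = 8) {
  empty <- data.frame(td_idx = integer(0), fos_idx = integer(0),
                      dist_um = numeric(0))
  n1 <- nrow(td); n2 <- nrow(fos)
  if (!n1 || !n2) return(empty)
  dx <- outer(td$x_um, fos$x_um, "-")
  dy <- outer(td$y_um, fos$y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= tol_um, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  dist <- d[cand]
  o <- order(dist, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]; dist <- dist[o]
  used1 <- logical(n1); used2 <- logical(n2)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used1[i] && !used2[j]) {
      keep[k] <- TRUE; used1[i] <- TRUE; used2[j] <- TRUE
    }
  }
  data.frame(td_idx = cand[keep, 1], fos_idx = cand[keep, 2],
             dist_um = dist[keep])
}

#' Double-labeling percentages
#'
#' Percentage of double-labeled cells among each channel's total. A zero
#' denominator yields NA with `flagged = TRUE`; flagged records are excluded
#' from group statistics.
#'
#' @param n_double,n_cfos,n_tdtomato counts.
#' @return list with pct_double_of_cfos, pct_double_of_tdtomato, flagged.
#' @export
double_label_percentages <- function(n_double, n_cfos, n_tdtomato) {
  if (n_double > min(n_cfos, n_tdtomato))
    stop("n_double cannot exceed either channel's total")
  list(pct_double_of_cfos = if (n_cfos > 0) 100 * n_double / n_cfos else NA_real_,
       pct_double_of_tdtomato = if (n_tdtomato > 0) 100 * n_double / n_tdtomato
                                else NA_real_,
       flagged = n_cfos == 0 || n_tdtomato == 0)
}

#' Default bregma subregion rules
#'
#' The caudoputamen splits into rostral/caudal/tail at +0.62 and -1.02 mm; the
#' periaqueductal gray splits into rostral/caudal at -4.2 mm. Boundaries
#' belong to the more rostral subregion.
#'
#' @return named list of rules usable by [split_by_bregma()].
#' @export
default_bregma_rules <- function() {
  list(
    CPu = list(breaks = c(0.62, -1.02), labels = c("rCPu", "cCPu", "tCPu")),
    PAG = list(breaks = -4.2, labels = c("rPAG", "cPAG")))
}

#' Assign subregion labels by bregma coordinate
#'
#' Half-open intervals defined by descending break points; a section exactly
#' on a break goes to the more rostral subregion. Regions without a rule keep
#' their name as the subregion. Sections outside a rule's optional `span` are
#' flagged with NA and excluded downstream.
#'
#' @param records data.frame with columns region and bregma_mm.
#' @param rules named list: per region, list(breaks = descending numeric,
#'   labels = character of length length(breaks) + 1, span = optional
#'   length-2 limits).
#' @return `records` with an added `subregion` column.
#' @export
split_by_bregma <- function(records, rules = default_bregma_rules()) {
  sub <- records$region
  for (rn in names(rules)) {
    rule <- rules[[rn]]
    idx <- which(records$region == rn)
    if (!length(idx)) next
    b <- records$bregma_mm[idx]
    breaks <- sort(rule$breaks, decreasing = TRUE)
    lab <- rep(rule$labels[length(rule$labels)], length(b))
    for (k in rev(seq_along(breaks))) lab[b >= breaks[k]] <- rule$labels[k]
    if (!is.null(rule$span))
      lab[b < min(rule$span) | b > max(rule$span)] <- NA_character_
    sub[idx] <- lab
  }
  records$subregion <- sub
  records
}

#' Average per-section densities within mouse and (sub)region
#'
#' Unweighted mean of per-section densities (sections are the replicates),
#' with the section count recorded.
#'
#' @param records data.frame with mouse_id, region (and optionally subregion,
#'   channel), section_id, density.
#' @return aggregated data.frame with columns mouse_id, region (subregion,
#'   channel if present), n_sections, density.
#' @export
aggregate_mouse <- function(records) {
  by_cols <- intersect(c("mouse_id", "group", "region", "subregion", "channel"),
                       names(records))
  records <- records[!is.na(records[[if ("subregion" %in% by_cols) "subregion"
                                     else "region"]]), , drop = FALSE]
  f <- stats::as.formula(paste("density ~", paste(by_cols, collapse = " + ")))
  out <- stats::aggregate(f, data = records, FUN = mean)
  cnt <- stats::aggregate(f, data = records, FUN = length)
  names(cnt)[names(cnt) == "density"] <- "n_sections"
  merge(out, cnt, by = by_cols)
}

#' Quantify a synthetic cohort into a long density table
#'
#' Runs the full ROI quantification on a [generate_cohort()] result:
#' re-assigns every detection to its region polygons (both hemispheres pooled
#' per section), computes per-section densities, averages across sections per
#' mouse, matches double-labeled cells per section, and attaches
#' double-labeling percentages per mouse.
#'
#' @param cohort a `usv_cohort`.
#' @param rules bregma subregion rules for [split_by_bregma()].
#' @param tol_um double-label matching tolerance.
#' @return data.frame (`density_long`): mouse_id, group, region, subregion,
#'   channel, n_sections, n_cells, n_double, area_mm2, density,
#'   pct_double_of_cfos, pct_double_of_tdtomato.
#' @export
quantify_cohort <- function(cohort, rules = list(), tol_um = 8) {
  stopifnot(inherits(cohort, "usv_cohort"))
  cells <- cohort$cells
  rows <- list()
  for (rn in names(cohort$rois)) {
    roi <- cohort$rois[[rn]]
    rcells <- cells[cells$region == rn, , drop = FALSE]
    keep <- rep(FALSE, nrow(rcells))
    for (hemi in c("left", "right")) {
      hsel <- rcells$hemisphere == hemi
      if (any(hsel))
        keep[hsel] <- points_in_polygon(rcells$x_um[hsel], rcells$y_um[hsel],
                                        roi$polygons[[hemi]])
    }
    rcells <- rcells[keep, , drop = FALSE]
    for (mid in cohort$mice$mouse_id) {
      mc <- rcells[rcells$mouse_id == mid, , drop = FALSE]
      secs <- unique(cells[cells$region == rn & cells$mouse_id == mid,
                           c("section_id", "bregma_mm")])
      if (!nrow(secs)) next
      for (si in seq_len(nrow(secs))) {
        sc <- mc[mc$section_id == secs$section_id[si], , drop = FALSE]
        td <- sc[sc$channel == "tdTomato", , drop = FALSE]
        fos <- sc[sc$channel == "cFos", , drop = FALSE]
        pairs <- match_double_labeled(td, fos, tol_um)
        for (ch in c("tdTomato", "cFos")) {
          n <- if (ch == "tdTomato") nrow(td) else nrow(fos)
          rows[[length(rows) + 1L]] <- data.frame(
            mouse_id = mid,
            group = cohort$mice$group[cohort$mice$mouse_id == mid],
            region = rn, section_id = secs$section_id[si],
            bregma_mm = secs$bregma_mm[si], channel = ch,
            n_cells = n, n_td = nrow(td), n_fos = nrow(fos),
            n_double = nrow(pairs), area_mm2 = roi$area_mm2,
            density = cell_density(n, roi$area_mm2))
        }
      }
    }
  }
  long <- do.call(rbind, rows)
  long <- split_by_bregma(long, rules)
  agg <- aggregate_mouse(long[, c("mouse_id", "group", "region", "subregion",
                                  "channel", "section_id", "density")])
  # per-mouse totals for double-label percentages (pooled over sections)
  tot <- stats::aggregate(cbind(n_cells, n_double, area_mm2) ~
                            mouse_id + group + region + subregion + channel,
                          data = long[!is.na(long$subregion), ], FUN = sum)
  out <- merge(agg, tot, by = c("mouse_id", "group", "region", "subregion",
                                "channel"))
  td_tot <- out[out$channel == "tdTomato", c("mouse_id", "region", "subregion",
                                             "n_cells", "n_double")]
  names(td_tot)[4:5] <- c("n_td_total", "n_double_total")
  out <- merge(out, td_tot, by = c("mouse_id", "region", "subregion"))
  fos_tot <- out[out$channel == "cFos", c("mouse_id", "region", "subregion", "n_cells")]
  names(fos_tot)[4] <- "n_fos_total"
  out <- merge(out, fos_tot, by = c("mouse_id", "region", "subregion"))
  out$pct_double_of_cfos <- ifelse(out$n_fos_total > 0,
                                   100 * out$n_double_total / out$n_fos_total,
                                   NA_real_)
  out$pct_double_of_tdtomato <- ifelse(out$n_td_total > 0,
                                       100 * out$n_double_total / out$n_td_total,
                                       NA_real_)
  out$n_double <- out$n_double_total
  rownames(out) <- NULL
  out[order(out$region, out$subregion, out$channel, out$mouse_id),
      c("mouse_id", "group", "region", "subregion", "channel", "n_sections",
        "n_cells", "n_double", "area_mm2", "density",
        "pct_double_of_cfos", "pct_double_of_tdtomato")]
}

#' Per-section density table for one region
#'
#' Section-level densities (hemispheres pooled) for anteroposterior
#' profiling: one row per mouse x section.
#'
#' @param cohort a `usv_cohort`.
#' @param region region name.
#' @param channel channel.
#' @param group restrict to one group (default the female-exposure mice, the
#'   ones with USV counts); NULL keeps all.
#' @return data.frame with mouse_id, section_id, bregma_mm, n_cells, density.
#' @export
section_density_table <- function(cohort, region, channel = "tdTomato",
                                  group = "female-exposure") {
  stopifnot(inherits(cohort, "usv_cohort"))
  roi <- cohort$rois[[region]]
  if (is.null(roi)) stop("unknown region: ", region)
  mice <- if (is.null(group)) cohort$mice
          else cohort$mice[cohort$mice$group == group, ]
  cells <- cohort$cells[cohort$cells$region == region &
                          cohort$cells$channel == channel &
                          cohort$cells$mouse_id %in% mice$mouse_id, ]
  secs <- unique(cohort$cells[cohort$cells$region == region &
                                cohort$cells$mouse_id %in% mice$mouse_id,
                              c("mouse_id", "section_id", "bregma_mm")])
  rows <- lapply(seq_len(nrow(secs)), function(i) {
    sc <- cells[cells$mouse_id == secs$mouse_id[i] &
                  cells$section_id == secs$section_id[i], ]
    data.frame(mouse_id = secs$mouse_id[i], section_id = secs$section_id[i],
               bregma_mm = secs$bregma_mm[i], n_cells = nrow(sc),
               density = nrow(sc) / roi$area_mm2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read ROI annotations from GeoJSON
#'
#' Parses a FeatureCollection of Polygon features with properties `region`,
#' `hemisphere`, and `bregma_mm` (coordinates in um).
#'
#' @param path GeoJSON file path.
#' @return list of [roi_annotation()] objects.
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a FeatureCollection")
  lapply(gj$features, function(ft) {
    if (!identical(ft$geometry$type, "Polygon"))
      stop("only Polygon geometries are supported")
    ring <- ft$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))[1:2]))
    pr <- ft$properties
    roi_annotation(region = pr$region %||% NA_character_,
                   hemisphere = pr$hemisphere %||% NA_character_,
                   bregma_mm = as.numeric(pr$bregma_mm %||% NA_real_),
                   polygon = poly)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simple blob detector for synthetic single-channel images
#'
#' Morphological background subtraction (top-hat with a disk of the background
#' radius), median filtering, global intensity thresholding, and connected
#' components; returns centroids and areas. Defaults follow the detection
#' settings used for the fluorescence channels (background radius 10 um;
#' median radius 10 um and threshold 20 for the tdTomato channel, 8 um and 10
#' for c-Fos). Intended for synthetic images only; real data enter as
#' detection tables.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param um_per_px pixel scale; required.
#' @param background_radius_um,median_radius_um,intensity_threshold detection
#'   parameters.
#' @return data.frame with x_um, y_um, intensity, area_um2.
#' @export
detect_cells_simple <- function(image, um_per_px,
                                background_radius_um = 10,
                                median_radius_um = 10,
                                intensity_threshold = 20) {
  if (missing(um_per_px) || is.null(um_per_px) || !is.finite(um_per_px))
    stop("um_per_px pixel scale is required")
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("detect_cells_simple requires the EBImage package")
  img <- EBImage::Image(t(image))  # EBImage is column-major x,y
  rb <- max(1L, round(background_radius_um / um_per_px))
  mb <- max(1L, round(median_radius_um / um_per_px))
  bg <- EBImage::opening(img, EBImage::makeBrush(2L * rb + 1L, "disc"))
  sub <- img - bg
  sub <- EBImage::medianFilter(sub / max(sub@.Data, 1), mb) * max(sub@.Data, 1)
  mask <- sub > intensity_threshold
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), area_um2 = numeric(0)))
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  px <- lab@.Data
  peak <- vapply(seq_len(n), function(i) max(image[t(px) == i]), 0)
  data.frame(x_um = (mom[, "m.cx"] - 0.5) * um_per_px,
             y_um = (mom[, "m.cy"] - 0.5) * um_per_px,
             intensity = peak,
             area_um2 = shp[, "s.area"] * um_per_px^2)
}
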