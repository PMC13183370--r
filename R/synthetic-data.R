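# Synthetic cohort generator. Emulates a two-session double-label mapping
# experiment: per-mouse USV counts, per-region/per-section cell detection
# tables in two channels (tdTomato = session-1 tag, c-Fos = session-2 acute
# marker), ROI polygons with bregma coordinates, and a ground-truth ledger.

#' Region specification for the synthetic cohort
#'
#' Describes one brain region's baseline labeling density, its response to
#' female exposure, and how tightly its per-mouse density tracks the number of
#' USVs emitted.
#'
#' @param name region label.
#' @param bregma_span_mm length-2 numeric, anteroposterior extent in mm
#'   (positive = anterior); order is normalized to c(caudal, rostral).
#' @param baseline_density expected cells/mm^2 in unexposed animals.
#' @param exposure_multiplier fold change in exposed animals (>= 0).
#' @param usv_coupling target sample Pearson correlation, in [-1, 1], between
#'   per-mouse density and USV count among exposed mice.
#' @param reactivation_prob probability that a session-1 tagged cell is
#'   re-labeled by c-Fos in session 2 (in [0, 1]).
#' @param roi_area_mm2 ROI area per section, both hemispheres pooled.
#' @param coupling_bregma_span optional length-2 numeric restricting the USV
#'   coupling to a sub-span of the region (sections outside it follow the
#'   exposure effect only). NULL couples the whole region.
#' @param noise_cv lognormal between-mouse coefficient of variation of density.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(name, bregma_span_mm, baseline_density,
                        exposure_multiplier = 1, usv_coupling = 0,
                        reactivation_prob = 0.3, roi_area_mm2 = 1,
                        coupling_bregma_span = NULL, noise_cv = 0.15) {
  stopifnot(length(bregma_span_mm) == 2, is.finite(bregma_span_mm))
  if (baseline_density < 0) stop("baseline_density must be >= 0")
  if (exposure_multiplier < 0) stop("exposure_multiplier must be >= 0")
  if (abs(usv_coupling) > 1) stop("usv_coupling must be in [-1, 1]")
  if (reactivation_prob < 0 || reactivation_prob > 1)
    stop("reactivation_prob must be in [0, 1]")
  if (roi_area_mm2 <= 0) stop("roi_area_mm2 must be > 0")
  structure(list(
    name = as.character(name),
    bregma_span_mm = sort(as.numeric(bregma_span_mm)),
    baseline_density = baseline_density,
    exposure_multiplier = exposure_multiplier,
    usv_coupling = usv_coupling,
    reactivation_prob = reactivation_prob,
    roi_area_mm2 = roi_area_mm2,
    coupling_bregma_span = if (is.null(coupling_bregma_span)) NULL
                           else sort(as.numeric(coupling_bregma_span)),
    noise_cv = noise_cv
  ), class = "region_spec")
}

#' Cohort configuration
#'
#' Study-design parameters for a synthetic experiment: group sizes, sectioning
#' scheme (30-um coronal sections collected into 12 parallel series, i.e.
#' 360-um within-series spacing), and the per-mouse USV count distribution
#' (negative binomial for exposed mice; unexposed controls emit none).
#'
#' @param regions list of [region_spec()] objects.
#' @param n_exposed,n_control group sizes (each >= 3).
#' @param section_thickness_um section thickness (default 30).
#' @param n_series number of parallel section series (default 12).
#' @param usv_mean,usv_dispersion negative-binomial mean and size for exposed
#'   mice's USV counts.
#' @param master_seed integer seed; all randomness derives from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(regions, n_exposed = 9, n_control = 7,
                          section_thickness_um = 30, n_series = 12,
                          usv_mean = 120, usv_dispersion = 2,
                          master_seed = 1) {
  if (n_exposed < 3 || n_control < 3) stop("need >= 3 mice per group")
  if (!length(regions) || !all(vapply(regions, inherits, TRUE, "region_spec")))
    stop("regions must be a non-empty list of region_spec objects")
  nms <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate region names")
  names(regions) <- nms
  structure(list(
    regions = regions, n_exposed = n_exposed, n_control = n_control,
    section_thickness_um = section_thickness_um, n_series = n_series,
    section_spacing_um = section_thickness_um * n_series,
    usv_mean = usv_mean, usv_dispersion = usv_dispersion,
    master_seed = as.integer(master_seed)
  ), class = "cohort_config")
}

# ROI polygon template for a region: a regular 12-gon per hemisphere, each
# holding half the region's per-section area, mirrored about x = 0.
region_roi_polygons <- function(area_mm2) {
  half_um2 <- area_mm2 / 2 * 1e6
  k <- 12L
  R <- sqrt(2 * half_um2 / (k * sin(2 * pi / k)))
  base <- disk_polygon(c(0, 0), R, k)  # circumradius form of the 12-gon
  # regular k-gon area = 0.5 k R^2 sin(2 pi / k); R chosen to match half_um2
  off <- R * 1.6
  list(left = sweep(base, 2, c(-off, 0), "+"),
       right = sweep(base, 2, c(off, 0), "+"))
}

# Solve the coupling exponent beta so that the expected sample Pearson
# correlation between realized per-mouse density and USV count matches the
# target. Density model: m_i = B * exp(beta * z_i + eps_i), eps ~ N(0, sig2),
# counts Poisson(m_i * area). The expected sample r is approximated by
#   cov(mu(beta), u) / sqrt((var(mu) + mean(lognormal var + Poisson var)) var(u))
# conditioned on the realized USV design, and inverted on a grid + uniroot.
solve_coupling_beta <- function(target_r, usv, base_density, sig2, area_tot_mm2) {
  if (target_r == 0) return(0)
  z <- as.numeric(scale(usv))
  expected_r <- function(beta) {
    if (beta == 0) return(0)
    mu <- base_density * exp(beta * z + sig2 / 2)
    v_noise <- mean(mu^2 * (exp(sig2) - 1) + mu / area_tot_mm2)
    stats::cov(mu, usv) / sqrt((stats::var(mu) + v_noise) * stats::var(usv))
  }
  grid <- seq(0, 4, by = 0.02) * sign(target_r)
  f <- vapply(grid, expected_r, 0)
  achievable <- if (target_r > 0) max(f) else min(f)
  if (abs(achievable) < abs(target_r)) {
    warning("target coupling ", target_r, " not achievable at this noise level; ",
            "using best attainable ", signif(achievable, 3))
    return(grid[if (target_r > 0) which.max(f) else which.min(f)])
  }
  idx <- which(abs(f) >= abs(target_r))[1]
  lo <- grid[idx - 1L]; hi <- grid[idx]
  stats::uniroot(function(b) expected_r(b) - target_r, c(min(lo, hi), max(lo, hi)),
                 tol = 1e-6)$root
}

#' Place synthetic cells inside an ROI polygon
#'
#' Draws a Poisson number of tdTomato cells (mean = density x area), uniformly
#' inside the polygon, then builds the c-Fos channel as a mixture of
#' reactivated cells (each tdTomato cell re-labeled with probability
#' `reactivation_prob`, displaced by a Gaussian jitter truncated at 2 um so
#' that truth is unambiguous at the 8-um matching tolerance) plus independent
#' c-Fos-only cells at density `cfos_density`.
#'
#' @param polygon ROI polygon in um (matrix, columns x/y).
#' @param density tdTomato density, cells/mm^2.
#' @param cfos_density density of c-Fos cells not shared with the tdTomato
#'   ensemble; the default keeps the two channels' expected totals equal.
#' @param reactivation_prob per-cell re-label probability.
#' @return data.frame with columns x_um, y_um, channel ("tdTomato"/"cFos"),
#'   intensity, area_um2.
#' @export
place_cells <- function(polygon, density,
                        cfos_density = density * (1 - reactivation_prob),
                        reactivation_prob = 0) {
  area_um2 <- polygon_area(polygon)
  if (area_um2 <= 0) stop("degenerate polygon: area is 0")
  if (density < 0 || cfos_density < 0) stop("densities must be >= 0")
  area_mm2 <- area_um2 / 1e6
  n_td <- stats::rpois(1, density * area_mm2)
  td <- sample_in_polygon(n_td, polygon)
  react <- if (n_td > 0) stats::runif(n_td) < reactivation_prob else logical(0)
  n_react <- sum(react)
  jitter <- function(n) {
    r <- pmin(abs(stats::rnorm(n, 0, 0.8)), 2)
    th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  }
  fos_react <- if (n_react > 0) td[react, , drop = FALSE] + jitter(n_react)
               else matrix(numeric(0), ncol = 2)
  n_extra <- stats::rpois(1, cfos_density * area_mm2)
  fos <- rbind(fos_react, sample_in_polygon(n_extra, polygon))
  n_fos <- nrow(fos)
  mk <- function(xy, channel, mean_area) {
    n <- nrow(xy)
    data.frame(x_um = xy[, 1], y_um = xy[, 2],
               channel = rep(channel, n),
               intensity = stats::rlnorm(n, log(50), 0.3),
               area_um2 = pmax(stats::rnorm(n, mean_area, 15), 20))
  }
  rbind(mk(td, "tdTomato", 80), mk(fos, "cFos", 60))
}

#' Generate a complete synthetic cohort
#'
#' Produces per-mouse USV counts (controls emit none), per-region per-section
#' cell detection tables for both channels, ROI annotations, and a
#' ground-truth ledger (true functional category and realized density-USV
#' correlation per region). Deterministic given `config$master_seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `usv_cohort`: list with elements `mice`
#'   (mouse_id, group, usv_count), `cells` (one detection table; columns
#'   mouse_id, region, section_id, bregma_mm, hemisphere, x_um, y_um, channel,
#'   intensity, area_um2), `rois` (per-region hemisphere polygons and area),
#'   `truth`, and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$master_seed)
  child <- sample.int(.Machine$integer.max - 1L, 3L)

  # --- per-mouse USV counts -------------------------------------------------
  set.seed(child[1])
  repeat {
    usv_exposed <- stats::rnbinom(config$n_exposed, mu = config$usv_mean,
                                  size = config$usv_dispersion)
    if (stats::sd(usv_exposed) > 0) break
  }
  mice <- data.frame(
    mouse_id = c(sprintf("FE%02d", seq_len(config$n_exposed)),
                 sprintf("NE%02d", seq_len(config$n_control))),
    group = rep(c("female-exposure", "no-exposure"),
                c(config$n_exposed, config$n_control)),
    usv_count = c(usv_exposed, rep(0L, config$n_control)),
    stringsAsFactors = FALSE)

  spacing_mm <- config$section_spacing_um / 1000
  set.seed(child[2])
  phase <- stats::runif(nrow(mice), 0, spacing_mm)  # per-mouse series offset
  names(phase) <- mice$mouse_id

  # --- per-region density model --------------------------------------------
  set.seed(child[3])
  z <- as.numeric(scale(usv_exposed))
  cells_list <- list(); rois <- list(); truth <- list()
  for (rs in config$regions) {
    sig2 <- log(1 + rs$noise_cv^2)
    span <- rs$bregma_span_mm
    n_sections_approx <- max(1, floor(diff(span) / spacing_mm))
    area_tot <- rs$roi_area_mm2 * n_sections_approx
    B_exp <- rs$baseline_density * rs$exposure_multiplier
    beta <- if (B_exp > 0)
      solve_coupling_beta(rs$usv_coupling, usv_exposed, B_exp, sig2, area_tot)
    else 0
    eps  <- stats::rnorm(nrow(mice), 0, sqrt(sig2))
    eps2 <- stats::rnorm(nrow(mice), 0, sqrt(sig2))
    exposed <- mice$group == "female-exposure"
    # coupled density (applies inside coupling_bregma_span, or everywhere)
    m_coupled <- ifelse(exposed,
                        B_exp * exp(beta * c(z, rep(0, config$n_control)) + eps),
                        rs$baseline_density * exp(eps))
    # uncoupled density for sections outside the coupling span
    m_flat <- ifelse(exposed, B_exp * exp(eps2), rs$baseline_density * exp(eps2))
    polys <- region_roi_polygons(rs$roi_area_mm2)
    rois[[rs$name]] <- list(polygons = polys, area_mm2 = rs$roi_area_mm2,
                            bregma_span_mm = span)
    reg_cells <- list()
    for (i in seq_len(nrow(mice))) {
      bregmas <- seq(span[2] - phase[i] %% spacing_mm, span[1], by = -spacing_mm)
      bregmas <- bregmas[bregmas >= span[1] & bregmas <= span[2]]
      if (!length(bregmas)) bregmas <- mean(span)
      for (si in seq_along(bregmas)) {
        b <- bregmas[si]
        in_span <- is.null(rs$coupling_bregma_span) ||
          (b >= rs$coupling_bregma_span[1] && b <= rs$coupling_bregma_span[2])
        m <- if (in_span) m_coupled[i] else m_flat[i]
        for (hemi in c("left", "right")) {
          tab <- place_cells(polys[[hemi]], m,
                             cfos_density = m * (1 - rs$reactivation_prob),
                             reactivation_prob = rs$reactivation_prob)
          if (nrow(tab)) {
            tab$mouse_id <- mice$mouse_id[i]; tab$region <- rs$name
            tab$section_id <- sprintf("s%02d", si); tab$bregma_mm <- b
            tab$hemisphere <- hemi
            reg_cells[[length(reg_cells) + 1L]] <- tab
          }
        }
      }
    }
    reg_tab <- do.call(rbind, reg_cells)
    cells_list[[rs$name]] <- reg_tab
    # realized per-mouse density (exposed) for the truth ledger
    realized_r <- NA_real_
    if (!is.null(reg_tab)) {
      dens <- vapply(mice$mouse_id[exposed], function(mid) {
        sub <- reg_tab[reg_tab$mouse_id == mid & reg_tab$channel == "tdTomato", ]
        n_sec <- length(unique(paste(sub$section_id)))
        if (!nrow(sub)) 0 else nrow(sub) / (max(n_sec, 1) * rs$roi_area_mm2)
      }, 0)
      if (stats::sd(dens) > 0) realized_r <- stats::cor(dens, usv_exposed)
    }
    truth[[rs$name]] <- list(
      category = true_category(rs), beta = beta,
      usv_coupling = rs$usv_coupling,
      exposure_multiplier = rs$exposure_multiplier,
      reactivation_prob = rs$reactivation_prob,
      expected_density = m_coupled, realized_r = realized_r)
  }
  cells <- do.call(rbind, unname(cells_list))
  cols <- c("mouse_id", "region", "section_id", "bregma_mm", "hemisphere",
            "x_um", "y_um", "channel", "intensity", "area_um2")
  if (is.null(cells)) {
    cells <- as.data.frame(stats::setNames(
      c(list(character(0), character(0), character(0), numeric(0), character(0)),
        list(numeric(0), numeric(0), character(0), numeric(0), numeric(0))), cols))
  }
  rownames(cells) <- NULL
  structure(list(mice = mice, cells = cells[, cols], rois = rois,
                 truth = truth, config = config),
            class = "usv_cohort")
}

true_category <- function(rs) {
  if (rs$usv_coupling > 0) "usv-positive"
  else if (rs$usv_coupling < 0) "usv-negative"
  else if (rs$exposure_multiplier != 1) "social-interaction-related"
  else "unrelated"
}

#' @export
print.usv_cohort <- function(x, ...) {
  cat("Synthetic USV mapping cohort\n")
  cat("  mice:", sum(x$mice$group == "female-exposure"), "female-exposure /",
      sum(x$mice$group == "no-exposure"), "no-exposure\n")
  cat("  regions:", paste(names(x$rois), collapse = ", "), "\n")
  cat("  detections:", nrow(x$cells), "cells\n")
  invisible(x)
}

#' Write a cohort to plain-text fixture files
#'
#' Writes `mice.csv`, one `cells_<mouse>.csv` per animal, and
#' `rois.geojson` (one FeatureCollection; properties region, hemisphere,
#' bregma span). Coordinates are um, origin top-left, y increasing ventrally;
#' bregma in mm, positive anterior.
#'
#' @param cohort a `usv_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "usv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$mice, file.path(dir, "mice.csv"), row.names = FALSE)
  for (mid in cohort$mice$mouse_id) {
    sub <- cohort$cells[cohort$cells$mouse_id == mid, ]
    utils::write.csv(sub, file.path(dir, sprintf("cells_%s.csv", mid)),
                     row.names = FALSE)
  }
  feats <- list()
  for (rn in names(cohort$rois)) {
    roi <- cohort$rois[[rn]]
    for (hemi in c("left", "right")) {
      poly <- roi$polygons[[hemi]]
      ring <- rbind(poly, poly[1, , drop = FALSE])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(region = rn, hemisphere = hemi,
                          bregma_span_mm = roi$bregma_span_mm),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(i) ring[i, ]))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "rois.geojson"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
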