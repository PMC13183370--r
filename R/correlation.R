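# Pearson correlation of per-region activation with USV counts, the
# three-way functional classification of brain regions, and bregma-resolved
# anteroposterior (AP) correlation profiling.
#
# Correlations use exposed mice only: unexposed controls emit no USVs, and
# including their zeros would manufacture correlation.

#' Correlate per-mouse region density with USV counts
#'
#' Product-moment r, R^2 = r^2, two-tailed p from the t transform with
#' df = n - 2, 95% CI on r by Fisher z, and the regression line.
#'
#' @param density per-mouse densities (exposed mice).
#' @param usv_counts matching USV counts.
#' @param region,channel optional labels carried through.
#' @return object of class `correlation_result` with fields n, r, R2, p,
#'   slope, intercept, fisher_ci, undefined.
#' @export
correlate_region <- function(density, usv_counts,
                             region = NA_character_, channel = NA_character_) {
  ok <- is.finite(density) & is.finite(usv_counts)
  x <- usv_counts[ok]; y <- density[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 mice with both density and USV count")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(region = region, channel = channel, n = n,
                          r = NA_real_, R2 = NA_real_, p = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          fisher_ci = c(NA_real_, NA_real_), undefined = TRUE),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  r <- unname(ct$estimate)
  slope <- r * stats::sd(y) / stats::sd(x)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA_real_, NA_real_)
  structure(list(region = region, channel = channel, n = n,
                 r = r, R2 = r^2, p = unname(ct$p.value),
                 slope = slope, intercept = mean(y) - slope * mean(x),
                 fisher_ci = ci, undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s [%s]: correlation undefined (zero variance), n = %d\n",
                x$region, x$channel, x$n))
  } else {
    cat(sprintf("%s [%s]: r = %.3f, R^2 = %.3f, p = %.4g, n = %d (95%% CI %.3f..%.3f)\n",
                x$region, x$channel, x$r, x$R2, x$p, x$n,
                x$fisher_ci[1], x$fisher_ci[2]))
  }
  invisible(x)
}

#' Coefficient of determination from a Pearson coefficient
#'
#' @param r Pearson correlation coefficient(s), |r| <= 1.
#' @return r^2.
#' @export
r_to_R2 <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  r^2
}

#' Classify a region's functional category
#'
#' Decision table: a significant density-USV correlation makes the region USV
#' production-related (positive or negative by the sign of r); otherwise a
#' significant exposed-vs-control group difference makes it social
#' interaction-related; otherwise it is unrelated. The strong-correlation
#' flag requires |r| > 0.7 and R^2 > 0.5. An undefined correlation can only
#' reach the social/unrelated branches (noted in the result).
#'
#' @param group_cmp a [compare_groups()] result.
#' @param corr a [correlate_region()] result for the same region/channel.
#' @param alpha significance level (default 0.05, two-tailed, uncorrected).
#' @return object of class `region_classification`: list with region,
#'   category, strong, note, and the evidence used.
#' @export
classify_region <- function(group_cmp, corr, alpha = 0.05) {
  stopifnot(inherits(group_cmp, "group_comparison"),
            inherits(corr, "correlation_result"))
  note <- NA_character_
  if (corr$undefined) {
    note <- "correlation undefined; classified on the group comparison only"
    category <- if (group_cmp$p_value < alpha) "social-interaction-related"
                else "unrelated"
    strong <- FALSE
  } else if (corr$p < alpha) {
    category <- if (corr$r > 0) "usv-positive" else "usv-negative"
    strong <- abs(corr$r) > 0.7 && corr$R2 > 0.5
  } else {
    category <- if (group_cmp$p_value < alpha) "social-interaction-related"
                else "unrelated"
    strong <- FALSE
  }
  structure(list(region = corr$region, category = category, strong = strong,
                 note = note, group_comparison = group_cmp, correlation = corr),
            class = "region_classification")
}

#' Classify every region in a long density table
#'
#' Runs the exposed-vs-control comparison and the density-USV correlation per
#' (sub)region for one channel, then applies the classification decision
#' table.
#'
#' @param density_long output of [quantify_cohort()] (or same columns).
#' @param mice data.frame with mouse_id, group, usv_count.
#' @param channel channel to classify.
#' @param alpha significance level.
#' @return data.frame of class `region_classification_table`: subregion,
#'   category, strong, r, R2, p_corr, p_group, n, test; the per-region
#'   objects are attached as the "details" attribute.
#' @export
classify_regions <- function(density_long, mice, channel = "tdTomato",
                             alpha = 0.05) {
  d <- density_long[density_long$channel == channel, ]
  out <- list(); details <- list()
  for (sr in unique(d$subregion)) {
    sub <- d[d$subregion == sr, ]
    sub <- merge(sub, mice[, c("mouse_id", "usv_count")], by = "mouse_id")
    exposed <- sub[sub$group == "female-exposure", ]
    control <- sub[sub$group == "no-exposure", ]
    if (nrow(exposed) < 3 || nrow(control) < 3) next
    cmp <- compare_groups(exposed$density, control$density,
                          region = sr, channel = channel)
    corr <- correlate_region(exposed$density, exposed$usv_count,
                             region = sr, channel = channel)
    cls <- classify_region(cmp, corr, alpha)
    details[[sr]] <- cls
    out[[sr]] <- data.frame(subregion = sr, category = cls$category,
                            strong = cls$strong, r = corr$r, R2 = corr$R2,
                            p_corr = corr$p, p_group = cmp$p_value,
                            n = corr$n, test = cmp$test_name)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "details") <- details
  class(tab) <- c("region_classification_table", "data.frame")
  tab
}

#' @export
print.region_classification_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$r <- round(df$r, 3); df$R2 <- round(df$R2, 3)
  df$p_corr <- signif(df$p_corr, 3); df$p_group <- signif(df$p_group, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Anteroposterior correlation profile
#'
#' Bins section-level densities along the bregma axis (bins anchored at
#' multiples of the bin width; a section on a bin edge goes to the more
#' rostral bin), averages per mouse within each bin, and correlates the
#' per-mouse bin means with USV counts. The peak is the bin with the largest
#' R^2 among bins with p < 0.05; with no significant bin there is no peak.
#' Bins with fewer than 3 contributing mice are flagged insufficient.
#'
#' @param sections data.frame with mouse_id, bregma_mm, density (one region,
#'   one channel, exposed mice).
#' @param mice data.frame with mouse_id, usv_count.
#' @param bin_width_mm bin width (default 0.2).
#' @return object of class `ap_profile`: data.frame bin_lo_mm, bin_hi_mm,
#'   bin_center_mm, n, r, R2, p, insufficient; the peak bin center is the
#'   "peak_mm" attribute (NA if none).
#' @export
ap_profile <- function(sections, mice, bin_width_mm = 0.2) {
  if (!nrow(sections)) stop("no sections supplied")
  b <- sections$bregma_mm
  # bins [lo, hi) anchored at multiples of the width; a section exactly on an
  # edge joins the bin extending rostrally from it
  idx <- floor(round(b / bin_width_mm, 9))
  rows <- list()
  for (k in sort(unique(idx), decreasing = TRUE)) {
    sel <- idx == k
    per_mouse <- tapply(sections$density[sel], sections$mouse_id[sel], mean)
    u <- mice$usv_count[match(names(per_mouse), mice$mouse_id)]
    n <- length(per_mouse)
    if (n >= 3 && stats::sd(per_mouse) > 0 && stats::sd(u) > 0) {
      cr <- correlate_region(as.numeric(per_mouse), u)
      rows[[length(rows) + 1L]] <- data.frame(
        bin_lo_mm = k * bin_width_mm, bin_hi_mm = (k + 1) * bin_width_mm,
        bin_center_mm = (k + 0.5) * bin_width_mm,
        n = n, r = cr$r, R2 = cr$R2, p = cr$p, insufficient = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        bin_lo_mm = k * bin_width_mm, bin_hi_mm = (k + 1) * bin_width_mm,
        bin_center_mm = (k + 0.5) * bin_width_mm,
        n = n, r = NA_real_, R2 = NA_real_, p = NA_real_, insufficient = TRUE)
    }
  }
  prof <- do.call(rbind, rows)
  rownames(prof) <- NULL
  sig <- which(!prof$insufficient & prof$p < 0.05)
  peak <- if (length(sig)) prof$bin_center_mm[sig[which.max(prof$R2[sig])]]
          else NA_real_
  attr(prof, "peak_mm") <- peak
  class(prof) <- c("ap_profile", "data.frame")
  prof
}

#' @export
print.ap_profile <- function(x, ...) {
  df <- as.data.frame(x)
  df$r <- round(df$r, 3); df$R2 <- round(df$R2, 3); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  pk <- attr(x, "peak_mm")
  cat(if (is.na(pk)) "no significant peak\n"
      else sprintf("peak R^2 at bregma %.2f mm\n", pk))
  invisible(x)
}
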