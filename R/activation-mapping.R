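# Group-comparison statistics with normality routing, Tukey-fence outlier
# exclusion, and the two complementary z-score heatmap normalizations.

#' Route a comparison to a parametric or nonparametric test
#'
#' Shapiro-Wilk normality per group at alpha = 0.05: if every group is
#' consistent with normality the t family is used (independent or paired),
#' otherwise the rank family (Mann-Whitney U between groups, Wilcoxon
#' signed-rank within subjects; for paired data the differences are tested).
#'
#' @param samples_by_group list of numeric vectors (>= 3 values each).
#' @param paired logical.
#' @param alpha normality test level.
#' @return one of "independent-t", "paired-t", "Mann-Whitney U",
#'   "Wilcoxon signed-rank".
#' @export
route_test <- function(samples_by_group, paired = FALSE, alpha = 0.05) {
  if (any(vapply(samples_by_group, length, 0L) < 3))
    stop("each group needs >= 3 values for the normality test")
  tested <- if (paired && length(samples_by_group) == 2)
    list(samples_by_group[[1]] - samples_by_group[[2]])
  else samples_by_group
  normal <- vapply(tested, function(x) {
    if (stats::sd(x) == 0) return(TRUE)  # degenerate: no evidence against
    stats::shapiro.test(x)$p.value >= alpha
  }, TRUE)
  if (all(normal)) {
    if (paired) "paired-t" else "independent-t"
  } else {
    if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
  }
}

#' Compare exposed and control groups
#'
#' Runs the routed two-tailed test and returns the statistic, p-value, effect
#' direction, and group summaries in the family's presentation style
#' (mean +/- SEM for the t family, median +/- IQR for the rank family).
#'
#' @param exposed,control numeric vectors.
#' @param paired logical (requires equal lengths).
#' @param region,channel optional labels carried through.
#' @return object of class `group_comparison`.
#' @export
compare_groups <- function(exposed, control, paired = FALSE,
                           region = NA_character_, channel = NA_character_) {
  test <- route_test(list(exposed = exposed, control = control), paired = paired)
  degenerate <- if (paired) stats::sd(exposed - control) == 0 &&
    mean(exposed - control) == 0
  else stats::sd(exposed) == 0 && stats::sd(control) == 0 &&
    mean(exposed) == mean(control)
  if (degenerate) {
    res <- list(statistic = 0, p.value = 1)  # degenerate-by-convention
  } else {
    res <- switch(test,
      "independent-t" = stats::t.test(exposed, control, var.equal = FALSE),
      "paired-t" = stats::t.test(exposed, control, paired = TRUE),
      "Mann-Whitney U" = stats::wilcox.test(
        exposed, control,
        exact = min(length(exposed), length(control)) <= 8 &&
                !anyDuplicated(c(exposed, control)),
        correct = TRUE),
      "Wilcoxon signed-rank" = stats::wilcox.test(
        exposed, control, paired = TRUE,
        exact = length(exposed) <= 8 && !anyDuplicated(abs(exposed - control)),
        correct = TRUE))
  }
  parametric <- test %in% c("independent-t", "paired-t")
  summarize <- function(x) {
    if (parametric)
      c(center = mean(x), spread = stats::sd(x) / sqrt(length(x)))
    else c(center = stats::median(x), spread = stats::IQR(x))
  }
  structure(list(
    region = region, channel = channel, test_name = test,
    statistic = unname(res$statistic), p_value = unname(res$p.value),
    direction = sign(if (parametric) mean(exposed) - mean(control)
                     else stats::median(exposed) - stats::median(control)),
    summary_exposed = summarize(exposed),
    summary_control = summarize(control),
    summary_style = if (parametric) "mean +/- SEM" else "median +/- IQR",
    n = c(exposed = length(exposed), control = length(control)),
    paired = paired), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(s) sprintf("%.3f +/- %.3f", s["center"], s["spread"])
  cat(sprintf("%s [%s]: %s, stat = %.4g, p = %.4g\n",
              x$region, x$channel, x$test_name, x$statistic, x$p_value))
  cat(sprintf("  exposed %s, control %s (%s)\n",
              fmt(x$summary_exposed), fmt(x$summary_control), x$summary_style))
  invisible(x)
}

#' Two-way ANOVA with Tukey HSD post hoc
#'
#' F and p for both main effects and the interaction, followed by Tukey
#' honestly-significant-difference pairwise comparisons (studentized range).
#' A design with an empty cell is rejected; a fully constant response returns
#' F = 0, p = 1 for every term by convention.
#'
#' @param data data.frame.
#' @param response,factor_a,factor_b column names.
#' @return list with `anova` (term, df, F, p) and `tukey` (TukeyHSD tables),
#'   class `two_way_anova`.
#' @export
two_way_anova_tukey <- function(data, response, factor_a, factor_b) {
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factor_a]]), B = factor(data[[factor_b]]))
  counts <- table(d$A, d$B)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", rownames(counts)[bad[1]], " x ",
         colnames(counts)[bad[2]])
  }
  if (any(counts < 2)) stop("need >= 2 replicates per design cell")
  terms <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  if (stats::sd(d$y) == 0) {
    tab <- data.frame(term = terms, df = NA_real_, F = 0, p = 1)
    return(structure(list(anova = tab, tukey = NULL), class = "two_way_anova"))
  }
  fit <- stats::aov(y ~ A * B, data = d)
  s <- summary(fit)[[1]]
  tab <- data.frame(term = terms,
                    df = s[1:3, "Df"],
                    F = s[1:3, "F value"],
                    p = s[1:3, "Pr(>F)"])
  tk <- stats::TukeyHSD(fit)
  names(tk) <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  structure(list(anova = tab, tukey = tk), class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, ...) {
  print(transform(x$anova, F = signif(F, 4), p = signif(p, 4)), row.names = FALSE)
  invisible(x)
}

#' Flag statistical outliers by Tukey fences
#'
#' A value is an outlier iff it falls outside [Q1 - k IQR, Q3 + k IQR]
#' (k = 1.5). Flagged entries are excluded from the z-score populations and
#' rendered as missing in heatmaps.
#'
#' @param x numeric vector (>= 4 values).
#' @param k fence multiplier.
#' @return logical mask, TRUE = outlier.
#' @export
flag_outliers <- function(x, k = 1.5) {
  if (sum(is.finite(x)) < 4) stop("need >= 4 finite values to flag outliers")
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  out <- x < q[1] - k * iqr | x > q[2] + k * iqr
  out & !is.na(out)
}

#' Dual-mode z-score normalization of a density matrix
#'
#' z = (x - mu) / sigma with sample SD (n - 1), where the normalization
#' population is either all mice within one region (columns;
#' "across_mouse_within_region") or all regions within one mouse (rows;
#' "within_mouse_across_regions"). Tukey-fence outliers are excluded from mu
#' and sigma and masked in the output. A zero-sigma population yields z = 0
#' with a warning flag rather than an error.
#'
#' @param mat numeric matrix, mice x regions (rownames = mouse ids).
#' @param mode normalization mode.
#' @param exclude_outliers apply [flag_outliers()] per population first
#'   (populations smaller than 4 are never masked).
#' @return object of class `zscore_matrix`: list with `values`,
#'   `outlier_mask`, `sigma_zero` flags, `mode`.
#' @export
zscore_matrix <- function(mat,
                          mode = c("across_mouse_within_region",
                                   "within_mouse_across_regions"),
                          exclude_outliers = TRUE) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  margin <- if (mode == "across_mouse_within_region") 2L else 1L
  if (dim(mat)[3L - margin] < 2)
    stop("each normalization population needs >= 2 values")
  z <- mat * NA_real_
  mask <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  sig0 <- logical(dim(mat)[margin])
  for (i in seq_len(dim(mat)[margin])) {
    x <- if (margin == 2L) mat[, i] else mat[i, ]
    out <- if (exclude_outliers && sum(is.finite(x)) >= 4) flag_outliers(x)
           else rep(FALSE, length(x))
    kept <- x[!out & is.finite(x)]
    mu <- mean(kept); sg <- stats::sd(kept)
    if (is.na(sg) || sg == 0) {
      sig0[i] <- TRUE
      zi <- ifelse(is.finite(x), 0, NA_real_)
    } else zi <- (x - mu) / sg
    zi[out] <- NA_real_
    if (margin == 2L) { z[, i] <- zi; mask[, i] <- out }
    else { z[i, ] <- zi; mask[i, ] <- out }
  }
  if (any(sig0))
    warning("zero-sigma population(s): z set to 0 for ",
            sum(sig0), " population(s)")
  structure(list(values = z, outlier_mask = mask, sigma_zero = sig0,
                 mode = mode), class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("z-score matrix (", x$mode, "): ", nrow(x$values), " x ",
      ncol(x$values), ", ", sum(x$outlier_mask), " outliers masked\n", sep = "")
  invisible(x)
}

#' Heatmap of a z-score matrix
#'
#' Blue-white-red image with masked outliers in gray.
#'
#' @param x a `zscore_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.zscore_matrix <- function(x, ...) {
  v <- x$values
  lim <- max(abs(v), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), t(v)[, rev(seq_len(nrow(v)))],
                  zlim = c(-lim, lim), col = pal, xlab = "region", ylab = "mouse",
                  axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(v)), colnames(v), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(v)), rev(rownames(v)), las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Order heatmap rows by USV count
#'
#' Exposed mice are sorted by descending USV count (stable, ties broken by
#' mouse id); control mice keep their input order in their own block after
#' the exposed block.
#'
#' @param zmat a `zscore_matrix` or plain matrix with mouse-id rownames.
#' @param mice data.frame with mouse_id, group, usv_count.
#' @return the input with rows reordered.
#' @export
order_by_usv <- function(zmat, mice) {
  v <- if (inherits(zmat, "zscore_matrix")) zmat$values else as.matrix(zmat)
  ids <- rownames(v)
  if (is.null(ids)) stop("matrix needs mouse-id rownames")
  m <- mice[match(ids, mice$mouse_id), ]
  if (any(is.na(m$usv_count[m$group == "female-exposure"])))
    stop("missing USV count for an exposed mouse")
  exp_ids <- ids[m$group == "female-exposure"]
  exp_counts <- m$usv_count[m$group == "female-exposure"]
  o <- order(-exp_counts, exp_ids)
  new_order <- c(exp_ids[o], ids[m$group != "female-exposure"])
  idx <- match(new_order, ids)
  if (inherits(zmat, "zscore_matrix")) {
    zmat$values <- v[idx, , drop = FALSE]
    zmat$outlier_mask <- zmat$outlier_mask[idx, , drop = FALSE]
    zmat
  } else v[idx, , drop = FALSE]
}

#' Mice-by-regions density matrix from a long table
#'
#' @param density_long output of [quantify_cohort()].
#' @param channel channel to extract.
#' @return numeric matrix, mice x subregions.
#' @export
density_matrix <- function(density_long, channel = "tdTomato") {
  d <- density_long[density_long$channel == channel, ]
  ids <- unique(d$mouse_id); regs <- unique(d$subregion)
  m <- matrix(NA_real_, length(ids), length(regs), dimnames = list(ids, regs))
  m[cbind(match(d$mouse_id, ids), match(d$subregion, regs))] <- d$density
  m
}
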