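test_that("normality routing matches a Shapiro-Wilk oracle on fixed draws", {
  set.seed(101)
  g1 <- rnorm(10); g2 <- rnorm(10)
  # oracle: both draws are consistent with normality at alpha = 0.05
  expect_gte(min(shapiro.test(g1)$p.value, shapiro.test(g2)$p.value), 0.05)
  expect_equal(route_test(list(g1, g2)), "independent-t")
  # paired routing tests the differences; assert whichever family the
  # Shapiro-Wilk oracle on g1 - g2 prescribes for this draw
  expected_paired <- if (shapiro.test(g1 - g2)$p.value >= 0.05) "paired-t"
                     else "Wilcoxon signed-rank"
  expect_equal(route_test(list(g1, g2), paired = TRUE), expected_paired)

  set.seed(202)
  sk <- rlnorm(20, 0, 1.5)
  expect_lt(shapiro.test(sk)$p.value, 0.05)
  expect_equal(route_test(list(rnorm(20), sk)), "Mann-Whitney U")
  expect_error(route_test(list(c(1, 2), c(1, 2, 3))), ">= 3")
})

test_that("group comparisons match a closed-form t oracle", {
  set.seed(7)
  control <- rnorm(9, 10, 1)
  exposed <- control + 10
  cmp <- compare_groups(exposed, control)
  expect_equal(cmp$test_name, "independent-t")
  expect_lt(cmp$p_value, 0.001)
  # Welch t computed by hand
  se <- sqrt(var(exposed) / 9 + var(control) / 9)
  t_hand <- (mean(exposed) - mean(control)) / se
  expect_equal(abs(cmp$statistic), abs(t_hand), tolerance = 1e-12)
  # identical groups: maximal p, zero effect
  same <- rnorm(8)
  cmp2 <- compare_groups(same, same, paired = TRUE)
  expect_equal(cmp2$p_value, 1)
  # degenerate zero-variance convention
  cmp3 <- compare_groups(rep(2, 5), rep(2, 6))
  expect_equal(cmp3$p_value, 1)
  expect_equal(cmp3$statistic, 0)
})

test_that("an exposure effect of 1.6x is detected in most synthetic cohorts", {
  hits <- vapply(1:40, function(s) {
    reg <- region_spec("R", c(1.5, 2.2), 15, exposure_multiplier = 1.6)
    coh <- generate_cohort(cohort_config(list(reg), master_seed = s + 400))
    dl <- quantify_cohort(coh)
    d <- dl[dl$channel == "tdTomato", ]
    cmp <- compare_groups(d$density[d$group == "female-exposure"],
                          d$density[d$group == "no-exposure"])
    cmp$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("two-way ANOVA matches a hand sums-of-squares oracle", {
  set.seed(33)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:4)
  d$y <- rnorm(nrow(d)) + 2 * (d$A == "a2") + 1.5 * (d$B == "b2")
  fit <- two_way_anova_tukey(d, "y", "A", "B")
  Fh <- oracle_anova_F(d$y, d$A, d$B)
  expect_equal(fit$anova$F, unname(Fh), tolerance = 1e-10)
  expect_true(all(c("A", "B", "A:B") %in% fit$anova$term))
  expect_s3_class(fit$tukey, "TukeyHSD")
  expect_true(is.matrix(fit$tukey$A))
  # constant response convention
  d0 <- transform(d, y = 5)
  fit0 <- two_way_anova_tukey(d0, "y", "A", "B")
  expect_true(all(fit0$anova$F == 0) && all(fit0$anova$p == 1))
  # empty cell is named
  expect_error(two_way_anova_tukey(d[d$A != "a1" | d$B != "b2", ], "y", "A", "B"),
               "a1 x b2")
})

test_that("additive two-factor effects are detected, interaction stays null", {
  res <- vapply(1:30, function(s) {
    set.seed(s + 600)
    d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:8)
    d$y <- rnorm(nrow(d)) + 2 * (d$A == "a2") + 2 * (d$B == "b2")
    fit <- two_way_anova_tukey(d, "y", "A", "B")
    p <- fit$anova$p
    c(main = p[1] < 0.01 && p[2] < 0.01, inter = p[3] >= 0.05)
  }, c(main = TRUE, inter = TRUE))
  expect_gte(mean(res["main", ]), 0.9)
  expect_gte(mean(res["inter", ]), 0.9)
})

test_that("outlier flags equal brute-force Tukey fences", {
  expect_equal(which(flag_outliers(c(1, 2, 3, 100))), 4L)
  expect_equal(sum(flag_outliers(rep(5, 6))), 0)
  set.seed(55)
  for (i in 1:25) {
    x <- rt(sample(8:30, 1), df = 2) * 10
    expect_identical(flag_outliers(x), oracle_fence_mask(x))
  }
  expect_error(flag_outliers(c(1, 2, 3)), ">= 4")
})

test_that("z-scores are definitionally normalized in both modes", {
  m <- rbind(m1 = c(2, 10), m2 = c(4, 20), m3 = c(6, 30))
  colnames(m) <- c("r1", "r2")
  z <- zscore_matrix(m, "across_mouse_within_region")
  expect_equal(unname(z$values[, "r1"]), c(-1, 0, 1))
  # retained entries of every population have mean 0, sd 1 to 1e-9
  set.seed(66)
  big <- matrix(rlnorm(9 * 6, 3, 0.6), 9, 6,
                dimnames = list(paste0("m", 1:9), paste0("r", 1:6)))
  for (mode in c("across_mouse_within_region", "within_mouse_across_regions")) {
    z2 <- zscore_matrix(big, mode)
    margin <- if (mode == "across_mouse_within_region") 2 else 1
    apply(z2$values, margin, function(col) {
      kept <- col[!is.na(col)]
      expect_lt(abs(mean(kept)), 1e-9)
      expect_lt(abs(sd(kept) - 1), 1e-9)
    })
  }
  # constant population: z = 0 with a warning flag
  cm <- cbind(r1 = c(3, 3, 3), r2 = c(1, 2, 4))
  rownames(cm) <- paste0("m", 1:3)
  expect_warning(zc <- zscore_matrix(cm, "across_mouse_within_region"), "zero-sigma")
  expect_true(all(zc$values[, "r1"] == 0))
  expect_true(zc$sigma_zero[1])
})

test_that("z-scores are invariant under positive affine transforms", {
  set.seed(77)
  m <- matrix(rnorm(8 * 5, 20, 4), 8, 5,
              dimnames = list(paste0("m", 1:8), paste0("r", 1:5)))
  z0 <- zscore_matrix(m, "across_mouse_within_region")$values
  z_shift <- zscore_matrix(m + 7, "across_mouse_within_region")$values
  z_scale <- zscore_matrix(m * 3.2, "across_mouse_within_region")$values
  expect_equal(z0, z_shift, tolerance = 1e-12)
  expect_equal(z0, z_scale, tolerance = 1e-12)
})

test_that("outlier exclusion is idempotent on fence-stable inputs", {
  set.seed(88)
  ok <- 0L; total <- 0L
  for (i in 1:20) {
    x <- c(rnorm(12), 25)
    mask <- flag_outliers(x)
    kept <- x[!mask]
    if (sum(is.finite(kept)) >= 4) {
      total <- total + 1L
      if (!any(flag_outliers(kept))) ok <- ok + 1L
    }
  }
  # fence-stable in the large majority of draws (re-flagging can cascade on
  # heavy-tailed data; that is logged, not forbidden)
  expect_gte(ok / total, 0.7)
})

test_that("rank-based routes are invariant under monotone transforms", {
  set.seed(99)
  a <- rlnorm(12, 0, 2); b <- rlnorm(12, 0.8, 2)
  expect_lt(shapiro.test(a)$p.value, 0.05)  # oracle: this draw is non-normal
  p1 <- suppressWarnings(wilcox.test(a, b)$p.value)
  p2 <- suppressWarnings(wilcox.test(log(a), log(b))$p.value)
  expect_equal(p1, p2)
  cmp1 <- compare_groups(a, b)
  expect_equal(cmp1$test_name, "Mann-Whitney U")
  # squaring is strictly monotone on positive data and preserves non-normality
  expect_lt(shapiro.test(a^2)$p.value, 0.05)
  cmp_sq <- compare_groups(a^2, b^2)
  expect_equal(cmp_sq$test_name, "Mann-Whitney U")
  expect_equal(cmp1$p_value, cmp_sq$p_value)
})

test_that("USV ordering sorts exposed rows and preserves control order", {
  m <- matrix(1:12, 4, 3, dimnames = list(c("FE01", "FE02", "FE03", "NE01"),
                                          c("r1", "r2", "r3")))
  mice <- data.frame(mouse_id = c("FE01", "FE02", "FE03", "NE01"),
                     group = c(rep("female-exposure", 3), "no-exposure"),
                     usv_count = c(5, 50, 20, 0))
  out <- order_by_usv(m, mice)
  expect_equal(rownames(out), c("FE02", "FE03", "FE01", "NE01"))
  # ties keep a stable, id-based order
  mice$usv_count <- c(5, 5, 5, 0)
  expect_equal(rownames(order_by_usv(m, mice))[1:3], c("FE01", "FE02", "FE03"))
  mice$usv_count[2] <- NA
  expect_error(order_by_usv(m, mice), "missing USV count")
})

test_that("strongly coupled regions show the USV-ordered z gradient", {
  hits <- vapply(1:25, function(s) {
    coh <- small_cohort(s + 700, fixture_regions()["pos"])
    dl <- quantify_cohort(coh)
    m <- density_matrix(dl)
    z <- zscore_matrix(m, "across_mouse_within_region")
    zo <- order_by_usv(z, coh$mice)
    expv <- zo$values[rownames(zo$values) %in%
                        coh$mice$mouse_id[coh$mice$group == "female-exposure"], 1]
    isTRUE(suppressWarnings(
      cor(seq_along(expv), expv, method = "spearman",
          use = "complete.obs")) < -0.6)
  }, TRUE)
  # rows are ordered by descending USV count, so z falls along the rows
  expect_gte(mean(hits), 0.8)
})
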