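test_that("cell assignment agrees with a ray-casting oracle", {
  set.seed(6)
  # an awkward non-convex polygon
  poly <- rbind(c(0, 0), c(400, 100), c(800, 0), c(800, 800), c(400, 300),
                c(0, 800))
  cells <- data.frame(x_um = runif(200, -50, 850), y_um = runif(200, -50, 850))
  kept <- assign_cells(cells, poly)
  oracle <- oracle_in_polygon(cells$x_um, cells$y_um, poly)
  expect_setequal(rownames(kept), rownames(cells)[oracle])

  # boundary conventions: vertex and edge points are inside
  expect_equal(nrow(assign_cells(data.frame(x_um = 0, y_um = 0), poly)), 1)
  expect_equal(nrow(assign_cells(data.frame(x_um = 800, y_um = 400), poly)), 1)
  # all cells outside -> empty
  far <- data.frame(x_um = c(2000, 3000), y_um = c(2000, 3000))
  expect_equal(nrow(assign_cells(far, poly)), 0)
})

test_that("density is count over area with scale equivariance", {
  roi <- roi_annotation("CPu", "left", 0.8,
                        rbind(c(0, 0), c(1500, 0), c(1500, 1000), c(0, 1000)))
  expect_equal(roi$area_mm2, 1.5)
  expect_equal(cell_density(30, roi), 20)
  expect_equal(cell_density(0, roi), 0)
  expect_error(cell_density(5, 0), "area")
  # doubling the cells doubles the density exactly
  set.seed(3)
  cells <- data.frame(x_um = runif(40, 0, 1500), y_um = runif(40, 0, 1000))
  d1 <- cell_density(assign_cells(cells, roi), roi)
  d2 <- cell_density(assign_cells(rbind(cells, cells), roi), roi)
  expect_identical(d2, 2 * d1)
})

test_that("double-label matching is exact, symmetric, and oracle-tight", {
  td <- data.frame(x_um = c(0, 100, 200), y_um = c(0, 0, 0))
  expect_equal(nrow(match_double_labeled(td, td)), 3)
  expect_true(all(match_double_labeled(td, td)$dist_um == 0))
  far <- data.frame(x_um = c(50, 150, 250), y_um = c(50, 50, 50))
  expect_equal(nrow(match_double_labeled(td, far, tol_um = 8)), 0)

  set.seed(10)
  for (i in 1:150) {
    n1 <- sample(0:8, 1); n2 <- sample(0:8, 1)
    a <- data.frame(x_um = runif(n1, 0, 120), y_um = runif(n1, 0, 120))
    b <- data.frame(x_um = runif(n2, 0, 120), y_um = runif(n2, 0, 120))
    # seed some genuine co-labeled pairs
    k <- min(n1, n2, sample(0:3, 1))
    if (k > 0) b[seq_len(k), ] <- a[seq_len(k), ] + rnorm(2 * k, 0, 1.5)
    m_ab <- match_double_labeled(a, b)
    m_ba <- match_double_labeled(b, a)
    expect_equal(nrow(m_ab), nrow(m_ba))
    expect_setequal(paste(m_ab$td_idx, m_ab$fos_idx),
                    paste(m_ba$fos_idx, m_ba$td_idx))
    if (n1 && n2) {
      d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
      expect_equal(nrow(m_ab), oracle_max_matching(d, 8))
    }
  }
})

test_that("double-label percentages handle zero denominators by flagging", {
  p <- double_label_percentages(5, 20, 10)
  expect_equal(p$pct_double_of_cfos, 25)
  expect_equal(p$pct_double_of_tdtomato, 50)
  expect_false(p$flagged)
  expect_equal(double_label_percentages(0, 20, 10)$pct_double_of_cfos, 0)
  z <- double_label_percentages(0, 0, 10)
  expect_true(is.na(z$pct_double_of_cfos) && z$flagged)
  expect_error(double_label_percentages(5, 3, 10), "exceed")
})

test_that("reactivation probability is recovered from cohort fixtures", {
  pc <- vapply(1:25, function(s) {
    reg <- region_spec("R", c(1.5, 2.2), 25, reactivation_prob = 0.4)
    coh <- generate_cohort(cohort_config(list(reg), master_seed = s + 100))
    dl <- quantify_cohort(coh)
    mean(dl$pct_double_of_tdtomato[dl$channel == "tdTomato"])
  }, 0)
  expect_lt(abs(mean(pc) - 40), 5)
})

test_that("bregma splitting follows the rostral-inclusive boundary rules", {
  rec <- data.frame(
    region = c("CPu", "CPu", "CPu", "CPu", "PAG", "PAG", "Other"),
    bregma_mm = c(0.80, 0.62, 0.00, -1.50, -4.5, -4.2, 1.0))
  out <- split_by_bregma(rec)
  expect_equal(out$subregion,
               c("rCPu", "rCPu", "cCPu", "tCPu", "cPAG", "rPAG", "Other"))
  # sections outside a declared span are flagged
  rules <- list(CPu = list(breaks = 0.62, labels = c("rCPu", "cCPu"),
                           span = c(-2, 1.7)))
  out2 <- split_by_bregma(data.frame(region = "CPu", bregma_mm = 3), rules)
  expect_true(is.na(out2$subregion))
})

test_that("per-mouse aggregation is the unweighted section mean", {
  rec <- data.frame(mouse_id = "m1", region = "X", subregion = "X",
                    channel = "tdTomato", section_id = c("s1", "s2", "s3"),
                    density = c(10, 20, 30))
  agg <- aggregate_mouse(rec)
  expect_equal(agg$density, 20)
  expect_equal(agg$n_sections, 3)
  one <- aggregate_mouse(rec[1, ])
  expect_equal(one$density, 10)
  # matches an independent mean on a random fixture
  set.seed(8)
  rec2 <- data.frame(mouse_id = rep(c("m1", "m2"), each = 5), region = "X",
                     subregion = "X", channel = "tdTomato",
                     section_id = paste0("s", 1:5), density = runif(10, 0, 50))
  agg2 <- aggregate_mouse(rec2)
  expect_equal(agg2$density[agg2$mouse_id == "m2"],
               mean(rec2$density[rec2$mouse_id == "m2"]))
})

test_that("pooled hemisphere counts equal the per-hemisphere sum", {
  coh <- small_cohort(19, fixture_regions()["pos"])
  cells <- coh$cells[coh$cells$channel == "tdTomato", ]
  by_hemi <- table(cells$mouse_id, cells$hemisphere)
  pooled <- table(cells$mouse_id)
  expect_equal(as.numeric(pooled), as.numeric(by_hemi[, "left"] + by_hemi[, "right"]))
})

test_that("the simple blob detector recovers planted blobs", {
  # 200 x 200 px at 2 um/px; five well-separated Gaussian blobs
  px <- 200; um_per_px <- 2
  centers <- rbind(c(40, 40), c(150, 40), c(40, 150), c(150, 150), c(100, 100))
  img <- matrix(0, px, px)
  xs <- matrix(rep(1:px, each = px), px)  # column index = x
  ys <- matrix(rep(1:px, times = px), px) # row index = y
  for (i in seq_len(nrow(centers)))
    img <- img + 60 * exp(-((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2) / (2 * 3^2))
  det <- detect_cells_simple(img, um_per_px, intensity_threshold = 20)
  expect_equal(nrow(det), 5)
  found <- det[order(det$y_um, det$x_um), ]
  truth <- centers[order(centers[, 2], centers[, 1]), ]
  expect_true(all(abs(found$x_um - (truth[, 1] - 0.5) * um_per_px) <= um_per_px))
  expect_true(all(abs(found$y_um - (truth[, 2] - 0.5) * um_per_px) <= um_per_px))
  # a blob below the channel threshold is excluded
  dim_img <- 8 * exp(-((xs - 100)^2 + (ys - 100)^2) / (2 * 3^2))
  expect_equal(nrow(detect_cells_simple(dim_img, um_per_px,
                                        intensity_threshold = 10)), 0)
  # blank image and missing scale
  expect_equal(nrow(detect_cells_simple(matrix(0, 50, 50), um_per_px)), 0)
  expect_error(detect_cells_simple(img, NULL), "scale")
})
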