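# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Ray-casting point-in-polygon (boundary handled separately by segment tests).
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  on_boundary <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
      cross <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
      if (abs(cross) < 1e-9 &&
          x >= min(ax, bx) - 1e-9 && x <= max(ax, bx) + 1e-9 &&
          y >= min(ay, by) - 1e-9 && y <= max(ay, by) + 1e-9) return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_boundary(x, y)) return(TRUE)
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ay <- poly[i, 2]; by <- poly[j, 2]
      if ((ay > y) != (by > y)) {
        xint <- poly[i, 1] + (y - ay) / (by - ay) * (poly[j, 1] - poly[i, 1])
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, TRUE)
}

# Maximum-cardinality matching under a distance cap by exhaustive recursion
# (feasible for <= 8 cells per channel).
oracle_max_matching <- function(d, tol) {
  n1 <- nrow(d); n2 <- ncol(d)
  if (!n1 || !n2) return(0L)
  rec <- function(i, used) {
    if (i > n1) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(n2)) {
      if (!used[j] && d[i, j] <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, n2))
}

# Tukey fences from first principles (sorted-order quartiles, type 7).
oracle_fence_mask <- function(x, k = 1.5) {
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

# Two-tailed Pearson p-value via the t transform, written out explicitly.
oracle_cor_p <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

# Permutation p-value for a Pearson correlation (two-tailed, shuffle y).
oracle_perm_p <- function(x, y, n_perm = 10000) {
  r_obs <- abs(stats::cor(x, y))
  hits <- 0L
  for (b in seq_len(n_perm))
    if (abs(stats::cor(x, sample(y))) >= r_obs - 1e-12) hits <- hits + 1L
  (hits + 1) / (n_perm + 1)
}

# Balanced two-way ANOVA sums of squares by hand.
oracle_anova_F <- function(y, A, B) {
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  nA <- table(A)[1]; nB <- table(B)[1]
  n_cell <- table(A, B)[1, 1]
  ss_A <- sum(table(A) * (mA - gm)^2)
  ss_B <- sum(table(B) * (mB - gm)^2)
  cellmeans <- tapply(y, list(A, B), mean)
  ss_cells <- n_cell * sum((cellmeans - gm)^2)
  ss_AB <- ss_cells - ss_A - ss_B
  ss_err <- sum((y - ave(y, A, B))^2)
  df_A <- nlevels(factor(A)) - 1; df_B <- nlevels(factor(B)) - 1
  df_AB <- df_A * df_B
  df_err <- length(y) - nlevels(factor(A)) * nlevels(factor(B))
  c(A = (ss_A / df_A) / (ss_err / df_err),
    B = (ss_B / df_B) / (ss_err / df_err),
    AB = (ss_AB / df_AB) / (ss_err / df_err))
}

# Rigid motion (rotation + translation) applied to an n x 2 matrix.
rigid_motion <- function(xy, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(xy %*% t(R), 2, shift, "+")
}
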