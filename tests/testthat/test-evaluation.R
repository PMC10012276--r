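vol_of <- function(values, dm = NULL) {
  if (is.null(dm)) dm <- dim(values)
  volume_grid(array(values, dim = dm), c(1, 1, 1))
}

test_that("mean error and MAE reproduce closed forms and the loop oracle", {
  dm <- c(5L, 5L, 2L)
  set.seed(31)
  gt <- vol_of(runif(prod(dm), 0, 70), dm)
  mask <- array(runif(prod(dm)) < 0.6, dm)
  rx <- 69.96

  expect_equal(mean_error(gt, gt, mask, rx), 0)
  expect_equal(mean_absolute_error(gt, gt, mask, rx), 0)

  shifted <- vol_of(gt$values + 0.05 * rx)
  expect_equal(mean_error(shifted, gt, mask, rx), 5)
  expect_equal(mean_absolute_error(shifted, gt, mask, rx), 5)

  # alternating +/- offsets cancel in ME but not MAE
  sgn <- array(rep_len(c(1, -1), prod(dm)), dm)
  alt <- vol_of(gt$values + sgn * 0.05 * rx)
  full <- array(TRUE, dm)
  expect_equal(mean_absolute_error(alt, gt, full, rx), 5)
  expect_equal(mean_error(alt, gt, full, rx), 0)

  # explicit double-loop oracle on random volumes
  pred <- vol_of(runif(prod(dm), 0, 70), dm)
  acc <- 0; acc_abs <- 0; m <- 0
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (!mask[i, j, k]) next
    diffv <- pred$values[i, j, k] - gt$values[i, j, k]
    acc <- acc + diffv; acc_abs <- acc_abs + abs(diffv); m <- m + 1
  }
  expect_equal(mean_error(pred, gt, mask, rx), acc / m / rx * 100)
  expect_equal(mean_absolute_error(pred, gt, mask, rx), acc_abs / m / rx * 100)

  expect_error(mean_error(pred, gt, array(FALSE, dm), rx), "empty")
  expect_error(mean_absolute_error(pred, gt, mask, 0), "positive")
})

test_that("MAE dominates |ME| across random volume pairs", {
  set.seed(77)
  dm <- c(4L, 4L, 3L)
  for (i in 1:100) {
    a <- vol_of(runif(prod(dm), 0, 70), dm)
    b <- vol_of(runif(prod(dm), 0, 70), dm)
    mask <- array(runif(prod(dm)) < 0.7, dm)
    if (!any(mask)) next
    expect_gte(mean_absolute_error(a, b, mask, 60.06),
               abs(mean_error(a, b, mask, 60.06)))
  }
})

test_that("isodose DSC counts voxels like the definition", {
  dm <- c(6L, 6L, 3L)
  set.seed(8)
  gt <- vol_of(runif(prod(dm), 0, 70), dm)
  expect_equal(as.numeric(isodose_dsc(gt, gt, 30)), 1.0)

  a <- vol_of(0, dm); b <- vol_of(0, dm)
  a$values[1:2, 1, 1] <- 50
  b$values[5:6, 6, 3] <- 50
  expect_equal(as.numeric(isodose_dsc(a, b, 30)), 0)

  # 8-voxel cube vs the same cube shifted to overlap 4 voxels
  a <- vol_of(0, dm); b <- vol_of(0, dm)
  a$values[1:2, 1:2, 1:2] <- 60
  b$values[1:2, 2:3, 1:2] <- 60
  expect_equal(as.numeric(isodose_dsc(a, b, 50)), 2 * 4 / (8 + 8))

  zero <- vol_of(0, dm)
  d0 <- isodose_dsc(zero, zero, 10)
  expect_equal(as.numeric(d0), 1.0)
  expect_true(isTRUE(attr(d0, "degenerate")))

  # symmetry over random pairs and levels
  for (i in 1:20) {
    x <- vol_of(runif(prod(dm), 0, 70), dm)
    y <- vol_of(runif(prod(dm), 0, 70), dm)
    l <- runif(1, 1, 60)
    expect_equal(isodose_dsc(x, y, l), isodose_dsc(y, x, l))
  }
})

test_that("the DSC curve spans 1-60 Gy with a 5-Gy statistics grid", {
  dm <- c(6L, 6L, 3L)
  set.seed(9)
  gt <- vol_of(runif(prod(dm), 0, 70), dm)
  curve <- dsc_curve(gt, gt)
  expect_equal(nrow(curve), 60L)
  expect_true(all(curve$dsc == 1))
  expect_equal(attr(curve, "stat_levels"), seq(5, 55, by = 5))

  pred <- vol_of(0.9 * gt$values)
  curve2 <- dsc_curve(pred, gt)
  for (r in seq_len(nrow(curve2))) {
    l <- curve2$level[r]
    A <- pred$values >= l; B <- gt$values >= l
    expected <- if (sum(A) + sum(B) == 0) 1 else 2 * sum(A & B) / (sum(A) + sum(B))
    expect_equal(curve2$dsc[r], expected)
  }
})

test_that("DVH curves are valid cumulative distributions", {
  dm <- c(5L, 5L, 4L)
  mask <- array(TRUE, dm)
  u <- dvh(vol_of(42, dm), mask, bin_width = 0.5)
  expect_equal(u$volume_pct[1], 100)
  expect_true(all(u$volume_pct[u$dose <= 42] == 100))
  expect_true(all(u$volume_pct[u$dose > 42] == 0))
  expect_true(all(diff(u$volume_pct) <= 0))

  two <- vol_of(0, c(2L, 1L, 1L)); two$values[] <- c(10, 20)
  d2 <- dvh(two, array(TRUE, c(2, 1, 1)), bin_width = 0.1)
  expect_equal(d2$volume_pct[which.min(abs(d2$dose - 15))], 50)

  # linear ramp: volume fraction above d falls linearly
  n <- 100L
  ramp <- vol_of(seq(0, 70, length.out = n), c(n, 1L, 1L))
  dr <- dvh(ramp, array(TRUE, c(n, 1, 1)), bin_width = 0.1)
  sel <- dr$dose > 1 & dr$dose < 69
  expect_equal(dr$volume_pct[sel], 100 * (1 - dr$dose[sel] / 70),
               tolerance = 2 / n * 100)
  expect_error(dvh(ramp, array(FALSE, c(n, 1, 1))), "empty")
})

test_that("Dx% matches order statistics and is monotone in x", {
  dm <- c(5L, 5L, 4L)
  u <- dvh(vol_of(42, dm), array(TRUE, dm))
  for (x in c(2, 5, 50, 95)) expect_equal(dose_at_volume(u, x), 42)

  set.seed(10)
  vals <- runif(100, 0, 70)
  roi <- vol_of(vals, c(100L, 1L, 1L))
  curve <- dvh(roi, array(TRUE, c(100, 1, 1)), bin_width = 0.01)
  for (x in c(5, 20, 50, 80)) {
    # sort-based oracle: the smallest dose within the hottest x% of voxels
    oracle <- sort(vals, decreasing = TRUE)[ceiling(x / 100 * length(vals))]
    expect_equal(dose_at_volume(curve, x), oracle, tolerance = 0.02)
  }
  xs <- c(1, 5, 25, 50, 75, 95)
  ds <- vapply(xs, function(x) dose_at_volume(curve, x), numeric(1))
  expect_true(all(diff(ds) <= 0))
  expect_error(dose_at_volume(curve, 0), "in \\(0, 100\\)")
  expect_error(dose_at_volume(data.frame(a = 1), 5), "malformed")
})

test_that("mean dose agrees with the loop oracle and the DVH integral", {
  dm <- c(5L, 4L, 3L)
  expect_equal(mean_dose(vol_of(42, dm), array(TRUE, dm)), 42)
  two <- vol_of(0, c(2L, 1L, 1L)); two$values[] <- c(0, 10)
  expect_equal(mean_dose(two, array(TRUE, c(2, 1, 1))), 5)

  set.seed(13)
  dose <- vol_of(runif(prod(dm), 0, 70), dm)
  mask <- array(runif(prod(dm)) < 0.5, dm)
  acc <- 0; m <- 0
  for (i in seq_len(prod(dm))) if (mask[i]) { acc <- acc + dose$values[i]; m <- m + 1 }
  expect_equal(mean_dose(dose, mask), acc / m)

  # conservation: mean dose equals the integral of the cumulative DVH
  bw <- 0.1
  curve <- dvh(dose, mask, bin_width = bw)
  integral <- sum((head(curve$volume_pct, -1) + tail(curve$volume_pct, -1)) /
                    2 / 100 * bw)
  expect_equal(mean_dose(dose, mask), integral, tolerance = bw)
})

test_that("metrics are scale-covariant in dose", {
  dm <- c(5L, 5L, 3L)
  set.seed(14)
  pred <- vol_of(runif(prod(dm), 0, 70), dm)
  gt <- vol_of(runif(prod(dm), 0, 70), dm)
  mask <- array(TRUE, dm)
  cscale <- 1.7
  ps <- vol_of(cscale * pred$values); gs <- vol_of(cscale * gt$values)
  expect_equal(mean_dose(ps, mask), cscale * mean_dose(pred, mask))
  expect_equal(dose_at_volume(dvh(ps, mask, 0.01), 5),
               cscale * dose_at_volume(dvh(pred, mask, 0.01), 5),
               tolerance = 0.05)
  for (l in c(10, 30, 50))
    expect_equal(isodose_dsc(ps, gs, cscale * l), isodose_dsc(pred, gt, l))
})

test_that("paired comparison flags degenerate inputs and matches the t formula", {
  a <- c(1, 2, 3, 4)
  r <- paired_comparison(a, a)
  expect_true(r$degenerate)
  expect_equal(r$mean_diff, 0)
  expect_true(is.na(r$p_value))

  set.seed(15)
  b <- rnorm(30, 5, 0.5)
  shifted <- b + 1 + rnorm(30, 0, 0.01)
  expect_lt(paired_comparison(shifted, b)$p_value, 0.05)

  # four hand-made pairs against the textbook statistic
  x <- c(5.1, 4.8, 6.0, 5.5)
  y <- c(4.9, 4.9, 5.2, 5.1)
  d <- x - y
  tstat <- mean(d) / (sd(d) / sqrt(4))
  pval <- 2 * stats::pt(-abs(tstat), df = 3)
  r2 <- paired_comparison(x, y)
  expect_equal(r2$mean_diff, mean(d))
  expect_equal(r2$p_value, pval)
  expect_error(paired_comparison(1:3, 1:4), "length")
  expect_error(paired_comparison(1, 2), "at least 2")
})
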