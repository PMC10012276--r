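test_that("DPTV is zero on PTV and outside the body, positive elsewhere in body", {
  case <- noiseless_case()
  rois <- case$rois$masks
  d <- case$dptv$values
  expect_true(all(d[rois$ptv] == 0))
  expect_true(all(d[!rois$body] == 0))
  expect_true(all(d[rois$body & !rois$ptv] > 0))
  expect_true(all(is.finite(d)))
})

test_that("single-voxel neighbours read the physical spacing", {
  dm <- c(5L, 5L, 5L)
  body <- array(TRUE, dm)
  ptv <- array(FALSE, dm)
  ptv[3, 3, 3] <- TRUE
  d <- compute_dptv(ptv, body, c(1, 1, 3))$values
  expect_equal(d[4, 3, 3], 1.0)   # lateral face neighbour
  expect_equal(d[3, 4, 3], 1.0)
  expect_equal(d[3, 3, 4], 3.0)   # axial neighbour, 3 mm slice step
  expect_equal(d[4, 4, 3], sqrt(2))
  expect_equal(d[4, 3, 4], sqrt(1 + 9))
})

test_that("distance transform matches the brute-force oracle on random grids", {
  set.seed(99)
  for (rep in 1:6) {
    dm <- c(sample(5:8, 1), sample(5:8, 1), sample(3:4, 1))
    sp <- runif(3, 0.4, 3.6)
    body <- array(runif(prod(dm)) < 0.85, dim = dm)
    ptv <- array(runif(prod(dm)) < 0.2, dim = dm) & body
    if (!any(ptv)) next
    got <- compute_dptv(ptv, body, sp)$values
    expect_lt(max(abs(got - bf_dptv(ptv, body, sp))), 1e-9)
  }
})

test_that("DPTV is 1-Lipschitz in physical distance and scales with spacing", {
  case <- noiseless_case()
  sp <- case$rois$spacing
  d <- case$dptv$values
  body <- case$rois$masks$body
  set.seed(12)
  iv <- which(body)
  pick <- matrix(sample(iv, 400, replace = TRUE), ncol = 2)
  ai <- arrayInd(pick[, 1], dim(d))
  bi <- arrayInd(pick[, 2], dim(d))
  sep <- sqrt(rowSums(((ai - bi) %*% diag(sp))^2))
  expect_true(all(abs(d[pick[, 1]] - d[pick[, 2]]) <= sep + 1e-9))

  # pure rescaling of the grid rescales every distance exactly
  dm <- c(7L, 6L, 4L)
  set.seed(5)
  body2 <- array(TRUE, dm)
  ptv2 <- array(runif(prod(dm)) < 0.2, dim = dm)
  ptv2[1, 1, 1] <- TRUE
  d1 <- compute_dptv(ptv2, body2, c(1, 2, 3))$values
  d2 <- compute_dptv(ptv2, body2, 2.5 * c(1, 2, 3))$values
  expect_equal(d2, 2.5 * d1, tolerance = 1e-12)
})

test_that("degenerate distance inputs are rejected", {
  dm <- c(4L, 4L, 4L)
  body <- array(TRUE, dm)
  none <- array(FALSE, dm)
  expect_error(compute_dptv(none, body, c(1, 1, 1)), "empty")
  expect_error(compute_dptv(array(TRUE, c(3, 4, 4)), body, c(1, 1, 1)),
               "different grid shapes")
  ptv <- none; ptv[1, 1, 1] <- TRUE
  expect_error(compute_dptv(ptv, none, c(1, 1, 1)), "inside the body")
  expect_error(compute_dptv(ptv, body, c(1, -1, 1)), "positive")
})

test_that("structure map matches the hand-painted toy expectation", {
  rois <- toy_rois()
  smap <- encode_structures(rois)
  lt <- smap$label_table
  expect_equal(unname(lt[c("outside", "body", "out_of_field", "cord", "ptv")]),
               c(0L, 1L, 2L, 3L, 100L))

  expected <- array(NA_integer_, dim = c(6, 6, 2))
  expected[, , 1] <- 1L          # in-field body
  expected[, , 2] <- 2L          # out-of-field body
  expected[1, , ] <- 0L          # outside body
  for (s in 1:2) {
    expected[2:3, 2:3, s] <- 3L                  # cord
    expected[3:5, 3:5, s] <- 100L                # target
    expected[3, 3, s] <- 103L                    # cord + target overlap sum
  }
  expect_identical(smap$labels, expected)
})

test_that("overlap sums are collision-free and ROIs recoverable", {
  case <- noiseless_case()
  smap <- encode_structures(case$rois)
  lt <- smap$label_table
  expect_gt(sum(smap$labels == lt[["larynx"]] + lt[["ptv"]]), 0)

  # every non-overlapping OAR is exactly the set of voxels with its code
  masks <- case$rois$masks
  oars <- names(case$rois$roles)[case$rois$roles == "oar"]
  targets <- names(case$rois$roles)[case$rois$roles == "target"]
  for (nm in oars) {
    others <- setdiff(c(oars, targets), nm)
    overlapped <- Reduce(`|`, masks[others])
    if (any(masks[[nm]] & overlapped)) next
    expect_identical(smap$labels == lt[[nm]], masks[[nm]], info = nm)
  }
  # the full code set is the table plus OAR+target sums
  valid <- c(lt, as.vector(outer(lt[oars], lt[targets], `+`)))
  expect_true(all(smap$labels %in% valid))
})

test_that("colliding custom label tables are rejected", {
  rois <- toy_rois()
  # cord (3) + ptv (100) = 103 collides with a second OAR coded 103
  bad <- rois
  bad$masks$second <- bad$masks$cord & FALSE
  bad$masks$second[6, 6, ] <- TRUE
  bad$roles <- c(bad$roles, second = "oar")
  tab <- c(outside = 0L, body = 1L, out_of_field = 2L, cord = 3L,
           second = 103L, ptv = 100L)
  attr(tab, "max_code") <- 203L
  expect_error(encode_structures(bad, tab), "collision")
  # missing body mask is also fatal
  nobody <- list(masks = rois$masks["ptv"], roles = c(ptv = "target"),
                 spacing = rois$spacing)
  expect_error(roi_set(nobody$masks, nobody$roles, nobody$spacing),
               "body mask")
})

test_that("input stacks carry the right channels and normalization", {
  case <- noiseless_case()
  anat <- assemble_inputs(case, "ANAT")
  com <- assemble_inputs(case, "COM")
  expect_equal(dim(anat$x)[3], 2L)
  expect_equal(dim(com$x)[3], 3L)
  expect_equal(dim(com$x)[c(1, 2, 4)], dim(case$ct$values))
  expect_true(all(com$x >= 0 & com$x <= 1))
  # CT at the window midpoint maps to 0.5
  flat <- case
  flat$ct <- volume_grid(array(0, dim = dim(case$ct$values)),
                         case$rois$spacing)
  expect_true(all(assemble_inputs(flat, "ANAT")$x[, , 1, ] == 0.5))
  # structure channel is labels over the max table code
  smap <- encode_structures(case$rois)
  expect_equal(com$x[, , 2, ],
               array(smap$labels / attr(smap$label_table, "max_code"),
                     dim = dim(smap$labels)),
               tolerance = 1e-12)
  # DPTV channel is capped at 1
  capped <- assemble_inputs(case, "COM", dptv_cap_mm = 10)
  expect_equal(max(capped$x[, , 3, ]), 1)
  expect_error(assemble_inputs(case, "BOGUS"), "arg")
})
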