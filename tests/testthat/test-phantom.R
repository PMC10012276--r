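test_that("phantom generation is deterministic and properly nested", {
  spec <- phantom_spec(seed = 11L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$rois$masks, b$rois$masks)

  ptv <- a$rois$masks$ptv
  boost <- a$rois$masks$boost
  body <- a$rois$masks$body
  expect_false(any(boost & !ptv))
  expect_false(any(ptv & !body))
  expect_lt(sum(boost), sum(ptv))
  expect_lt(sum(ptv), sum(body))
  for (nm in names(a$rois$masks)[a$rois$roles == "oar"])
    expect_false(any(a$rois$masks[[nm]] & !body))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(ptv_semiaxes = c(200, 200, 50)),
               "not strictly inside the body")
  expect_error(phantom_spec(boost_semiaxes = c(40, 40, 15)),
               "not strictly inside the PTV")
  expect_error(phantom_spec(boost_center = c(30, 10, 0)),
               "not strictly inside the PTV")
  expect_error(phantom_spec(grid_shape = c(6, 6, 4)), "at least 8")
  expect_error(phantom_spec(grid_shape = c(32, 32, 8),
                            spacing = c(2, 2, 3)),
               "too small to contain the body")
  expect_error(phantom_spec(ptv_semiaxes = c(-5, 20, 10)), "positive")
})

test_that("schematic CT separates air, soft tissue and bone tiers", {
  case <- generate_phantom(phantom_spec(seed = 3L))
  ct <- case$ct$values
  body <- case$rois$masks$body
  air <- mean(ct[!body])
  expect_lt(air, -900)
  # bone-like shell reads high, interior soft tissue low
  expect_gt(quantile(ct[body], 0.95), 500)
  expect_lt(median(ct[body]), 200)
})

test_that("engine dose plateaus at the prescriptions and follows the stated falloff", {
  case <- noiseless_case()
  params <- dose_engine_params(noise_sd = 0)
  dose <- case$dose_gt$values
  rois <- case$rois$masks
  expect_true(all(dose[rois$boost] == 69.96))
  expect_true(all(dose[rois$ptv & !rois$boost] == 60.06))
  expect_true(all(dose >= 0))
  expect_true(all(dose[!rois$body] == 0))

  d <- case$dptv$values
  spared <- Reduce(`|`, case$rois$masks[names(case$rois$masks) %in%
                                          names(default_oar_sparing())])
  free <- rois$body & !rois$ptv & rois$field & !spared
  # closed form at DPTV = tau
  at_tau <- which(free & abs(d - params$falloff_tau) < 1e-9)
  if (!length(at_tau)) {
    # no voxel lands exactly on tau on this grid; check the form everywhere
    expect_equal(dose[free], 60.06 * exp(-d[free] / params$falloff_tau),
                 tolerance = 1e-12)
  } else {
    expect_equal(dose[at_tau], rep(60.06 * exp(-1), length(at_tau)))
  }
  # monotone falloff for a specific near/far pair
  iv <- which(free)
  near <- iv[which.min(d[iv])]
  far <- iv[which.max(d[iv])]
  expect_gt(dose[near], dose[far])
})

test_that("out-of-field dose is capped and grids must align", {
  case <- noiseless_case()
  rois <- case$rois$masks
  off <- rois$body & !rois$field
  expect_gt(sum(off), 0)
  expect_true(all(case$dose_gt$values[off] <= 0.02 * 60.06 + 1e-12))

  bad <- volume_grid(array(0, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_error(simulate_dose(case, dose_engine_params(), dptv = bad),
               "grid mismatch")
})

test_that("dose decreases strictly with distance on unspared in-field tissue", {
  case <- noiseless_case()
  rois <- case$rois$masks
  spared <- Reduce(`|`, case$rois$masks[names(case$rois$masks) %in%
                                          names(default_oar_sparing())])
  free <- rois$body & !rois$ptv & rois$field & !spared
  rho <- cor(rank(case$dptv$values[free]), rank(case$dose_gt$values[free]))
  expect_equal(rho, -1)
})

test_that("high-dose volume matches the PTV volume up to boundary voxels", {
  case <- noiseless_case()
  rois <- case$rois$masks
  dose <- case$dose_gt$values
  d <- case$dptv$values
  frac_high <- mean(dose[rois$body] > 0.9 * 60.06)
  frac_ptv <- mean(rois$ptv[rois$body])
  boundary <- mean((d[rois$body] > 0) & (d[rois$body] <= 3))
  expect_lte(abs(frac_high - frac_ptv), boundary + 1e-12)
})

test_that("noise is additive, clipped at zero and seed-stable", {
  base <- generate_phantom(phantom_spec(seed = 5L))
  base$dptv <- compute_dptv(base$rois$masks$ptv, base$rois$masks$body,
                            base$rois$spacing)
  a <- simulate_dose(base, dose_engine_params(noise_sd = 2), dptv = base$dptv)
  b <- simulate_dose(base, dose_engine_params(noise_sd = 2), dptv = base$dptv)
  expect_identical(a$dose_gt$values, b$dose_gt$values)
  expect_true(all(a$dose_gt$values >= 0))
  clean <- simulate_dose(base, dose_engine_params(noise_sd = 0),
                         dptv = base$dptv)
  expect_gt(sd(a$dose_gt$values - clean$dose_gt$values), 1)
})

test_that("cohorts are reproducible with distinct per-case geometry", {
  co <- make_cohort(10, seed = 21L)
  centers <- t(vapply(co, function(cs) cs$spec$ptv_center, numeric(3)))
  expect_equal(nrow(unique(centers)), 10L)
  co2 <- make_cohort(10, seed = 21L)
  for (i in seq_along(co))
    expect_identical(co[[i]]$dose_gt$values, co2[[i]]$dose_gt$values)

  one <- make_cohort(1, seed = 4L)
  expect_length(one, 1L)
  expect_s3_class(one[[1L]], "phantom_case")
  expect_false(is.null(one[[1L]]$dose_gt))

  expect_error(make_cohort(0), "at least 1")
  expect_error(make_cohort(2, spec_ranges = list(ptv_jitter_mm = 1,
                                                 oar_jitter_mm = 1,
                                                 ptv_scale = numeric(0),
                                                 body_scale = c(1, 1))),
               "non-empty")
})
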