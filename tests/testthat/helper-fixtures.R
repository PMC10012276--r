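# Shared fixtures: everything is generated in code at test time.

# brute-force nearest-PTV-voxel search; the independent oracle for the
# distance transform
bf_dptv <- function(ptv, body, spacing) {
  dm <- dim(ptv)
  idx <- which(ptv, arr.ind = TRUE)
  out <- array(0, dim = dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (ptv[i, j, k] || !body[i, j, k]) next
    out[i, j, k] <- sqrt(min(((idx[, 1] - i) * spacing[1])^2 +
                               ((idx[, 2] - j) * spacing[2])^2 +
                               ((idx[, 3] - k) * spacing[3])^2))
  }
  out
}

# one default phantom with noiseless engine dose, cached across tests
noiseless_case <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      case <- generate_phantom(phantom_spec(seed = 7L))
      case$dptv <- compute_dptv(case$rois$masks$ptv, case$rois$masks$body,
                                case$rois$spacing)
      val <<- simulate_dose(case, dose_engine_params(noise_sd = 0),
                            dptv = case$dptv)
    }
    val
  }
})

tiny_net_config <- function(in_channels = 3L, wm = 1 / 16) {
  network_config(in_channels = in_channels,
                 stage_blocks = c(1L, 1L, 1L, 1L),
                 width_multiplier = wm)
}

# hand-built 6x6x2 toy ROI set: body excludes the x = 1 plane, one OAR
# ("cord", x 2:3 / y 2:3), one target ("ptv", x 3:5 / y 3:5), in-field
# region = slice 1 only
toy_rois <- function() {
  dm <- c(6L, 6L, 2L)
  body <- array(TRUE, dm); body[1, , ] <- FALSE
  cord <- array(FALSE, dm); cord[2:3, 2:3, ] <- TRUE
  ptv <- array(FALSE, dm); ptv[3:5, 3:5, ] <- TRUE
  field <- array(FALSE, dm); field[, , 1] <- TRUE
  roi_set(list(body = body, cord = cord, ptv = ptv, field = field),
          c(body = "body", cord = "oar", ptv = "target", field = "field"),
          spacing = c(1, 1, 1))
}
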