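#' Training configuration for the dose predictor
#'
#' @param epochs training epochs (default 100, matching the convergence
#'   budget used at clinical scale; desk-scale experiments use fewer).
#' @param loss `"mse"` (default) or `"mae"`, computed on dose normalized by
#'   the boost prescription.
#' @param optimizer only `"adam"` is implemented.
#' @param lr learning rate.
#' @param batch_size slices per gradient step.
#' @param seed RNG seed covering weight initialization and slice shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, loss = c("mse", "mae"),
                         optimizer = "adam", lr = 1e-4, batch_size = 8L,
                         seed = 1L) {
  loss <- match.arg(loss)
  if (epochs < 1L) stop("epochs must be at least 1")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(list(epochs = as.integer(epochs), loss = loss,
                 optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p))),
       v = lapply(params, function(p) array(0, dim = dim(p))),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in ls(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    net$params[[nm]] <- net$params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# stack training slices from a list of cases
build_training_set <- function(cases, mode, ct_window = c(-1000, 1000),
                               dptv_cap_mm = 150) {
  xs <- list()
  ts <- list()
  denom <- NULL
  for (case in cases) {
    if (is.null(case$dose_gt)) stop("every training case needs dose_gt")
    stack <- assemble_inputs(case, mode, ct_window, dptv_cap_mm)
    denom <- case$prescriptions$boost
    d <- vol_values(case$dose_gt) / denom
    dims <- dim(d)
    xs[[length(xs) + 1L]] <- stack$x
    ts[[length(ts) + 1L]] <- array(d, dim = c(dims[1L], dims[2L], 1L, dims[3L]))
  }
  x <- array(0, dim = c(dim(xs[[1L]])[1:3], sum(vapply(xs, function(a) dim(a)[4L], 0))))
  t_ <- array(0, dim = c(dim(ts[[1L]])[1:3], dim(x)[4L]))
  at <- 0L
  for (i in seq_along(xs)) {
    ns <- dim(xs[[i]])[4L]
    x[, , , at + seq_len(ns)] <- xs[[i]]
    t_[, , , at + seq_len(ns)] <- ts[[i]]
    at <- at + ns
  }
  list(x = x, target = t_, denom = denom)
}

#' Train a dose predictor on phantom cases
#'
#' Slice-wise training: each axial slice of each case becomes one sample
#' mapping the normalized input stack to the ground-truth dose slice
#' divided by the boost prescription. Optimizes the configured loss with
#' Adam; fully deterministic given the seed. After the final epoch the
#' batch-normalization inference statistics are recalibrated in a single
#' pass over (up to 128) training slices, so evaluation-mode activations
#' match the trained regime rather than a lagging running average.
#'
#' @param predictor a `dose_predictor` from [build_network()], or a
#'   [network_config()] (the network is then built under the training seed).
#' @param cases list of `phantom_case` with `dose_gt`, sharing one grid.
#' @param mode `"ANAT"` or `"COM"`; must match the network's `in_channels`.
#' @param tconfig a [train_config()].
#' @param ct_window,dptv_cap_mm input normalization, see
#'   [assemble_inputs()].
#' @return An object of class `trained_model` with the fitted network, the
#'   per-epoch loss `history`, and the normalization metadata needed at
#'   prediction time.
#' @export
train <- function(predictor, cases, mode = c("COM", "ANAT"),
                  tconfig = train_config(),
                  ct_window = c(-1000, 1000), dptv_cap_mm = 150) {
  mode <- match.arg(mode)
  if (!length(cases)) stop("need at least one training case")
  set.seed(tconfig$seed)
  if (inherits(predictor, "network_config")) predictor <- build_network(predictor)
  need <- if (mode == "COM") 3L else 2L
  if (predictor$config$in_channels != need)
    stop(sprintf("mode %s needs %d input channels but the network has %d",
                 mode, need, predictor$config$in_channels))
  dat <- build_training_set(cases, mode, ct_window, dptv_cap_mm)
  ns <- dim(dat$x)[4L]
  state <- adam_init(predictor$params)
  history <- numeric(tconfig$epochs)
  for (ep in seq_len(tconfig$epochs)) {
    perm <- sample.int(ns)
    starts <- seq(1L, ns, by = tconfig$batch_size)
    ep_loss <- 0
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + tconfig$batch_size - 1L, ns)]
      xb <- dat$x[, , , idx, drop = FALSE]
      tb <- dat$target[, , , idx, drop = FALSE]
      fwd <- net_forward(predictor, xb, training = TRUE, with_cache = TRUE)
      predictor <- apply_buffer_updates(predictor, fwd$upd)
      resid <- fwd$y - tb
      loss <- if (tconfig$loss == "mse") mean(resid^2) else mean(abs(resid))
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (batch starting %d): %s",
                     ep, s0, format(loss)))
      dy <- if (tconfig$loss == "mse") 2 * resid / length(resid)
            else sign(resid) / length(resid)
      grads <- net_backward(predictor, fwd, dy)
      upd <- adam_step(predictor, grads, state, tconfig$lr)
      predictor <- upd$net
      state <- upd$state
      ep_loss <- ep_loss + loss * length(idx)
    }
    history[ep] <- ep_loss / ns
  }
  predictor <- calibrate_bn(predictor, dat$x)
  structure(list(net = predictor, mode = mode, tconfig = tconfig,
                 history = history,
                 norm = list(dose_denominator = dat$denom,
                             ct_window = ct_window,
                             dptv_cap_mm = dptv_cap_mm)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> mode=%s, %d epochs, final loss %.4g\n",
              x$mode, length(x$history), tail(x$history, 1L)))
  invisible(x)
}

#' Predict a 3D dose map for a case
#'
#' Runs slice-wise inference, stacks the slices back to a volume,
#' de-normalizes to Gy by the boost prescription and clips negative
#' outputs to zero.
#'
#' @param model a `trained_model`.
#' @param case a `phantom_case` (dose not required).
#' @param batch_slices slices per forward pass.
#' @return A [volume_grid()] dose map in Gy.
#' @export
predict_volume <- function(model, case, batch_slices = 16L) {
  stack <- assemble_inputs(case, model$mode, model$norm$ct_window,
                           model$norm$dptv_cap_mm)
  d <- dim(stack$x)
  out <- array(0, dim = c(d[1L], d[2L], d[4L]))
  for (s0 in seq(1L, d[4L], by = batch_slices)) {
    idx <- s0:min(s0 + batch_slices - 1L, d[4L])
    fwd <- net_forward(model$net, stack$x[, , , idx, drop = FALSE],
                       training = FALSE)
    out[, , idx] <- fwd$y[, , 1L, ]
  }
  out <- out * model$norm$dose_denominator
  out[out < 0] <- 0
  volume_grid(out, case$rois$spacing)
}

#' Deterministic k-fold split of a cohort
#'
#' Randomly partitions case indices into k disjoint folds whose sizes
#' differ by at most one (the first `n %% k` folds take the extra case).
#' Each fold is used once as the test set with the remainder for training.
#'
#' @param cohort a list of cases, or an integer case count.
#' @param k number of folds (>= 2, <= cohort size).
#' @param seed RNG seed for the partition.
#' @return List of k elements, each `list(train = indices, test = indices)`.
#' @export
kfold_split <- function(cohort, k, seed = 1L) {
  n <- if (is.numeric(cohort) && length(cohort) == 1L) as.integer(cohort)
       else length(cohort)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the cohort size")
  set.seed(seed)
  perm <- sample.int(n)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  at <- 0L
  lapply(seq_len(k), function(i) {
    test <- sort(perm[at + seq_len(sizes[i])])
    at <<- at + sizes[i]
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
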