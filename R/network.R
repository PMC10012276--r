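#' Configuration of the fully-convolutional dose predictor
#'
#' A residual encoder-decoder for slice-wise dose regression. The encoder
#' is a bottleneck residual network: a 7x7, 64-filter stem convolution with
#' stride 2, a 3x3 max-pool, then four stages of "deeper bottleneck"
#' blocks (1x1 -> 3x3 -> 1x1 convolutions with a skip connection) with
#' default block counts (3, 4, 23, 5). Only the stem, the pool and the
#' second stage downsample; the last two stages hold the feature map at 1/8
#' of the input resolution using dilation 2 and 4 — the standard
#' dense-prediction adaptation that realizes the 1/8 output stride.
#' The decoder restores full resolution with three fractionally-strided
#' (transposed) convolutions of stride 2 and a final 1x1 projection to one
#' dose channel.
#'
#' `width_multiplier` scales every channel count, allowing desk-scale
#' models (e.g. 1/16 width with one block per stage) that train in seconds
#' on a CPU while preserving the architecture's shape contracts.
#'
#' @param in_channels 2 (ANAT: CT + structure map) or 3 (COM: + DPTV).
#' @param stage_blocks integer length-4, bottleneck blocks per stage.
#' @param width_multiplier channel scale factor in (0, 1].
#' @param base_filters stem filter count before scaling (64).
#' @param out_channels output channels (1 dose map).
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 3L,
                           stage_blocks = c(3L, 4L, 23L, 5L),
                           width_multiplier = 1,
                           base_filters = 64L,
                           out_channels = 1L) {
  if (!in_channels %in% 2:3) stop("in_channels must be 2 (ANAT) or 3 (COM)")
  if (length(stage_blocks) != 4L || any(stage_blocks < 1L))
    stop("stage_blocks must be 4 positive counts")
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must be in (0, 1]")
  structure(list(in_channels = as.integer(in_channels),
                 stage_blocks = as.integer(stage_blocks),
                 width_multiplier = width_multiplier,
                 base_filters = as.integer(base_filters),
                 out_channels = as.integer(out_channels)),
            class = "network_config")
}

# ---- parameter store -------------------------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$params <- list()
  env$buffers <- list()
  env$n <- 0L
  env
}

add_param <- function(bld, dims, sd = NULL) {
  bld$n <- bld$n + 1L
  nm <- sprintf("p%03d", bld$n)
  v <- if (is.null(sd) || sd == 0) array(0, dim = dims)
       else array(rnorm(prod(dims), sd = sd), dim = dims)
  bld$params[[nm]] <- v
  nm
}

add_buffer <- function(bld, dims, value) {
  bld$n <- bld$n + 1L
  nm <- sprintf("b%03d", bld$n)
  bld$buffers[[nm]] <- array(value, dim = dims)
  nm
}

mk_conv <- function(bld, kh, kw, cin, cout, stride = 1L, pad = 0L,
                    dil = 1L, bias = FALSE, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (kh * kw * cin))  # He initialization
  list(type = "conv",
       w = add_param(bld, c(kh, kw, cin, cout), sd),
       b = if (bias) add_param(bld, cout, 0) else NULL,
       stride = as.integer(stride), pad = as.integer(pad),
       dil = as.integer(dil))
}

# transposed conv, kernel 4 / stride 2 / pad 1: exact x2 upsampling
mk_tconv <- function(bld, cin, cout) {
  list(type = "tconv",
       w = add_param(bld, c(4L, 4L, cout, cin), sqrt(2 / (16 * cin))),
       b = add_param(bld, cout, 0),
       stride = 2L, pad = 1L, k = 4L)
}

mk_bn <- function(bld, c) {
  bld$n <- bld$n + 1L
  gamma <- sprintf("p%03dg", bld$n)
  beta <- sprintf("p%03db", bld$n)
  bld$params[[gamma]] <- array(1, dim = c)
  bld$params[[beta]] <- array(0, dim = c)
  list(type = "bn", gamma = gamma, beta = beta,
       rm = add_buffer(bld, c, 0), rv = add_buffer(bld, c, 1),
       eps = 1e-5, momentum = 0.1)
}

mk_seq <- function(...) list(type = "seq", children = list(...))

mk_bottleneck <- function(bld, cin, mid, cout, stride = 1L, dil = 1L) {
  main <- mk_seq(
    mk_conv(bld, 1L, 1L, cin, mid), mk_bn(bld, mid), list(type = "relu"),
    mk_conv(bld, 3L, 3L, mid, mid, stride = stride, pad = dil, dil = dil),
    mk_bn(bld, mid), list(type = "relu"),
    mk_conv(bld, 1L, 1L, mid, cout), mk_bn(bld, cout))
  proj <- if (cin != cout || stride != 1L)
    mk_seq(mk_conv(bld, 1L, 1L, cin, cout, stride = stride), mk_bn(bld, cout))
  list(type = "block", main = main, proj = proj)
}

#' Build a dose predictor network
#'
#' Instantiates the architecture described by [network_config()] with
#' He-initialized weights drawn from the current R random stream (seed
#' before calling for reproducible initialization).
#'
#' @param config a [network_config()].
#' @return An object of class `dose_predictor`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  wm <- config$width_multiplier
  base <- max(1L, as.integer(round(config$base_filters * wm)))
  bld <- new_builder()

  stem <- mk_seq(mk_conv(bld, 7L, 7L, config$in_channels, base,
                         stride = 2L, pad = 3L),
                 mk_bn(bld, base), list(type = "relu"),
                 list(type = "maxpool", k = 3L, stride = 2L, pad = 1L))

  stages <- list()
  cin <- base
  dils <- c(1L, 1L, 2L, 4L)
  strides <- c(1L, 2L, 1L, 1L)
  for (s in 1:4) {
    mid <- base * 2L^(s - 1L)
    cout <- 4L * mid
    for (b in seq_len(config$stage_blocks[s])) {
      stages[[length(stages) + 1L]] <-
        mk_bottleneck(bld, cin, mid, cout,
                      stride = if (b == 1L) strides[s] else 1L,
                      dil = dils[s])
      cin <- cout
    }
  }

  decoder <- mk_seq(
    mk_tconv(bld, cin, 4L * base), mk_bn(bld, 4L * base),
    list(type = "relu"),
    mk_tconv(bld, 4L * base, 2L * base), mk_bn(bld, 2L * base),
    list(type = "relu"),
    mk_tconv(bld, 2L * base, base), mk_bn(bld, base),
    list(type = "relu"),
    mk_conv(bld, 1L, 1L, base, config$out_channels, bias = TRUE, sd = 0.01))

  net <- list(config = config,
              encoder = mk_seq(stem, do.call(mk_seq, stages)),
              decoder = decoder,
              params = bld$params,
              buffers = bld$buffers)
  class(net) <- "dose_predictor"
  net
}

#' @export
print.dose_predictor <- function(x, ...) {
  cat(sprintf(paste0("<dose_predictor> in_channels=%d, stages (%s), width x%g,",
                     " %d parameter tensors (%s values)\n"),
              x$config$in_channels,
              paste(x$config$stage_blocks, collapse = ","),
              x$config$width_multiplier, length(x$params),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable scalar parameters
#' @param net a `dose_predictor` or `trained_model`.
#' @return Integer count.
#' @export
n_parameters <- function(net) {
  if (inherits(net, "trained_model")) net <- net$net
  sum(vapply(net$params, length, numeric(1)))
}

# ---- forward / backward ----------------------------------------------------

chan_sum <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1L] * d[2L], d[3L], d[4L])
  rowSums(colSums(a))
}

lay_fwd <- function(layer, x, net, training, upd) {
  switch(layer$type,
    conv = {
      w <- net$params[[layer$w]]
      y <- .cpp_conv_fwd(x, w, layer$stride, layer$stride,
                         layer$pad, layer$pad, layer$dil, layer$dil)
      if (!is.null(layer$b)) {
        d <- dim(y)
        y <- y + rep(net$params[[layer$b]], each = d[1L] * d[2L])
      }
      list(y = y, cache = x)
    },
    tconv = {
      w <- net$params[[layer$w]]
      d <- dim(x)
      y <- .cpp_conv_bwd_data(x, w, layer$stride, layer$stride,
                              layer$pad, layer$pad, 1L, 1L,
                              d[1L] * 2L, d[2L] * 2L)
      dy <- dim(y)
      y <- y + rep(net$params[[layer$b]], each = dy[1L] * dy[2L])
      list(y = y, cache = x)
    },
    bn = {
      d <- dim(x)
      hw <- d[1L] * d[2L]
      m <- hw * d[4L]
      if (training) {
        sums <- chan_sum(x)
        mu <- sums / m
        ex2 <- chan_sum(x * x) / m
        v <- pmax(ex2 - mu^2, 0)
        mom <- if (is.null(net$bn_momentum)) layer$momentum else net$bn_momentum
        upd[[layer$rm]] <- (1 - mom) * net$buffers[[layer$rm]] + mom * mu
        upd[[layer$rv]] <- (1 - mom) * net$buffers[[layer$rv]] + mom * v
      } else {
        mu <- as.numeric(net$buffers[[layer$rm]])
        v <- as.numeric(net$buffers[[layer$rv]])
      }
      ivs <- 1 / sqrt(v + layer$eps)
      xhat <- (x - rep(mu, each = hw)) * rep(ivs, each = hw)
      y <- xhat * rep(net$params[[layer$gamma]], each = hw) +
        rep(net$params[[layer$beta]], each = hw)
      list(y = y, cache = list(xhat = xhat, ivs = ivs, m = m))
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = mask)
    },
    maxpool = {
      r <- .cpp_maxpool_fwd(x, layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1L], W = dim(x)[2L]))
    },
    seq = {
      caches <- vector("list", length(layer$children))
      for (i in seq_along(layer$children)) {
        r <- lay_fwd(layer$children[[i]], x, net, training, upd)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    block = {
      rm <- lay_fwd(layer$main, x, net, training, upd)
      if (is.null(layer$proj)) {
        s <- rm$y + x
        pc <- NULL
      } else {
        rp <- lay_fwd(layer$proj, x, net, training, upd)
        s <- rm$y + rp$y
        pc <- rp$cache
      }
      mask <- s > 0
      list(y = s * mask, cache = list(main = rm$cache, proj = pc,
                                      mask = mask))
    },
    stop("unknown layer type ", layer$type))
}

acc_grad <- function(g, nm, val) {
  if (is.null(g[[nm]])) g[[nm]] <- val else g[[nm]] <- g[[nm]] + val
}

lay_bwd <- function(layer, cache, dy, net, g) {
  switch(layer$type,
    conv = {
      x <- cache
      w <- net$params[[layer$w]]
      wd <- dim(w)
      if (!is.null(layer$b)) acc_grad(g, layer$b, chan_sum(dy))
      acc_grad(g, layer$w,
               .cpp_conv_bwd_filter(x, dy, wd[1L], wd[2L],
                                    layer$stride, layer$stride,
                                    layer$pad, layer$pad,
                                    layer$dil, layer$dil))
      .cpp_conv_bwd_data(dy, w, layer$stride, layer$stride,
                         layer$pad, layer$pad, layer$dil, layer$dil,
                         dim(x)[1L], dim(x)[2L])
    },
    tconv = {
      x <- cache
      w <- net$params[[layer$w]]
      acc_grad(g, layer$b, chan_sum(dy))
      acc_grad(g, layer$w,
               .cpp_conv_bwd_filter(dy, x, layer$k, layer$k,
                                    layer$stride, layer$stride,
                                    layer$pad, layer$pad, 1L, 1L))
      .cpp_conv_fwd(dy, w, layer$stride, layer$stride,
                    layer$pad, layer$pad, 1L, 1L)
    },
    bn = {
      hw <- dim(dy)[1L] * dim(dy)[2L]
      xhat <- cache$xhat
      m <- cache$m
      acc_grad(g, layer$gamma, chan_sum(dy * xhat))
      acc_grad(g, layer$beta, chan_sum(dy))
      dxhat <- dy * rep(net$params[[layer$gamma]], each = hw)
      s1 <- chan_sum(dxhat)
      s2 <- chan_sum(dxhat * xhat)
      (dxhat - rep(s1 / m, each = hw) - xhat * rep(s2 / m, each = hw)) *
        rep(cache$ivs, each = hw)
    },
    relu = dy * cache,
    maxpool = .cpp_maxpool_bwd(dy, cache$idx, cache$H, cache$W),
    seq = {
      for (i in rev(seq_along(layer$children)))
        dy <- lay_bwd(layer$children[[i]], cache[[i]], dy, net, g)
      dy
    },
    block = {
      ds <- dy * cache$mask
      dx <- lay_bwd(layer$main, cache$main, ds, net, g)
      if (is.null(layer$proj)) dx + ds
      else dx + lay_bwd(layer$proj, cache$proj, ds, net, g)
    },
    stop("unknown layer type ", layer$type))
}

pad_to_multiple <- function(x, mult = 8L) {
  d <- dim(x)
  ph <- (mult - d[1L] %% mult) %% mult
  pw <- (mult - d[2L] %% mult) %% mult
  if (ph == 0L && pw == 0L) return(list(x = x, pad = c(0L, 0L)))
  message(sprintf("input %dx%d not divisible by %d: padding to %dx%d and cropping the output",
                  d[1L], d[2L], mult, d[1L] + ph, d[2L] + pw))
  xp <- array(0, dim = c(d[1L] + ph, d[2L] + pw, d[3L], d[4L]))
  xp[seq_len(d[1L]), seq_len(d[2L]), , ] <- x
  list(x = xp, pad = c(ph, pw))
}

# forward pass over a batch of slices; x is (H, W, C, N)
net_forward <- function(net, x, training = FALSE, with_cache = FALSE) {
  stopifnot(length(dim(x)) == 4L)
  if (dim(x)[3L] != net$config$in_channels)
    stop(sprintf("input has %d channels but the network expects %d",
                 dim(x)[3L], net$config$in_channels))
  d0 <- dim(x)
  p <- pad_to_multiple(x)
  upd <- new.env(parent = emptyenv())
  enc <- lay_fwd(net$encoder, p$x, net, training, upd)
  dec <- lay_fwd(net$decoder, enc$y, net, training, upd)
  y <- dec$y
  if (any(p$pad > 0L)) y <- y[seq_len(d0[1L]), seq_len(d0[2L]), , , drop = FALSE]
  out <- list(y = y, encoded_dim = dim(enc$y), upd = upd)
  if (with_cache) {
    out$enc_cache <- enc$cache
    out$dec_cache <- dec$cache
    out$pad <- p$pad
    out$dims_in <- dim(p$x)
  }
  out
}

# backward pass; returns an environment of parameter gradients
net_backward <- function(net, fwd, dy) {
  if (any(fwd$pad > 0L)) {
    d <- fwd$dims_in
    dyp <- array(0, dim = c(d[1L], d[2L], dim(dy)[3L], d[4L]))
    dyp[seq_len(dim(dy)[1L]), seq_len(dim(dy)[2L]), , ] <- dy
    dy <- dyp
  }
  g <- new.env(parent = emptyenv())
  denc <- lay_bwd(net$decoder, fwd$dec_cache, dy, net, g)
  lay_bwd(net$encoder, fwd$enc_cache, denc, net, g)
  g
}

apply_buffer_updates <- function(net, upd) {
  for (nm in ls(upd)) net$buffers[[nm]] <- upd[[nm]]
  net
}

# Recompute batch-norm inference statistics from a representative sample in
# one pass (momentum 1), so evaluation-mode activations match the trained
# regime instead of a lagging running average.
calibrate_bn <- function(net, x, max_slices = 128L) {
  n <- dim(x)[4L]
  if (n > max_slices) x <- x[, , , seq_len(max_slices), drop = FALSE]
  net$bn_momentum <- 1
  fwd <- net_forward(net, x, training = TRUE)
  net <- apply_buffer_updates(net, fwd$upd)
  net$bn_momentum <- NULL
  net
}
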