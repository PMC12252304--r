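# ---------------------------------------------------------------------------
# Dynamic convolution: input-conditioned softmax routing over a bank of M
# expert kernels, aggregated into one kernel per sample.
#
#   alpha = softmax(MLP(GlobalAvgPool(x)))      (one alpha per sample)
#   W'    = sum_i alpha_i W_i
#   y_n   = conv(x_n, W'_n)
#
# The router is a two-layer perceptron (C_in -> hidden -> M) with a SiLU on
# the hidden layer and plain softmax on the logits (temperature exposed but 1
# by default).
# ---------------------------------------------------------------------------

#' Create a kernel bank for dynamic convolution
#'
#' A kernel bank holds `M` expert convolution kernels of identical shape
#' `(k, k, c_in/groups, c_out)` and an optional shared bias.
#'
#' @param experts number of expert kernels (M >= 1).
#' @param c_in,c_out input and output channel counts.
#' @param k kernel size (square).
#' @param groups channel groups (depthwise when `groups == c_in`).
#' @param bias logical; include a shared output bias.
#' @param init `"kaiming"` (default) or `"zero"`.
#' @param seed optional integer seed for reproducible initialization.
#' @return an object of class `kernel_bank`.
#' @export
kernel_bank <- function(experts, c_in, c_out, k = 3L, groups = 1L,
                        bias = FALSE, init = "kaiming", seed = NULL) {
  stopifnot(experts >= 1, c_in >= 1, c_out >= 1, k >= 1, c_in %% groups == 0)
  w <- array(0, c(k, k, c_in %/% groups, c_out, experts))
  if (init == "kaiming") {
    n <- length(w)
    fan_in <- k * k * (c_in %/% groups)
    w[] <- local_runif(n, -1, 1, seed = seed %||% 0L) / sqrt(fan_in)
  }
  structure(list(w = w, b = if (bias) numeric(c_out) else NULL,
                 experts = as.integer(experts), c_in = as.integer(c_in),
                 c_out = as.integer(c_out), k = as.integer(k),
                 groups = as.integer(groups)),
            class = "kernel_bank")
}

#' Create a routing network for dynamic convolution
#'
#' Two-layer perceptron mapping the globally average-pooled input descriptor
#' (length `c_in`) to `M` softmax logits.
#'
#' @param c_in input channel count.
#' @param experts number of experts M (output dimension).
#' @param hidden hidden width; default `max(c_in/4, 4)`.
#' @param temperature softmax temperature (default 1).
#' @param seed optional seed for reproducible initialization.
#' @return an object of class `dyn_router`.
#' @export
make_router <- function(c_in, experts, hidden = NULL, temperature = 1,
                        seed = NULL) {
  stopifnot(c_in >= 1, experts >= 1, temperature > 0)
  if (is.null(hidden)) hidden <- max(c_in %/% 4L, 4L)
  s <- seed %||% 0L
  w1 <- matrix(local_runif(c_in * hidden, -1, 1, seed = s) / sqrt(c_in), c_in, hidden)
  w2 <- matrix(local_runif(hidden * experts, -1, 1, seed = s + 1L) / sqrt(hidden),
               hidden, experts)
  structure(list(w1 = w1, b1 = numeric(hidden), w2 = w2, b2 = numeric(experts),
                 c_in = as.integer(c_in), experts = as.integer(experts),
                 hidden = as.integer(hidden), temperature = temperature),
            class = "dyn_router")
}

#' Per-sample routing coefficients
#'
#' Applies global average pooling to the input, pushes the pooled descriptor
#' through the router MLP and returns one softmax simplex vector per sample.
#'
#' @param x feature map array `(H, W, C, N)` (or `(H, W, C)` for one sample).
#' @param router a [make_router()] object.
#' @return an `N x M` matrix; each row is non-negative and sums to 1.
#' @export
routing_coefficients <- function(x, router) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[3] != router$c_in)
    stop("channel mismatch: input has ", d[3], " channels, router expects ",
         router$c_in)
  a <- gap_hw(x)                                    # C x N
  z1 <- t(a) %*% router$w1 + rep(router$b1, each = d[4])
  h1 <- silu(z1)
  z2 <- h1 %*% router$w2 + rep(router$b2, each = d[4])
  softmax_rows(z2 / router$temperature)
}

#' Aggregate a kernel bank with routing coefficients
#'
#' Forms `W' = sum_i alpha_i W_i` (and the shared bias, unchanged).
#'
#' @param bank a [kernel_bank()].
#' @param alpha numeric vector of length M (a single sample's coefficients).
#' @return array `(k, k, c_in/groups, c_out)`.
#' @export
aggregate_kernel <- function(bank, alpha) {
  if (length(alpha) != bank$experts)
    stop("alpha has length ", length(alpha), ", bank has ", bank$experts,
         " experts")
  d <- dim(bank$w)
  m <- matrix(bank$w, ncol = d[5])
  array(as.numeric(m %*% alpha), d[1:4])
}

#' Dynamic convolution forward pass
#'
#' Each sample in the batch is convolved with its own aggregated kernel.
#'
#' @param x input array `(H, W, C, N)` or `(H, W, C)`.
#' @param bank a [kernel_bank()].
#' @param router a [make_router()] with matching `c_in` and `experts`.
#' @param stride,padding convolution geometry; `padding = NULL` means "same"
#'   for odd kernels.
#' @return output feature map array.
#' @export
dynamic_conv_forward <- function(x, bank, router, stride = 1L, padding = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(bank$experts == router$experts)
  if (is.null(padding)) padding <- (bank$k - 1L) %/% 2L
  alpha <- routing_coefficients(x, router)
  d <- dim(x)
  out <- NULL
  for (n in seq_len(d[4])) {
    wn <- aggregate_kernel(bank, alpha[n, ])
    xn <- x[, , , n, drop = FALSE]
    yn <- .conv2d_fw(xn, dim(xn), wn, dim(wn), bank$b, as.integer(stride),
                     as.integer(padding), bank$groups)
    if (is.null(out)) out <- array(0, c(dim(yn)[1:3], d[4]))
    out[, , , n] <- yn
  }
  out
}

#' Parameter and FLOP cost of a dynamic convolution layer
#'
#' Itemizes trainable parameters (bank, router, bias) and the per-forward
#' floating point operations (1 multiply-accumulate = 2 FLOPs) at a given
#' input spatial size: the convolution itself (identical to a standard
#' convolution with the aggregated kernel), global average pooling, the router
#' MLP and the bank aggregation.
#'
#' @param bank a [kernel_bank()].
#' @param router a [make_router()].
#' @param input_hw input spatial size (single side, square input).
#' @param stride convolution stride.
#' @return list with `params` and `flops`, each itemized plus a `total`.
#' @export
layer_cost <- function(bank, router, input_hw, stride = 1L) {
  kw <- bank$k^2 * (bank$c_in %/% bank$groups) * bank$c_out
  p_bank <- bank$experts * kw
  p_bias <- if (is.null(bank$b)) 0L else bank$c_out
  p_router <- router$c_in * router$hidden + router$hidden +
    router$hidden * router$experts + router$experts
  ho <- floor((input_hw + 2 * ((bank$k - 1) %/% 2) - bank$k) / stride) + 1
  f_conv <- 2 * kw * ho * ho
  f_pool <- bank$c_in * input_hw * input_hw
  f_router <- 2 * (router$c_in * router$hidden + router$hidden * router$experts)
  f_agg <- 2 * bank$experts * kw
  list(params = list(bank = p_bank, router = p_router, bias = p_bias,
                     total = p_bank + p_router + p_bias),
       flops = list(conv = f_conv, pool = f_pool, router = f_router,
                    aggregation = f_agg,
                    total = f_conv + f_pool + f_router + f_agg))
}

# --- tape integration -------------------------------------------------------

dynconv_router_fw <- function(x, P, op) {
  a <- gap_hw(x)                                   # C x N
  N <- ncol(a)
  z1 <- t(a) %*% P[[op$r1]] + rep(P[[op$r1b]], each = N)
  h1 <- silu(z1)
  z2 <- h1 %*% P[[op$r2]] + rep(P[[op$r2b]], each = N)
  alpha <- softmax_rows(z2 / op$temperature)
  list(a = a, z1 = z1, h1 = h1, alpha = alpha)
}

# Per-sample convolution with the aggregated kernels is realized as one
# grouped convolution over the whole batch: the (H, W, C, N) buffer is,
# bitwise, a (H, W, C*N, 1) map, and stacking the N aggregated kernels along
# the output dimension with groups = N * groups reproduces "each sample gets
# its own kernel" in a single gemm-backed call.
dynconv_fw <- function(x, P, op) {
  r <- dynconv_router_fw(x, P, op)
  d <- dim(x); N <- d[4]
  bank <- P[[op$w]]
  bd <- dim(bank)
  bm <- matrix(bank, ncol = bd[5])
  K <- bm %*% t(r$alpha)                           # (k*k*Cg*Co) x N
  wstack <- array(K, c(bd[1], bd[2], bd[3], bd[4] * N))
  xr <- x; dim(xr) <- c(d[1], d[2], d[3] * N, 1L)
  bs <- if (is.null(op$b)) NULL else rep(P[[op$b]], N)
  y <- .conv2d_fw(xr, dim(xr), wstack, dim(wstack), bs,
                  op$stride, op$pad, op$groups * N)
  dy <- dim(y)
  dim(y) <- c(dy[1], dy[2], op$cout, N)
  list(y = y, aux = c(r, list(K = K)))
}

dynconv_bw <- function(x, P, op, aux, gy, need_gx) {
  d <- dim(x); N <- d[4]
  bank <- P[[op$w]]
  bd <- dim(bank)
  bm <- matrix(bank, ncol = bd[5])
  wstack <- array(aux$K, c(bd[1], bd[2], bd[3], bd[4] * N))
  xr <- x; dim(xr) <- c(d[1], d[2], d[3] * N, 1L)
  gyr <- gy; dgy <- dim(gy)
  dim(gyr) <- c(dgy[1], dgy[2], dgy[3] * N, 1L)
  r <- .conv2d_bw(xr, dim(xr), wstack, dim(wstack), gyr, !is.null(op$b),
                  op$stride, op$pad, op$groups * N, need_gx)
  gwm <- matrix(r$gw, ncol = N)                    # per-sample kernel grads
  gbank <- gwm %*% aux$alpha                       # (k*k*Cg*Co) x M
  galpha <- crossprod(gwm, bm)                     # N x M
  gb <- if (is.null(op$b)) NULL else
    rowSums(matrix(r$gb, op$cout, N))
  gx <- NULL
  if (need_gx) { gx <- r$gx; dim(gx) <- d }
  # softmax + MLP backward
  al <- aux$alpha
  gz2 <- (galpha - rowSums(galpha * al)) * al / op$temperature
  gW2 <- crossprod(aux$h1, gz2)
  gb2 <- colSums(gz2)
  gh1 <- gz2 %*% t(P[[op$r2]])
  gz1 <- gh1 * silu_grad(aux$z1)
  gW1 <- aux$a %*% gz1
  gb1 <- colSums(gz1)
  ga <- P[[op$r1]] %*% t(gz1)                       # C x N
  if (need_gx) {
    hw <- d[1] * d[2]
    gx <- gx + sweep_batch_channels(d, ga / hw)
  }
  pg <- list()
  pg[[op$w]] <- array(gbank, bd)
  if (!is.null(gb)) pg[[op$b]] <- gb
  pg[[op$r1]] <- gW1; pg[[op$r1b]] <- gb1
  pg[[op$r2]] <- gW2; pg[[op$r2b]] <- gb2
  list(pg = pg, gx = gx)
}

# broadcast a (C x N) per-channel-per-sample value over (H,W,C,N)
sweep_batch_channels <- function(d, v) {
  array(rep(as.numeric(v), each = d[1] * d[2]), d)
}

gap_hw <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  matrix(colMeans(m), d[3], d[4])
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
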