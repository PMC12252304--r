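#' @useDynLib stomadet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A minimal static-graph runtime with reverse-mode differentiation.
#
# A model is a "tape": an ordered list of primitive ops, each reading one or
# more numbered buffers and writing one. Parameters live in an environment
# keyed by hierarchical names ("b3.conv.w", "hP3.cv2.1.bn.gamma", ...), so the
# same structures serve execution, exact parameter accounting and the
# DynamicConv replacement-site mechanism. Feature buffers are numeric arrays
# with dim c(H, W, C, N).
# ---------------------------------------------------------------------------

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$ops <- list()
  g$nbuf <- 0L
  g$params <- new.env(parent = emptyenv())   # trainable
  g$buffers <- new.env(parent = emptyenv())  # running stats, fixed kernels
  g
}

g_buf <- function(g) { g$nbuf <- g$nbuf + 1L; g$nbuf }

g_emit <- function(g, kind, ins, out, attrs = list()) {
  g$ops[[length(g$ops) + 1L]] <- c(list(kind = kind, ins = ins, out = out), attrs)
  out
}

g_input <- function(g) g_buf(g)

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }

# --- primitive emitters -----------------------------------------------------

g_conv <- function(g, x, name, cin, cout, k, stride = 1L, pad = NULL,
                   groups = 1L, bias = FALSE) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  wn <- paste0(name, ".w")
  assign(wn, array(0, c(k, k, cin %/% groups, cout)), envir = g$params)
  bn <- NULL
  if (bias) {
    bn <- paste0(name, ".b")
    assign(bn, numeric(cout), envir = g$params)
  }
  g_emit(g, "conv", x, g_buf(g),
         list(w = wn, b = bn, stride = as.integer(stride), pad = as.integer(pad),
              groups = as.integer(groups), cin = cin, cout = cout, k = k))
}

g_dynconv <- function(g, x, name, cin, cout, k, stride = 1L, pad = NULL,
                      groups = 1L, bias = FALSE, experts = 4L,
                      router_hidden = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  if (is.null(router_hidden)) router_hidden <- max(cin %/% 4L, 4L)
  M <- as.integer(experts); h <- as.integer(router_hidden)
  wn <- paste0(name, ".bank")
  assign(wn, array(0, c(k, k, cin %/% groups, cout, M)), envir = g$params)
  bn <- NULL
  if (bias) { bn <- paste0(name, ".b"); assign(bn, numeric(cout), envir = g$params) }
  r1 <- paste0(name, ".router.w1"); r1b <- paste0(name, ".router.b1")
  r2 <- paste0(name, ".router.w2"); r2b <- paste0(name, ".router.b2")
  assign(r1, matrix(0, cin, h), envir = g$params)
  assign(r1b, numeric(h), envir = g$params)
  assign(r2, matrix(0, h, M), envir = g$params)
  assign(r2b, numeric(M), envir = g$params)
  g_emit(g, "dynconv", x, g_buf(g),
         list(w = wn, b = bn, r1 = r1, r1b = r1b, r2 = r2, r2b = r2b,
              stride = as.integer(stride), pad = as.integer(pad),
              groups = as.integer(groups), cin = cin, cout = cout, k = k,
              M = M, hidden = h, temperature = 1))
}

g_bn <- function(g, x, name, c) {
  gn <- paste0(name, ".gamma"); bn <- paste0(name, ".beta")
  assign(gn, rep(1, c), envir = g$params)
  assign(bn, numeric(c), envir = g$params)
  assign(paste0(name, ".rm"), numeric(c), envir = g$buffers)
  assign(paste0(name, ".rv"), rep(1, c), envir = g$buffers)
  g_emit(g, "bn", x, g_buf(g), list(gamma = gn, beta = bn,
                                    rm = paste0(name, ".rm"),
                                    rv = paste0(name, ".rv"), c = c))
}

g_silu <- function(g, x) g_emit(g, "silu", x, g_buf(g))
g_add <- function(g, a, b) g_emit(g, "add", c(a, b), g_buf(g))
g_concat <- function(g, ins) g_emit(g, "concat", ins, g_buf(g))
g_slice <- function(g, x, from, to) g_emit(g, "slice", x, g_buf(g),
                                           list(from = as.integer(from), to = as.integer(to)))
g_maxpool <- function(g, x, k = 5L, stride = 1L, pad = 2L)
  g_emit(g, "maxpool", x, g_buf(g),
         list(k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad)))
g_up2 <- function(g, x) g_emit(g, "up2", x, g_buf(g))

# multi-head self-attention over spatial positions; input is the qkv map
# (C + 2*kd*nh channels); output has C channels. Scale = kd^-0.5.
g_mhsa <- function(g, qkv, nh, kd, c)
  g_emit(g, "mhsa", qkv, g_buf(g), list(nh = as.integer(nh), kd = as.integer(kd),
                                        c = as.integer(c)))

# --- forward ---------------------------------------------------------------

#' @noRd
graph_forward <- function(model, x, train = FALSE, keep = NULL) {
  g <- model$graph
  vals <- vector("list", g$nbuf)
  aux <- vector("list", length(g$ops))
  vals[[model$input]] <- x
  P <- g$params; B <- g$buffers
  for (i in seq_along(g$ops)) {
    op <- g$ops[[i]]
    out <- switch(op$kind,
      conv = {
        xin <- vals[[op$ins]]
        .conv2d_fw(xin, dim(xin), P[[op$w]], dim(P[[op$w]]),
                   if (is.null(op$b)) NULL else P[[op$b]],
                   op$stride, op$pad, op$groups)
      },
      dynconv = {
        xin <- vals[[op$ins]]
        r <- dynconv_fw(xin, P, op)
        aux[[i]] <- r$aux
        r$y
      },
      bn = {
        xin <- vals[[op$ins]]
        d <- dim(xin)
        nel <- d[1] * d[2] * d[4]
        if (train) {
          mu <- .channel_sums(xin, d) / nel
          xc <- .scale_shift(xin, d, rep(1, d[3]), -mu)
          v <- .channel_sums(xc * xc, d) / nel
          mom <- 0.03
          B[[op$rm]] <- (1 - mom) * B[[op$rm]] + mom * mu
          B[[op$rv]] <- (1 - mom) * B[[op$rv]] + mom * v * nel / max(nel - 1, 1)
        } else {
          mu <- B[[op$rm]]; v <- B[[op$rv]]
        }
        invstd <- 1 / sqrt(v + 1e-5)
        xhat <- .scale_shift(xin, d, invstd, -mu * invstd)
        aux[[i]] <- list(xhat = xhat, invstd = invstd)
        .scale_shift(xhat, d, P[[op$gamma]], P[[op$beta]])
      },
      silu = .silu_fw(vals[[op$ins]]),
      add = vals[[op$ins[1]]] + vals[[op$ins[2]]],
      concat = {
        parts <- vals[op$ins]
        concat_channels(parts)
      },
      slice = {
        xin <- vals[[op$ins]]
        xin[, , op$from:op$to, , drop = FALSE]
      },
      maxpool = {
        xin <- vals[[op$ins]]
        r <- .maxpool_fw(xin, dim(xin), op$k, op$stride, op$pad)
        aux[[i]] <- r$idx
        r$y
      },
      up2 = {
        xin <- vals[[op$ins]]
        .upsample2_fw(xin, dim(xin))
      },
      mhsa = {
        xin <- vals[[op$ins]]
        r <- mhsa_fw(xin, op)
        aux[[i]] <- r$aux
        r$y
      },
      stop("unknown op ", op$kind))
    vals[[g$ops[[i]]$out]] <- out
  }
  list(vals = vals, aux = aux)
}

# --- backward ---------------------------------------------------------------

#' @noRd
graph_backward <- function(model, fw, grad_out) {
  # grad_out: named-by-buffer list of gradients on output buffers
  g <- model$graph
  P <- g$params
  grads <- vector("list", g$nbuf)
  for (b in names(grad_out)) grads[[as.integer(b)]] <- grad_out[[b]]
  pg <- new.env(parent = emptyenv())
  addg <- function(nm, v) {
    if (is.null(pg[[nm]])) pg[[nm]] <- v else pg[[nm]] <- pg[[nm]] + v
  }
  for (i in rev(seq_along(g$ops))) {
    op <- g$ops[[i]]
    gy <- grads[[op$out]]
    if (is.null(gy)) next
    vals <- fw$vals
    switch(op$kind,
      conv = {
        xin <- vals[[op$ins]]
        r <- .conv2d_bw(xin, dim(xin), P[[op$w]], dim(P[[op$w]]), gy,
                        !is.null(op$b), op$stride, op$pad, op$groups,
                        op$ins != model$input)
        addg(op$w, array(r$gw, dim(P[[op$w]])))
        if (!is.null(op$b)) addg(op$b, as.numeric(r$gb))
        if (!is.null(r$gx)) grads[[op$ins]] <- accum(grads[[op$ins]], r$gx)
      },
      dynconv = {
        xin <- vals[[op$ins]]
        r <- dynconv_bw(xin, P, op, fw$aux[[i]], gy, op$ins != model$input)
        for (nm in names(r$pg)) addg(nm, r$pg[[nm]])
        if (!is.null(r$gx)) grads[[op$ins]] <- accum(grads[[op$ins]], r$gx)
      },
      bn = {
        a <- fw$aux[[i]]
        xhat <- a$xhat; invstd <- a$invstd
        d <- dim(gy); nel <- d[1] * d[2] * d[4]
        ggamma <- .channel_sums(gy * xhat, d)
        gbeta <- .channel_sums(gy, d)
        addg(op$gamma, ggamma); addg(op$beta, gbeta)
        gxh <- .scale_shift(gy, d, P[[op$gamma]], numeric(d[3]))
        mg <- .channel_sums(gxh, d) / nel
        mgx <- .channel_sums(gxh * xhat, d) / nel
        gx <- gxh - .scale_shift(xhat, d, mgx, mg)
        gx <- .scale_shift(gx, d, invstd, numeric(d[3]))
        grads[[op$ins]] <- accum(grads[[op$ins]], gx)
      },
      silu = {
        xin <- vals[[op$ins]]
        grads[[op$ins]] <- accum(grads[[op$ins]], .silu_bw(xin, gy))
      },
      add = {
        grads[[op$ins[1]]] <- accum(grads[[op$ins[1]]], gy)
        grads[[op$ins[2]]] <- accum(grads[[op$ins[2]]], gy)
      },
      concat = {
        off <- 0L
        for (b in op$ins) {
          cb <- dim(vals[[b]])[3]
          grads[[b]] <- accum(grads[[b]], gy[, , (off + 1L):(off + cb), , drop = FALSE])
          off <- off + cb
        }
      },
      slice = {
        xin <- vals[[op$ins]]
        gx <- array(0, dim(xin))
        gx[, , op$from:op$to, ] <- gy
        grads[[op$ins]] <- accum(grads[[op$ins]], gx)
      },
      maxpool = {
        xin <- vals[[op$ins]]
        gx <- .maxpool_bw(gy, fw$aux[[i]], dim(xin))
        grads[[op$ins]] <- accum(grads[[op$ins]], gx)
      },
      up2 = {
        gx <- .upsample2_bw(gy, dim(gy))
        grads[[op$ins]] <- accum(grads[[op$ins]], gx)
      },
      mhsa = {
        gx <- mhsa_bw(fw$vals[[op$ins]], op, fw$aux[[i]], gy)
        grads[[op$ins]] <- accum(grads[[op$ins]], gx)
      })
    grads[[op$out]] <- NULL  # free
  }
  pg
}

accum <- function(a, b) if (is.null(a)) b else a + b

# channel helpers for (H,W,C,N) arrays ---------------------------------------

sweep_channels <- function(x, v, fun) {
  d <- dim(x)
  vv <- rep(rep(v, each = d[1] * d[2]), d[4])
  y <- switch(fun, "-" = x - vv, "*" = x * vv, "+" = x + vv)
  dim(y) <- d
  y
}

channel_sums <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  s <- colSums(m)
  as.numeric(rowSums(matrix(s, nrow = d[3])))
}

channel_means <- function(x) {
  d <- dim(x)
  channel_sums(x) / (d[1] * d[2] * d[4])
}

concat_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (p in parts) {
    cb <- dim(p)[3]
    out[, , (off + 1L):(off + cb), ] <- p
    off <- off + cb
  }
  out
}
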