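# ---------------------------------------------------------------------------
# Masked generative feature distillation.
#
# A random spatial mask zeroes a fraction lambda of the student's feature-map
# positions at each distillation layer; a small generation network (1x1
# channel alignment where needed, then 3x3 conv -> ReLU -> 3x3 conv) must
# regenerate the frozen teacher's features from the masked student features.
# The squared regeneration error, weighted by alpha, is added to the task
# loss. Forcing generation (rather than imitation) makes the student encode
# enough context to reconstruct its teacher.
# ---------------------------------------------------------------------------

#' Distillation configuration
#'
#' @param lambda spatial mask ratio in [0,1]: the probability that a feature
#'   position is zeroed before regeneration. Default 0.65, the customary
#'   detection setting for this distillation family.
#' @param alpha non-negative weight blending the distillation term into the
#'   task loss (`L = L_task + alpha * L_distill`). Default 2e-5.
#' @param layers character vector of distillation layers (default: the neck
#'   output feeding each active head scale).
#' @param seed mask seed.
#' @return object of class `distill_config`.
#' @export
distill_config <- function(lambda = 0.65, alpha = 2e-5, layers = NULL,
                           seed = 0L) {
  stopifnot(lambda >= 0, lambda <= 1, alpha >= 0)
  structure(list(lambda = lambda, alpha = alpha, layers = layers,
                 seed = as.integer(seed)),
            class = "distill_config")
}

#' Random spatial feature mask
#'
#' Entries are 0 with probability `lambda` (independently per position) and 1
#' otherwise; the mask is broadcast over channels by the caller.
#'
#' @param shape `c(H, W)`.
#' @param lambda mask ratio in [0,1].
#' @param seed integer seed (same seed, same mask).
#' @return H x W 0/1 matrix.
#' @export
random_feature_mask <- function(shape, lambda, seed = 0L) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  r <- local_runif(prod(shape[1:2]), 0, 1, seed = seed)
  matrix(as.numeric(r >= lambda), shape[1], shape[2])
}

# Build the per-layer alignment + generation parameters for a
# student/teacher pair (channel counts per distillation layer).
make_distiller <- function(cs, ct, seed = 0L) {
  stopifnot(length(cs) == length(ct))
  P <- new.env(parent = emptyenv())
  for (i in seq_along(cs)) {
    pre <- paste0("dl", i)
    if (cs[i] != ct[i]) {
      a <- array(local_rnorm((cs[i]) * ct[i], 0, 1 / sqrt(cs[i]),
                             seed = sub_seed(seed, i, 1)),
                 c(1, 1, cs[i], ct[i]))
      assign(paste0(pre, ".align.w"), a, envir = P)
    }
    w1 <- array(local_rnorm(9 * ct[i] * ct[i], 0, sqrt(2 / (9 * ct[i])),
                            seed = sub_seed(seed, i, 2)),
                c(3, 3, ct[i], ct[i]))
    w2 <- array(local_rnorm(9 * ct[i] * ct[i], 0, sqrt(2 / (9 * ct[i])),
                            seed = sub_seed(seed, i, 3)),
                c(3, 3, ct[i], ct[i]))
    assign(paste0(pre, ".g1.w"), w1, envir = P)
    assign(paste0(pre, ".g2.w"), w2, envir = P)
  }
  structure(list(params = P, n_layers = length(cs), cs = cs, ct = ct),
            class = "distiller")
}

#' Generation network: conv -> ReLU -> conv
#'
#' Applies the two 3x3 convolutions (channel-preserving, padding 1) with a
#' ReLU between, as used to regenerate teacher features from masked student
#' features.
#'
#' @param x input array `(H, W, C, N)`.
#' @param w1,w2 conv kernels `(3, 3, C, C)`.
#' @return array of the same spatial size.
#' @export
generation_network <- function(x, w1, w2) {
  stopifnot(dim(x)[3] == dim(w1)[3])
  p1 <- (dim(w1)[1] - 1L) %/% 2L
  p2 <- (dim(w2)[1] - 1L) %/% 2L
  z1 <- .conv2d_fw(x, dim(x), w1, dim(w1), NULL, 1L, p1, 1L)
  r1 <- pmax(z1, 0)
  .conv2d_fw(r1, dim(r1), w2, dim(w2), NULL, 1L, p2, 1L)
}

#' Masked generative distillation loss
#'
#' Sum over layers, channels and positions of the squared difference between
#' the teacher features and the features regenerated from the masked,
#' aligned student features:
#' `sum_l sum_k,i,j (T - G(f_align(S * M)))^2`.
#'
#' @param student list of student feature maps `(H, W, Cs, N)` per layer.
#' @param teacher list of teacher feature maps `(H, W, Ct, N)` per layer.
#' @param masks list of H x W 0/1 masks per layer (broadcast over channels
#'   and batch; see [random_feature_mask()]).
#' @param distiller a distiller created for the channel pair (internal
#'   constructor `make_distiller`).
#' @param need_grad also return gradients (on student maps and distiller
#'   parameters).
#' @return list: `loss`, and when `need_grad` `gs` (per-layer student-map
#'   gradients) and `pg` (distiller parameter gradients).
#' @export
mgd_loss <- function(student, teacher, masks, distiller, need_grad = FALSE) {
  stopifnot(length(student) == distiller$n_layers,
            length(teacher) == distiller$n_layers,
            length(masks) == distiller$n_layers)
  P <- distiller$params
  loss <- 0
  gs <- vector("list", distiller$n_layers)
  pg <- list()
  for (l in seq_len(distiller$n_layers)) {
    S <- student[[l]]; T <- teacher[[l]]; m <- masks[[l]]
    if (any(dim(S)[1:2] != dim(m)) || any(dim(S)[1:2] != dim(T)[1:2]))
      stop("shape mismatch at distillation layer ", l)
    pre <- paste0("dl", l)
    an <- paste0(pre, ".align.w")
    d <- dim(S)
    mm <- array(rep(as.numeric(m), d[3] * d[4]), d)
    Sm <- S * mm
    A <- if (!is.null(P[[an]]))
      .conv2d_fw(Sm, dim(Sm), P[[an]], dim(P[[an]]), NULL, 1L, 0L, 1L)
    else Sm
    w1 <- P[[paste0(pre, ".g1.w")]]; w2 <- P[[paste0(pre, ".g2.w")]]
    p1 <- (dim(w1)[1] - 1L) %/% 2L; p2k <- (dim(w2)[1] - 1L) %/% 2L
    z1 <- .conv2d_fw(A, dim(A), w1, dim(w1), NULL, 1L, p1, 1L)
    r1 <- pmax(z1, 0)
    G <- .conv2d_fw(r1, dim(r1), w2, dim(w2), NULL, 1L, p2k, 1L)
    diff <- G - T
    loss <- loss + sum(diff * diff)
    if (need_grad) {
      gG <- 2 * diff
      b2 <- .conv2d_bw(r1, dim(r1), w2, dim(w2), gG, FALSE, 1L, p2k, 1L, TRUE)
      gr1 <- b2$gx * (z1 > 0)
      b1 <- .conv2d_bw(A, dim(A), w1, dim(w1), gr1, FALSE, 1L, p1, 1L, TRUE)
      pg[[paste0(pre, ".g2.w")]] <- array(b2$gw, dim(w2))
      pg[[paste0(pre, ".g1.w")]] <- array(b1$gw, dim(w1))
      gA <- b1$gx
      if (!is.null(P[[an]])) {
        ba <- .conv2d_bw(Sm, dim(Sm), P[[an]], dim(P[[an]]), gA, FALSE,
                         1L, 0L, 1L, TRUE)
        pg[[an]] <- array(ba$gw, dim(P[[an]]))
        gSm <- ba$gx
      } else gSm <- gA
      gs[[l]] <- gSm * mm
    }
  }
  out <- list(loss = loss)
  if (need_grad) { out$gs <- gs; out$pg <- pg }
  out
}

#' Blend task and distillation losses
#'
#' `L_all = L_task + alpha * L_distill`.
#' @param task_loss,distill_loss finite scalars.
#' @param alpha non-negative blend weight.
#' @export
total_loss <- function(task_loss, distill_loss, alpha) {
  stopifnot(is.finite(task_loss), is.finite(distill_loss), alpha >= 0)
  task_loss + alpha * distill_loss
}

# checksum of all parameters of a model (frozen-teacher contract)
param_checksum <- function(model) {
  P <- model$graph$params
  s <- 0
  for (nm in sort(ls(P))) s <- s + sum(P[[nm]]) + length(P[[nm]])
  s
}
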