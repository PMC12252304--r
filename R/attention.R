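# Spatial multi-head self-attention used in the stride-32 attention block.
#
# The op consumes a qkv feature map whose channels are grouped per head as
# [query (kd) | key (kd) | value (hd)] and emits the attended value map.
# Softmax is taken over key positions; scale = kd^-0.5.

mhsa_fw <- function(x, op) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  nh <- op$nh; kd <- op$kd; C <- op$c
  hd <- C %/% nh
  P <- H * W
  scale <- 1 / sqrt(kd)
  y <- array(0, c(H, W, C, N))
  aux <- vector("list", N)
  per_head <- 2L * kd + hd
  for (n in seq_len(N)) {
    haux <- vector("list", nh)
    for (h in seq_len(nh)) {
      off <- (h - 1L) * per_head
      q <- t(matrix(x[, , off + seq_len(kd), n], nrow = P))            # kd x P
      k <- t(matrix(x[, , off + kd + seq_len(kd), n], nrow = P))       # kd x P
      v <- t(matrix(x[, , off + 2L * kd + seq_len(hd), n], nrow = P))  # hd x P
      A <- crossprod(q, k) * scale                                     # P x P
      A <- A - apply(A, 1, max)
      S <- exp(A); S <- S / rowSums(S)
      O <- v %*% t(S)                                                  # hd x P
      y[, , (h - 1L) * hd + seq_len(hd), n] <- array(t(O), c(H, W, hd))
      haux[[h]] <- list(q = q, k = k, v = v, S = S)
    }
    aux[[n]] <- haux
  }
  list(y = y, aux = aux)
}

mhsa_bw <- function(x, op, aux, gy) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  nh <- op$nh; kd <- op$kd; C <- op$c
  hd <- C %/% nh
  P <- H * W
  scale <- 1 / sqrt(kd)
  gx <- array(0, d)
  per_head <- 2L * kd + hd
  for (n in seq_len(N)) {
    for (h in seq_len(nh)) {
      a <- aux[[n]][[h]]
      gO <- t(matrix(gy[, , (h - 1L) * hd + seq_len(hd), n], nrow = P))  # hd x P
      gV <- gO %*% a$S                                                   # hd x P
      gS <- crossprod(gO, a$v)                                           # P x P
      gA <- (gS - rowSums(gS * a$S)) * a$S
      gQ <- scale * (a$k %*% t(gA))                                      # kd x P
      gK <- scale * (a$q %*% gA)                                         # kd x P
      off <- (h - 1L) * per_head
      gx[, , off + seq_len(kd), n] <- array(t(gQ), c(H, W, kd))
      gx[, , off + kd + seq_len(kd), n] <- array(t(gK), c(H, W, kd))
      gx[, , off + 2L * kd + seq_len(hd), n] <- array(t(gV), c(H, W, hd))
    }
  }
  gx
}
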