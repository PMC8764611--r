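# Network primitives operating on activation arrays of dim (H, W, N, C).
# Forward functions return the output plus whatever the matching backward
# pass needs; backward functions return input gradients and parameter
# gradients in the same nesting as the parameters.

conv_fwd <- function(x, p, stride, pad) {
  conv2d_fwd_cpp(x, p$w, p$b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, p, dout, stride, pad) {
  conv2d_bwd_cpp(x, p$w, dout, as.integer(stride), as.integer(pad))
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# Fused BN -> ReLU (compiled). Training mode uses batch statistics and
# returns updated running statistics; inference mode uses the running ones.
bnrelu_fwd <- function(x, p, state, training) {
  bnrelu_fwd_cpp(x, p$gamma, p$beta, state$mean, state$var,
                 BN_MOMENTUM, BN_EPS, training)
}

bnrelu_bwd <- function(dr, x, r, mu, invsd, p) {
  bnrelu_bwd_cpp(dr, x, r, mu, invsd, p$gamma)
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)  # (2H, 2W, N, C)
  a <- dout
  dim(a) <- c(2, d[1] / 2, d[2], d[3], d[4])
  a <- a[1, , , , , drop = TRUE] + a[2, , , , , drop = TRUE]
  dim(a) <- c(d[1] / 2, 2, d[2] / 2, d[3], d[4])
  a <- a[, 1, , , , drop = TRUE] + a[, 2, , , , drop = TRUE]
  dim(a) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  a
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

split_channels_bwd <- function(dout, c1) {
  d <- dim(dout)
  list(da = dout[, , , seq_len(c1), drop = FALSE],
       db = dout[, , , (c1 + 1):d[4], drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- residual unit ---------------------------------------------------------
# Pre-activation residual unit: [BN -> ReLU -> conv] x convs on the main
# path; shortcut is the identity, or a 1x1 projection convolution (with the
# block's stride) whenever the channel count or spatial size changes. The
# first conv carries the block's stride; all later convs have stride 1.

res_block_fwd <- function(x, p, state, stride, k, training) {
  cur <- x
  caches <- vector("list", length(p$convs))
  for (j in seq_along(p$convs)) {
    cp <- p$convs[[j]]
    bn <- bnrelu_fwd(cur, cp$bn, state$convs[[j]], training)
    if (training)
      state$convs[[j]] <- list(mean = bn$rmean, var = bn$rvar)
    s_j <- if (j == 1) stride else 1
    out <- conv_fwd(bn$r, cp, s_j, pad = (k - 1) %/% 2)
    if (training)
      caches[[j]] <- list(x = cur, r = bn$r, mu = bn$mu, invsd = bn$invsd)
    cur <- out
  }
  if (!is.null(p$proj)) short <- conv_fwd(x, p$proj, stride, pad = 0)
  else short <- x
  list(out = cur + short,
       cache = if (training) list(convs = caches, x = x) else NULL,
       state = state)
}

res_block_bwd <- function(dout, p, cache, stride, k) {
  g <- list(convs = vector("list", length(p$convs)))
  dcur <- dout
  for (j in rev(seq_along(p$convs))) {
    cp <- p$convs[[j]]; cc <- cache$convs[[j]]
    s_j <- if (j == 1) stride else 1
    cb <- conv_bwd(cc$r, cp, dcur, s_j, pad = (k - 1) %/% 2)
    bb <- bnrelu_bwd(cb$dx, cc$x, cc$r, cc$mu, cc$invsd, cp$bn)
    g$convs[[j]] <- list(bn = list(gamma = bb$dgamma, beta = bb$dbeta),
                         w = cb$dw, b = cb$db)
    dcur <- bb$dx
  }
  if (!is.null(p$proj)) {
    pb <- conv_bwd(cache$x, p$proj, dout, stride, pad = 0)
    g$proj <- list(w = pb$dw, b = pb$db)
    dx <- dcur + pb$dx
  } else {
    dx <- dcur + dout
  }
  list(dx = dx, grads = g)
}

# --- parameter tree utilities ---------------------------------------------

tree_zip <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]]))
    do.call(Map, c(list(function(...) tree_zip(f, ...)), trees))
  else do.call(f, trees)
}

tree_count <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_count, numeric(1)))
  else length(tree)
}
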