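# Minimal neural-network toolkit with hand-derived backprop. Activations
# flow as "flat" matrices (n_vectors x feat); sequence structure is imposed
# only at the recurrent and attention layers via 3-d arrays. Recurrent-cell
# and attention kernels live in src/kernels.cpp.

# ---- parameter trees ------------------------------------------------------

tree_flatten <- function(x) {
  if (!is.list(x)) return(list(x))
  do.call(c, lapply(x, tree_flatten))
}

tree_unflatten <- function(skeleton, leaves) {
  i <- 0L
  rec <- function(s) {
    if (!is.list(s)) {
      i <<- i + 1L
      return(leaves[[i]])
    }
    lapply(s, rec)
  }
  rec(skeleton)
}

tree_n_params <- function(x) {
  sum(vapply(tree_flatten(x), length, numeric(1)))
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nr, nc, fan_in = nr) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

init_vec <- function(n) numeric(n)

# ---- elementary layers ----------------------------------------------------

linear_fwd <- function(x, p) {
  list(out = sweep(x %*% p$W, 2L, p$b, `+`), x = x)
}

linear_bwd <- function(dout, cache, p) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

ln_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(sweep(xhat, 2L, p$g, `*`), 2L, p$b, `+`)
  list(out = out, xhat = xhat, istd = istd)
}

ln_bwd <- function(dout, cache, p) {
  Fdim <- ncol(dout)
  dxhat <- sweep(dout, 2L, p$g, `*`)
  xhat <- cache$xhat
  # standard layer-norm backward over the feature dimension
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$istd
  list(dx = dx,
       grads = list(g = colSums(dout * xhat), b = colSums(dout)))
}

# ---- bidirectional multi-layer recurrent stack ---------------------------
# Flat layout everywhere: row = b + (t - 1) * n_batch, so time step t is the
# contiguous row block (t-1)*n_batch + 1 .. t*n_batch.
# p$layers[[l]]$f / $b : list(Wx, Uh, bias); type in {"gru","lstm","rnn"}

# row permutation that reverses time order within each sequence
rev_time_rows <- function(n_batch, n_time) {
  as.vector(outer(seq_len(n_batch), (rev(seq_len(n_time)) - 1L) * n_batch,
                  `+`))
}

cell_fwd <- function(type, x, n_batch, w) {
  switch(type,
         gru = gru_fwd(x, n_batch, w$Wx, w$Uh, w$bias),
         lstm = lstm_fwd(x, n_batch, w$Wx, w$Uh, w$bias),
         rnn = rnn_fwd(x, n_batch, w$Wx, w$Uh, w$bias))
}

cell_bwd <- function(type, x, n_batch, w, cache, dh) {
  switch(type,
         gru = gru_bwd(x, n_batch, w$Wx, w$Uh, cache, dh),
         lstm = lstm_bwd(x, n_batch, w$Wx, w$Uh, cache, dh),
         rnn = rnn_bwd(x, n_batch, w$Wx, w$Uh, cache, dh))
}

init_cell <- function(type, n_in, n_hidden) {
  mult <- switch(type, gru = 3L, lstm = 4L, rnn = 1L)
  list(Wx = init_mat(n_in, mult * n_hidden, fan_in = n_in),
       Uh = init_mat(n_hidden, mult * n_hidden, fan_in = n_hidden),
       bias = init_vec(mult * n_hidden))
}

init_birnn <- function(type, n_in, n_hidden, depth) {
  layers <- vector("list", depth)
  for (l in seq_len(depth)) {
    nin <- if (l == 1L) n_in else 2L * n_hidden
    layers[[l]] <- list(f = init_cell(type, nin, n_hidden),
                        b = init_cell(type, nin, n_hidden))
  }
  list(layers = layers)
}

birnn_fwd <- function(x, n_batch, n_time, p, type) {
  rv <- rev_time_rows(n_batch, n_time)
  caches <- vector("list", length(p$layers))
  for (l in seq_along(p$layers)) {
    w <- p$layers[[l]]
    xr <- x[rv, , drop = FALSE]
    cf <- cell_fwd(type, x, n_batch, w$f)
    cb <- cell_fwd(type, xr, n_batch, w$b)
    caches[[l]] <- list(x = x, xr = xr, cf = cf, cb = cb)
    x <- cbind(cf$h, cb$h[rv, , drop = FALSE])
  }
  list(out = x, caches = caches)
}

birnn_bwd <- function(dout, n_batch, n_time, p, type, caches) {
  rv <- rev_time_rows(n_batch, n_time)
  gl <- vector("list", length(p$layers))
  for (l in rev(seq_along(p$layers))) {
    w <- p$layers[[l]]
    cc <- caches[[l]]
    H <- ncol(cc$cf$h)
    dhf <- dout[, seq_len(H), drop = FALSE]
    dhb <- dout[rv, H + seq_len(H), drop = FALSE]
    bf <- cell_bwd(type, cc$x, n_batch, w$f, cc$cf, dhf)
    bb <- cell_bwd(type, cc$xr, n_batch, w$b, cc$cb, dhb)
    dout <- bf$dx + bb$dx[rv, , drop = FALSE]
    gl[[l]] <- list(f = list(Wx = bf$dWx, Uh = bf$dUh, bias = as.numeric(bf$db)),
                    b = list(Wx = bb$dWx, Uh = bb$dUh, bias = as.numeric(bb$db)))
  }
  list(dx = dout, grads = list(layers = gl))
}

# ---- multi-head self-attention wrapper -----------------------------------

init_mha <- function(d_model) {
  list(Wq = init_mat(d_model, d_model), Wk = init_mat(d_model, d_model),
       Wv = init_mat(d_model, d_model), Wo = init_mat(d_model, d_model))
}

mha_flat_fwd <- function(x, n_batch, n_time, p, n_heads) {
  r <- mha_fwd(x, n_batch, p$Wq, p$Wk, p$Wv, p$Wo, n_heads)
  list(out = r$out, cache = r, x = x)
}

mha_flat_bwd <- function(dout, n_batch, n_time, p, n_heads, cache) {
  r <- mha_bwd(cache$x, n_batch, p$Wq, p$Wk, p$Wv, p$Wo, n_heads,
               cache$cache, dout)
  list(dx = r$dx,
       grads = list(Wq = r$dWq, Wk = r$dWk, Wv = r$dWv, Wo = r$dWo))
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  leaves <- tree_flatten(params)
  list(m = lapply(leaves, function(p) p * 0),
       v = lapply(leaves, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  p <- tree_flatten(params)
  g <- tree_flatten(grads)
  stopifnot(length(p) == length(g))
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(p)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g[[i]]^2
    p[[i]] <- p[[i]] - lr * (state$m[[i]] / c1) /
      (sqrt(state$v[[i]] / c2) + eps)
  }
  list(params = tree_unflatten(params, p), state = state)
}

sgd_step <- function(params, grads, lr) {
  p <- tree_flatten(params)
  g <- tree_flatten(grads)
  for (i in seq_along(p)) p[[i]] <- p[[i]] - lr * g[[i]]
  tree_unflatten(params, p)
}
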