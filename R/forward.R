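# End-to-end forward/backward of the two-stage beamformer. Sequence
# activations are "interleaved flat" matrices: row = q + (j - 1) * n_seq for
# sequence q and frame j, so chunk gathers, recurrent batching, and batching
# of whole scenes are all plain row indexing. A minibatch of scenes is one
# forward pass: scenes are just additional parallel sequences.

# Index plan for dual-path processing of n_seq parallel sequences.
chunk_plan <- function(n_frames, K, P, n_seq, S_fixed = NULL) {
  if (!is.null(S_fixed)) {
    S <- S_fixed
    padded <- NULL
  } else {
    S <- if (n_frames <= K) 1L else as.integer(ceiling((n_frames - K) / P)) + 1L
    padded <- (S - 1L) * P + K
  }
  n <- n_seq * S * K
  qv <- rep(seq_len(n_seq), times = S * K)
  sv <- rep(rep(seq_len(S), each = n_seq), times = K)
  kv <- rep(seq_len(K), each = n_seq * S)
  row2 <- qv + (kv - 1L) * n_seq + (sv - 1L) * n_seq * K
  to_inter <- integer(n)
  to_inter[row2] <- seq_len(n)
  plan <- list(S = S, K = K, n_seq = n_seq, Bq1 = n_seq * S, Bq2 = n_seq * K,
               to_inter = to_inter, from_inter = row2)
  if (!is.null(padded)) {
    jv <- (sv - 1L) * P + kv
    gidx <- qv + (jv - 1L) * n_seq
    plan$padded <- padded
    plan$gidx <- gidx
    plan$cnt_row <- tabulate(gidx, n_seq * padded)
  }
  plan
}

# ---- one residual path (RNN -> [MSAM] -> FC -> LN -> +x) -----------------

dp_path_fwd <- function(x, n_batch, n_time, pp, config) {
  r <- birnn_fwd(x, n_batch, n_time, pp$rnn, config$rnn_type)
  if (config$use_msam) {
    a <- mha_flat_fwd(r$out, n_batch, n_time, pp$attn, config$n_heads)
  } else {
    a <- list(out = r$out)
  }
  f <- linear_fwd(a$out, pp$fc)
  l <- ln_fwd(f$out, pp$ln)
  list(out = l$out + x, r = r, a = a, f = f, l = l)
}

dp_path_bwd <- function(dout, cache, pp, config, n_batch, n_time) {
  dl <- ln_bwd(dout, cache$l, pp$ln)
  df <- linear_bwd(dl$dx, cache$f, pp$fc)
  if (config$use_msam) {
    da <- mha_flat_bwd(df$dx, n_batch, n_time, pp$attn, config$n_heads,
                       cache$a)
    dr_in <- da$dx
  } else {
    dr_in <- df$dx
  }
  dr <- birnn_bwd(dr_in, n_batch, n_time, pp$rnn, config$rnn_type,
                  cache$r$caches)
  grads <- list(rnn = dr$grads)
  if (config$use_msam) grads$attn <- da$grads
  grads$fc <- df$grads
  grads$ln <- dl$grads
  list(dx = dr$dx + dout, grads = grads)
}

# ---- one dual-path block (intra over K, then inter over S) ---------------

dp_block_fwd <- function(x, plan, bp, config) {
  i1 <- dp_path_fwd(x, plan$Bq1, plan$K, bp$intra, config)
  x2 <- i1$out[plan$to_inter, , drop = FALSE]
  i2 <- dp_path_fwd(x2, plan$Bq2, plan$S, bp$inter, config)
  list(out = i2$out[plan$from_inter, , drop = FALSE], i1 = i1, i2 = i2)
}

dp_block_bwd <- function(dout, cache, plan, bp, config) {
  d2 <- dout[plan$to_inter, , drop = FALSE]
  b2 <- dp_path_bwd(d2, cache$i2, bp$inter, config, plan$Bq2, plan$S)
  d1 <- b2$dx[plan$from_inter, , drop = FALSE]
  b1 <- dp_path_bwd(d1, cache$i1, bp$intra, config, plan$Bq1, plan$K)
  list(dx = b1$dx, grads = list(intra = b1$grads, inter = b2$grads))
}

# ---- one filter-estimation stage -----------------------------------------
# Xin: interleaved (n_seq * n_frames) x (feature_dim + n_lags) inputs
# (embedding already applied by the caller; gradients for the encoder D are
# assembled there from dXin).

stage_fwd <- function(sp, Xin, n_seq, n_frames, config) {
  plan <- chunk_plan(n_frames, config$chunk_len, config$chunk_hop, n_seq)
  nv <- n_seq * n_frames
  proj <- linear_fwd(Xin, sp$proj)
  Fd <- config$feature_dim
  Xf <- matrix(0, n_seq * plan$padded, Fd)
  Xf[seq_len(nv), ] <- proj$out
  x <- Xf[plan$gidx, , drop = FALSE]
  bcaches <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    bc <- dp_block_fwd(x, plan, sp$blocks[[b]], config)
    bcaches[[b]] <- bc
    x <- bc$out
  }
  merged <- rowsum(x, plan$gidx) / plan$cnt_row
  Zf <- merged[seq_len(nv), , drop = FALSE]
  A <- linear_fwd(Zf, sp$out_tanh)
  G <- linear_fwd(Zf, sp$out_gate)
  th <- tanh(A$out)
  sg <- 1 / (1 + exp(-G$out))
  list(filters = th * sg, plan = plan, proj = proj, bcaches = bcaches,
       A = A, G = G, th = th, sg = sg, nv = nv)
}

stage_bwd <- function(dfilters, cache, sp, config) {
  plan <- cache$plan
  th <- cache$th; sg <- cache$sg
  dA <- dfilters * sg * (1 - th^2)
  dG <- dfilters * th * sg * (1 - sg)
  bA <- linear_bwd(dA, cache$A, sp$out_tanh)
  bG <- linear_bwd(dG, cache$G, sp$out_gate)
  dZf <- bA$dx + bG$dx
  Fd <- config$feature_dim
  dmerged <- matrix(0, plan$n_seq * plan$padded, Fd)
  dmerged[seq_len(cache$nv), ] <- dZf
  dx <- (dmerged / plan$cnt_row)[plan$gidx, , drop = FALSE]
  gblocks <- vector("list", config$n_blocks)
  for (b in rev(seq_len(config$n_blocks))) {
    bb <- dp_block_bwd(dx, cache$bcaches[[b]], plan, sp$blocks[[b]], config)
    gblocks[[b]] <- bb$grads
    dx <- bb$dx
  }
  dXf <- rowsum(dx, plan$gidx)
  dZ0 <- dXf[seq_len(cache$nv), , drop = FALSE]
  bproj <- linear_bwd(dZ0, cache$proj, sp$proj)
  list(dXin = bproj$dx,
       grads = list(proj = bproj$grads, blocks = gblocks,
                    out_tanh = bA$grads, out_gate = bG$grads))
}

# ---- scene featurization (fixed per scene; reused across epochs) ---------

# Interleave per-scene frame matrices into one batch matrix:
# big[q + (j - 1) * n_sc, ] = mats[[q]][j, ].
stack_interleave <- function(mats) {
  n_sc <- length(mats)
  if (n_sc == 1L) return(mats[[1]])
  n_frames <- nrow(mats[[1]])
  big <- matrix(0, n_sc * n_frames, ncol(mats[[1]]))
  for (q in seq_len(n_sc)) {
    big[seq(q, by = n_sc, length.out = n_frames), ] <- mats[[q]]
  }
  big
}

scene_rows <- function(q, n_sc, n_frames) {
  seq(q, by = n_sc, length.out = n_frames)
}

# Batch featurization: context windows, center frames and averaged NCC for
# a list of equally sized multi-channel mixtures.
prep_batch_input <- function(mixtures, config) {
  if (!is.list(mixtures)) mixtures <- list(mixtures)
  mats <- lapply(mixtures, function(m) {
    if (inherits(m, "multichannel_recording")) m$samples else m
  })
  N <- nrow(mats[[1]])
  T <- ncol(mats[[1]])
  stopifnot(all(vapply(mats, nrow, 0L) == N),
            all(vapply(mats, ncol, 0L) == T))
  L <- config$frame_len
  M <- max(1L, L %/% 2L)
  cl <- config$context_len
  n_sc <- length(mats)
  CTX <- lapply(seq_len(N), function(i) {
    stack_interleave(lapply(mats, function(x) context_matrix(x[i, ], L, M, cl)))
  })
  n_frames <- nrow(CTX[[1]]) / n_sc
  ncc_avg <- NULL
  if (N >= 2L) {
    nccs <- lapply(2:N, function(i) {
      ncc_matrix(CTX[[1]], CTX[[i]][, cl + seq_len(L), drop = FALSE])
    })
    ncc_avg <- Reduce(`+`, nccs) / (N - 1L)
  }
  inp <- list(CTX = CTX, ncc_avg = ncc_avg, N = N, T = T,
              n_sc = n_sc, n_frames = as.integer(n_frames), L = L, M = M,
              context_len = cl, ola = ola_index(as.integer(n_frames), L, M))
  inp
}

# center frames of channel i (the L-sample frame proper inside each context)
inp_frames <- function(inp, i) {
  inp$CTX[[i]][, inp$context_len + seq_len(inp$L), drop = FALSE]
}

# single-scene convenience wrapper (exported ops, tests)
prep_scene_input <- function(mixture, config) {
  prep_batch_input(list(mixture), config)
}

# ---- full model forward / backward ---------------------------------------

# `fixed_cue`: optional list (per stage-2 pair) of precomputed cue NCC
# matrices. Training treats the cue as detached from the graph; supplying a
# frozen cue makes the analytic gradient exact for verification.
# `active_sources`: which output streams to beamform (default all). The
# gated output always yields every stream's filters in one product, but the
# per-stream convolutions and stage-2 passes are run only for active
# streams; training uses this to touch only supervised streams.
forward_full <- function(weights, inp, config, fixed_cue = NULL,
                         active_sources = NULL) {
  N <- inp$N
  C <- config$n_sources
  if (is.null(active_sources)) active_sources <- seq_len(C)
  nl <- n_lags_of(config)
  L <- inp$L
  n_sc <- inp$n_sc
  n_frames <- inp$n_frames
  emb1 <- inp_frames(inp, 1L) %*% weights$stage1$D
  s1 <- stage_fwd(weights$stage1, cbind(emb1, inp$ncc_avg), n_sc, n_frames,
                  config)
  y1 <- vector("list", C)
  for (cc in active_sources) {
    f1 <- s1$filters[, (cc - 1L) * nl + seq_len(nl), drop = FALSE]
    y1[[cc]] <- frame_corr_fwd(f1, inp$CTX[[1]], L)
  }
  yframes <- y1
  s2 <- NULL
  pair_i <- pair_c <- integer(0)
  rows_pair <- NULL
  if (N >= 2L) {
    pair_i <- rep(2:N, times = length(active_sources))
    pair_c <- rep(active_sources, each = N - 1L)
    n_pairs <- length(pair_i)
    n_seq2 <- n_sc * n_pairs
    rows_pair <- lapply(seq_len(n_pairs), function(p) {
      as.vector(outer(seq_len(n_sc) + (p - 1L) * n_sc,
                      (seq_len(n_frames) - 1L) * n_seq2, `+`))
    })
    emb2 <- lapply(2:N, function(i) inp_frames(inp, i) %*% weights$stage2$D)
    Xin2 <- matrix(0, n_seq2 * n_frames, config$feature_dim + nl)
    for (p in seq_len(n_pairs)) {
      i <- pair_i[p]; cc <- pair_c[p]
      ncc2 <- if (is.null(fixed_cue)) ncc_matrix(inp$CTX[[i]], y1[[cc]]) else
        fixed_cue[[p]]
      Xin2[rows_pair[[p]], ] <- cbind(emb2[[i - 1L]], ncc2)
    }
    s2 <- stage_fwd(weights$stage2, Xin2, n_seq2, n_frames, config)
    for (p in seq_len(n_pairs)) {
      i <- pair_i[p]; cc <- pair_c[p]
      f2 <- s2$filters[rows_pair[[p]], (cc - 1L) * nl + seq_len(nl),
                       drop = FALSE]
      yframes[[cc]] <- yframes[[cc]] + frame_corr_fwd(f2, inp$CTX[[i]], L)
    }
  }
  sources <- vector("list", n_sc)
  for (q in seq_len(n_sc)) {
    src <- matrix(0, C, inp$T)
    rw <- scene_rows(q, n_sc, n_frames)
    for (cc in active_sources) {
      src[cc, ] <- overlap_add(yframes[[cc]][rw, , drop = FALSE],
                               M = inp$M, source_length = inp$T)
    }
    sources[[q]] <- src
  }
  list(sources = sources, y1 = y1, yframes = yframes, s1 = s1, s2 = s2,
       pair_i = pair_i, pair_c = pair_c, rows_pair = rows_pair,
       active_sources = active_sources)
}

# dsources: list (per scene) of C x T matrices of loss gradients w.r.t. the
# output waveforms. The stage-2 cue NCC is treated as detached: gradients
# reach stage 1 only through the additive reference-estimate term.
backward_full <- function(weights, inp, config, fwd, dsources) {
  N <- inp$N
  C <- config$n_sources
  nl <- n_lags_of(config)
  L <- inp$L
  n_sc <- inp$n_sc
  n_frames <- inp$n_frames
  cnt <- inp$ola$count
  idx <- inp$ola$idx
  pad_to <- length(cnt)
  active <- fwd$active_sources
  dframes <- vector("list", C)
  for (cc in active) {
    big <- matrix(0, n_sc * n_frames, L)
    for (q in seq_len(n_sc)) {
      dy_ext <- numeric(pad_to)
      dy_ext[seq_len(inp$T)] <- dsources[[q]][cc, ] / cnt[seq_len(inp$T)]
      big[scene_rows(q, n_sc, n_frames), ] <- dy_ext[idx]
    }
    dframes[[cc]] <- big
  }
  out <- list()
  if (N >= 2L) {
    n_pairs <- length(fwd$pair_i)
    n_seq2 <- n_sc * n_pairs
    dfilt2 <- matrix(0, n_seq2 * n_frames, C * nl)
    for (p in seq_len(n_pairs)) {
      i <- fwd$pair_i[p]; cc <- fwd$pair_c[p]
      dfilt2[fwd$rows_pair[[p]], (cc - 1L) * nl + seq_len(nl)] <-
        frame_corr_bwd(dframes[[cc]], inp$CTX[[i]], nl)
    }
    s2b <- stage_bwd(dfilt2, fwd$s2, weights$stage2, config)
    dD2 <- matrix(0, L, config$feature_dim)
    for (p in seq_len(n_pairs)) {
      i <- fwd$pair_i[p]
      demb <- s2b$dXin[fwd$rows_pair[[p]], seq_len(config$feature_dim),
                       drop = FALSE]
      dD2 <- dD2 + crossprod(inp_frames(inp, i), demb)
    }
    out$stage2 <- c(list(D = dD2), s2b$grads)
  }
  # direct residual path of the final sum: d y1 = d yframes
  dfilt1 <- matrix(0, n_sc * n_frames, C * nl)
  for (cc in active) {
    dfilt1[, (cc - 1L) * nl + seq_len(nl)] <-
      frame_corr_bwd(dframes[[cc]], inp$CTX[[1]], nl)
  }
  s1b <- stage_bwd(dfilt1, fwd$s1, weights$stage1, config)
  demb1 <- s1b$dXin[, seq_len(config$feature_dim), drop = FALSE]
  dD1 <- crossprod(inp_frames(inp, 1L), demb1)
  res <- list(stage1 = c(list(D = dD1), s1b$grads))
  if (N >= 2L) res$stage2 <- out$stage2
  res
}

# ---- training loss --------------------------------------------------------
# negative SI-SNR with analytic gradient; smooth (uncapped) form.

loss_neg_sisnr <- function(est, ref) {
  e <- est - mean(est)
  r <- ref - mean(ref)
  rr <- sum(r^2)
  al <- sum(e * r) / rr
  s <- al * r
  err <- e - s
  ssq <- sum(s^2)
  esq <- sum(err^2) + 1e-12
  loss <- -10 * log10(ssq / esq)
  k <- 10 / log(10)
  dde <- -k * (2 * al * r / max(ssq, 1e-12) - 2 * err / esq)
  list(loss = loss, grad = dde - mean(dde))
}

#' Separate a multi-channel mixture with MultiSAMS
#'
#' End-to-end inference: framing, frame embedding + NCC features, dual-path
#' filter estimation, stage-1 filter-and-sum on the reference channel,
#' stage-2 filtering of the remaining channels cued by the stage-1
#' estimate, and overlap-add back to `C` full-length waveforms. Band-pass
#' conditioning is the caller's choice (see [bandpass_condition()]).
#'
#' @param mixture a [multichannel_recording()] with N >= 2 channels.
#' @param config the [model_config()] matching `weights`.
#' @param weights a `multisams_weights` object ([multisams_init()] or a
#'   trained checkpoint).
#' @return A `separation_result`: list with `sources` (C x T matrix, source
#'   1 is the trained signal stream), `sample_rate_hz` and `config`.
#' @export
multisams_forward <- function(mixture, config, weights) {
  stopifnot(inherits(mixture, "multichannel_recording"))
  if (n_channels(mixture) < 2L) {
    stop("MultiSAMS needs N >= 2 sensor channels", call. = FALSE)
  }
  inp <- prep_scene_input(mixture, config)
  fwd <- forward_full(weights, inp, config)
  structure(list(sources = fwd$sources[[1]],
                 sample_rate_hz = mixture$sample_rate_hz,
                 config = config),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> %d source(s) x %d samples @ %d Hz\n",
              nrow(x$sources), ncol(x$sources), x$sample_rate_hz))
  invisible(x)
}
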