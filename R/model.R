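#' MultiSAMS model configuration
#'
#' Architecture hyperparameters of the two-stage filter-and-sum beamformer.
#' Defaults follow the reference configuration: feature dimension 64,
#' hidden dimension 128 per direction, segment (chunk) size 200, 8 attention
#' heads, GRU cells of depth 4. The attention model dimension is twice the
#' hidden dimension (bidirectional concatenation) and must be divisible by
#' `n_heads`.
#'
#' @param rnn_type recurrent cell: `"gru"`, `"lstm"` or `"rnn"`.
#' @param rnn_depth bidirectional layers per recurrent stack.
#' @param n_blocks number of dual-path blocks B.
#' @param feature_dim bottleneck feature dimension inside the blocks.
#' @param hidden_dim recurrent hidden units per direction.
#' @param chunk_len within-chunk length K. @param chunk_hop chunk stride P
#'   (default `chunk_len/2`).
#' @param n_heads attention heads (default 8).
#' @param n_sources number of output streams C (default 2: signal +
#'   residual).
#' @param frame_len beamforming frame length L in samples.
#' @param context_len context half-span in samples (default `frame_len`,
#'   giving 2L+1 filter taps).
#' @param use_msam include the multi-head self-attention module after each
#'   recurrent stack.
#' @param seed weight-initialization seed.
#' @return A `multisams_config` list.
#' @export
model_config <- function(rnn_type = c("gru", "lstm", "rnn"),
                         rnn_depth = 4L, n_blocks = 4L,
                         feature_dim = 64L, hidden_dim = 128L,
                         chunk_len = 200L, chunk_hop = NULL,
                         n_heads = 8L, n_sources = 2L,
                         frame_len = 64L, context_len = NULL,
                         use_msam = TRUE, seed = 1L) {
  rnn_type <- match.arg(rnn_type)
  if (is.null(chunk_hop)) chunk_hop <- max(1L, chunk_len %/% 2L)
  if (is.null(context_len)) context_len <- frame_len
  cfg <- list(rnn_type = rnn_type, rnn_depth = as.integer(rnn_depth),
              n_blocks = as.integer(n_blocks),
              feature_dim = as.integer(feature_dim),
              hidden_dim = as.integer(hidden_dim),
              chunk_len = as.integer(chunk_len),
              chunk_hop = as.integer(chunk_hop),
              n_heads = as.integer(n_heads),
              n_sources = as.integer(n_sources),
              frame_len = as.integer(frame_len),
              context_len = as.integer(context_len),
              use_msam = isTRUE(use_msam), seed = as.integer(seed))
  stopifnot(cfg$rnn_depth >= 1L, cfg$n_blocks >= 1L, cfg$feature_dim >= 1L,
            cfg$hidden_dim >= 1L, cfg$chunk_len >= cfg$chunk_hop,
            cfg$chunk_hop >= 1L, cfg$n_sources >= 1L, cfg$frame_len >= 1L)
  if ((2L * cfg$hidden_dim) %% cfg$n_heads != 0L) {
    stop("n_heads must divide the attention dimension 2*hidden_dim",
         call. = FALSE)
  }
  structure(cfg, class = "multisams_config")
}

n_lags_of <- function(config) 2L * config$context_len + 1L

# one filter-estimation stage: encoder + input projection + B dual-path
# blocks + gated output producing C filter banks per frame
init_stage <- function(config) {
  K_emb <- config$feature_dim
  Fd <- config$feature_dim
  H <- config$hidden_dim
  nl <- n_lags_of(config)
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    mk_path <- function() {
      p <- list(rnn = init_birnn(config$rnn_type, Fd, H, config$rnn_depth))
      if (config$use_msam) p$attn <- init_mha(2L * H)
      p$fc <- list(W = init_mat(2L * H, Fd), b = init_vec(Fd))
      p$ln <- list(g = rep(1, Fd), b = init_vec(Fd))
      p
    }
    blocks[[b]] <- list(intra = mk_path(), inter = mk_path())
  }
  list(D = init_mat(config$frame_len, K_emb),
       proj = list(W = init_mat(K_emb + nl, Fd), b = init_vec(Fd)),
       blocks = blocks,
       out_tanh = list(W = init_mat(Fd, config$n_sources * nl),
                       b = init_vec(config$n_sources * nl)),
       out_gate = list(W = init_mat(Fd, config$n_sources * nl),
                       b = init_vec(config$n_sources * nl)))
}

#' Initialize MultiSAMS weights
#'
#' Draws all trainable parameters (uniform fan-in scaling) for the two
#' filter-estimation stages from `config$seed`.
#'
#' @param config a [model_config()].
#' @return A `multisams_weights` list with elements `stage1` and `stage2`.
#' @export
multisams_init <- function(config) {
  stopifnot(inherits(config, "multisams_config"))
  restore <- local_rng(config$seed)
  on.exit(restore())
  w <- list(stage1 = init_stage(config), stage2 = init_stage(config))
  attr(w, "config") <- config
  class(w) <- "multisams_weights"
  w
}

#' Count trainable parameters
#'
#' @param weights a `multisams_weights` object (or any parameter tree).
#' @return integer number of trainable scalars.
#' @export
multisams_parameter_count <- function(weights) {
  tree_n_params(unclass(weights))
}

# ---- chunk segmentation ---------------------------------------------------

#' Segment a feature sequence into overlapping chunks
#'
#' Splits an `F x n_frames` sequence into chunks of length `K` with stride
#' `P` (zero-padded at the tail), the dual-path decomposition into local
#' (within-chunk) and global (across-chunk) axes.
#'
#' @param seq numeric matrix, features x frames.
#' @param K chunk length. @param P chunk stride, `1 <= P <= K`.
#' @return A 3-d array of dim `(F, K, S)` with attributes `n_frames` and
#'   `P`; `S = ceil((n_frames - K)/P) + 1`.
#' @export
segment_chunks <- function(seq, K, P) {
  stopifnot(is.matrix(seq), K >= 1L, P >= 1L, P <= K)
  n_frames <- ncol(seq)
  S <- if (n_frames <= K) 1L else as.integer(ceiling((n_frames - K) / P)) + 1L
  padded <- (S - 1L) * P + K
  sp <- cbind(seq, matrix(0, nrow(seq), padded - n_frames))
  out <- array(0, c(nrow(seq), K, S))
  for (s in seq_len(S)) {
    out[, , s] <- sp[, (s - 1L) * P + seq_len(K)]
  }
  attr(out, "n_frames") <- n_frames
  attr(out, "P") <- as.integer(P)
  out
}

#' Merge chunks back into a feature sequence
#'
#' Inverse of [segment_chunks()]: overlapping chunk positions are averaged,
#' so `merge_chunks(segment_chunks(x, K, P))` recovers `x` exactly.
#'
#' @param chunks array from [segment_chunks()] (or any `(F, K, S)` array
#'   with the same attributes).
#' @param n_frames,P override the stored attributes if given.
#' @return numeric matrix, features x n_frames.
#' @export
merge_chunks <- function(chunks, n_frames = NULL, P = NULL) {
  if (is.null(n_frames)) n_frames <- attr(chunks, "n_frames")
  if (is.null(P)) P <- attr(chunks, "P")
  stopifnot(!is.null(n_frames), !is.null(P))
  d <- dim(chunks)
  K <- d[2]; S <- d[3]
  padded <- (S - 1L) * P + K
  acc <- matrix(0, d[1], padded)
  cnt <- numeric(padded)
  for (s in seq_len(S)) {
    sl <- (s - 1L) * P + seq_len(K)
    acc[, sl] <- acc[, sl] + chunks[, , s]
    cnt[sl] <- cnt[sl] + 1
  }
  (acc / rep(pmax(cnt, 1), each = d[1]))[, seq_len(n_frames), drop = FALSE]
}

# ---- attention (single-matrix reference surface) -------------------------

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, the attention primitive: each output row
#' is a convex combination of value rows, weighted by query-key similarity.
#'
#' @param Q,K,V numeric matrices; `ncol(Q) == ncol(K)` (= d_k) and
#'   `nrow(K) == nrow(V)`.
#' @return list with `output` (`nrow(Q) x ncol(V)`) and `weights`
#'   (row-stochastic `nrow(Q) x nrow(K)`).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  stopifnot(is.matrix(Q), is.matrix(K), is.matrix(V),
            ncol(Q) == ncol(K), nrow(K) == nrow(V))
  if (ncol(K) == 0L) stop("d_k must be positive", call. = FALSE)
  S <- Q %*% t(K) / sqrt(ncol(K))
  S <- S - apply(S, 1L, max)
  A <- exp(S)
  A <- A / rowSums(A)
  list(output = A %*% V, weights = A)
}

#' Multi-head self-attention
#'
#' Splits `d_model` into `h` heads after learned Q/K/V projections, applies
#' scaled dot-product attention per head, concatenates and projects with
#' `W_o`; shape-preserving.
#'
#' @param X numeric matrix, time x d_model.
#' @param params list with square `d_model x d_model` matrices `Wq`, `Wk`,
#'   `Wv`, `Wo`.
#' @param h number of heads; must divide `d_model`.
#' @return numeric matrix, same shape as `X`.
#' @export
multi_head_attention <- function(X, params, h = 8L) {
  stopifnot(is.matrix(X))
  if (ncol(X) %% h != 0L) {
    stop("h must divide the model dimension", call. = FALSE)
  }
  r <- mha_fwd(X, 1L, params$Wq, params$Wk, params$Wv, params$Wo,
               as.integer(h))
  r$out
}

#' Apply one dual-path block
#'
#' One block of the filter-estimation network: a bidirectional recurrent
#' stack over the within-chunk axis, optionally multi-head self-attention,
#' a fully connected layer restoring the feature dimension, layer norm and
#' a residual connection -- then the same stack over the across-chunk axis.
#' Shape-preserving.
#'
#' @param z a `(F, K, S)` chunk array (see [segment_chunks()]).
#' @param block_params one element of `weights$stage1$blocks`.
#' @param config the [model_config()] the weights were built with.
#' @return array of the same shape and attributes as `z`.
#' @export
dual_path_block <- function(z, block_params, config) {
  d <- dim(z)
  S <- d[3]; K <- d[2]
  flat <- matrix(aperm(z, c(3L, 2L, 1L)), S * K, d[1])
  plan <- chunk_plan(n_frames = NULL, K = K, P = K, n_seq = 1L,
                     S_fixed = S)
  out <- dp_block_fwd(flat, plan, block_params, config)$out
  res <- aperm(array(out, c(S, K, d[1])), c(3L, 2L, 1L))
  attr(res, "n_frames") <- attr(z, "n_frames")
  attr(res, "P") <- attr(z, "P")
  res
}

#' Estimate reference-channel beamforming filters
#'
#' Runs the stage-1 filter-estimation network: the concatenated frame
#' embedding and averaged NCC feature are projected, processed by the
#' dual-path stack, and passed through the gated output
#' `tanh(..) * sigmoid(..)`, whose product is strictly inside (-1, 1).
#'
#' @param emb n_frames x feature_dim embedding matrix ([encode_frames()]).
#' @param ncc n_frames x (2*context_len+1) averaged NCC matrix.
#' @param weights a `multisams_weights` object.
#' @param config the matching [model_config()].
#' @return A `beamforming_filter_set`: array `(n_frames, n_lags, C)` with
#'   attribute `channel = 1`.
#' @export
estimate_filters_reference <- function(emb, ncc, weights, config) {
  sf <- stage_fwd(weights$stage1, cbind(emb, ncc), n_seq = 1L,
                  n_frames = nrow(emb), config = config)
  nl <- n_lags_of(config)
  filt <- array(0, c(nrow(emb), nl, config$n_sources))
  for (cc in seq_len(config$n_sources)) {
    filt[, , cc] <- sf$filters[, (cc - 1L) * nl + seq_len(nl)]
  }
  structure(filt, class = "beamforming_filter_set", channel = 1L)
}

#' Filter-and-sum beamforming
#'
#' Applies per-channel time-domain filters to the channels' context windows
#' by valid sliding correlation and sums across channels:
#' `y[t, j] = sum_i sum_g f_i[t, g] ctx_i[t, g + j]`. With a unit impulse at
#' the center lag the output is the frame itself.
#'
#' @param contexts a single context (vector or n_frames x width matrix) or
#'   a list of them, one per channel.
#' @param filters matching filter(s): vector(s) of length `n_lags` or
#'   n_frames x n_lags matrices.
#' @return beamformed frame(s): length-L vector or n_frames x L matrix,
#'   where `L = width - n_lags + 1`.
#' @export
filter_and_sum <- function(contexts, filters) {
  if (!is.list(contexts)) contexts <- list(contexts)
  if (!is.list(filters)) filters <- list(filters)
  stopifnot(length(contexts) == length(filters), length(contexts) >= 1L)
  as_mat <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1L)
  vec_in <- !is.matrix(contexts[[1]])
  out <- NULL
  for (i in seq_along(contexts)) {
    ctx <- as_mat(if (inherits(contexts[[i]], "context_frame"))
      contexts[[i]]$values else contexts[[i]])
    f <- as_mat(filters[[i]])
    L <- ncol(ctx) - ncol(f) + 1L
    if (L < 1L || nrow(ctx) != nrow(f)) {
      stop("filter/context length mismatch", call. = FALSE)
    }
    y <- frame_corr_fwd(f, ctx, L)
    out <- if (is.null(out)) y else out + y
  }
  if (vec_in) drop(out) else out
}

#' Estimate second-stage filters from the reference estimate
#'
#' The stage-1 estimate for a source is used as the cue: its NCC with each
#' remaining channel's context window replaces the inter-channel feature,
#' and the shared stage-2 network estimates one filter bank per remaining
#' channel for that source.
#'
#' @param other_contexts list of context matrices (n_frames x width), one
#'   per channel 2..N.
#' @param ref_estimate n_frames x L matrix of stage-1 beamformed frames for
#'   one source.
#' @param weights a `multisams_weights` object.
#' @param config the matching [model_config()].
#' @param source which source's filter bank of the gated output to return.
#' @return A `beamforming_filter_set` array `(n_frames, n_lags, n_other)`
#'   with attribute `channels = 2..N`.
#' @export
second_stage_filters <- function(other_contexts, ref_estimate, weights,
                                 config, source = 1L) {
  stopifnot(is.list(other_contexts), length(other_contexts) >= 1L)
  n_other <- length(other_contexts)
  n_frames <- nrow(ref_estimate)
  L <- config$frame_len
  nl <- n_lags_of(config)
  # interleaved input rows: sequence q varies fastest, then frame
  Xin <- matrix(0, n_other * n_frames, config$feature_dim + nl)
  for (q in seq_len(n_other)) {
    ctx <- other_contexts[[q]]
    fr <- ctx[, config$context_len + seq_len(L), drop = FALSE]
    emb <- fr %*% weights$stage2$D
    ncc <- ncc_matrix(ctx, ref_estimate)
    rows <- q + (seq_len(n_frames) - 1L) * n_other
    Xin[rows, ] <- cbind(emb, ncc)
  }
  sf <- stage_fwd(weights$stage2, Xin, n_seq = n_other,
                  n_frames = n_frames, config = config)
  filt <- array(0, c(n_frames, nl, n_other))
  cols <- (source - 1L) * nl + seq_len(nl)
  for (q in seq_len(n_other)) {
    rows <- q + (seq_len(n_frames) - 1L) * n_other
    filt[, , q] <- sf$filters[rows, cols]
  }
  structure(filt, class = "beamforming_filter_set",
            channels = 1L + seq_len(n_other))
}
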