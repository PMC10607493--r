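#' Linear frame encoder
#'
#' Maps each L-sample frame to a K-dimensional embedding through a learned
#' weight matrix (no bias): `Z = X D`. This is the per-frame form of a
#' 1-D convolutional encoder whose kernel spans the frame.
#'
#' @param frames a `frame_set` or a plain n_frames x L matrix.
#' @param D weight matrix, L x K.
#' @return n_frames x K embedding matrix.
#' @export
encode_frames <- function(frames, D) {
  X <- if (inherits(frames, "frame_set")) frames$frames else frames
  stopifnot(is.matrix(X), is.matrix(D))
  if (ncol(X) != nrow(D)) {
    stop("encoder dimension mismatch: frames have L = ", ncol(X),
         " but D has ", nrow(D), " rows", call. = FALSE)
  }
  X %*% D
}

#' Normalized cross-correlation between a context and a frame
#'
#' The per-lag cosine similarity between every L-sample slice of the
#' reference context window and another channel's frame: the beamformer's
#' inter-channel spatial feature. With the default 3L context there are
#' 2L+1 lags, spanning inter-sensor delays of +/- L samples. Slices or
#' frames of zero norm yield 0, the neutral "no correlation" value.
#'
#' @param ref_context a `context_frame` (see [extract_context()]) or a
#'   numeric vector of length `L + 2*context_len`.
#' @param other_frame numeric vector of length L.
#' @return numeric vector of per-lag cosine similarities, all in \[-1, 1\].
#' @export
ncc_feature <- function(ref_context, other_frame) {
  ctx <- if (inherits(ref_context, "context_frame")) ref_context$values else
    as.numeric(ref_context)
  fr <- as.numeric(other_frame)
  L <- length(fr)
  if (length(ctx) < L) stop("context shorter than frame", call. = FALSE)
  drop(ncc_all_lags(matrix(ctx, nrow = 1L), matrix(fr, nrow = 1L)))
}

# All frames at once: CTX is n_frames x (L + 2*context_len), FR is
# n_frames x L; returns n_frames x n_lags.
ncc_matrix <- function(CTX, FR) {
  ncc_all_lags(CTX, FR)
}

#' Average NCC features over the non-reference channels
#'
#' Elementwise mean of the per-channel NCC vectors for channels 2..N.
#'
#' @param features list of equal-length numeric vectors (or matrices), one
#'   per non-reference channel.
#' @return the elementwise mean, same shape as each element.
#' @export
average_ncc <- function(features) {
  if (!is.list(features) || length(features) == 0L) {
    stop("need a non-empty list of NCC features", call. = FALSE)
  }
  lens <- vapply(features, length, numeric(1))
  if (length(unique(lens)) != 1L) {
    stop("NCC features have unequal lengths", call. = FALSE)
  }
  Reduce(`+`, features) / length(features)
}
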