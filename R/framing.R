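#' Zero-phase band-pass conditioning
#'
#' Removes sensor drift and out-of-band noise before separation. The
#' acquisition chain keeps 100 Hz--15 kHz, bracketing the 6--12 kHz band
#' where boring-vibration energy concentrates; those are the defaults. The
#' filter is a cascade of Butterworth high-pass and low-pass sections run
#' forward-backward (`signal::filtfilt`), so conditioning is zero phase and
#' never shifts pulse timing between channels.
#'
#' @param rec a [multichannel_recording()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order of each section (per pass).
#' @return A conditioned [multichannel_recording()].
#' @export
bandpass_condition <- function(rec, low_hz = 100, high_hz = 15000,
                               order = 4L) {
  stopifnot(inherits(rec, "multichannel_recording"))
  fs <- rec$sample_rate_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  }
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  out <- t(apply(rec$samples, 1L, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  if (n_channels(rec) == 1L) out <- matrix(out, nrow = 1L)
  multichannel_recording(out, fs, rec$channel_ids)
}

#' Segment a signal into hopped frames
#'
#' Frame `t` (0-based) is `x[t*M : t*M + L - 1]`; the tail is zero-padded so
#' every sample is covered, giving `ceil((T - L)/M) + 1` frames.
#'
#' @param x numeric vector (one channel).
#' @param L frame length in samples.
#' @param M hop in samples, `1 <= M <= L`; default `L/2` (50% overlap).
#' @param channel_id optional label carried through.
#' @return A `frame_set`: list with `frames` (n_frames x L matrix), `L`, `M`,
#'   `source_length` and `channel_id`.
#' @export
frame_signal <- function(x, L, M = L %/% 2L, channel_id = "ch1") {
  x <- as.numeric(x)
  L <- as.integer(L); M <- as.integer(M)
  if (L < 1L || M < 1L || M > L) {
    stop("need L >= 1 and 1 <= M <= L", call. = FALSE)
  }
  T <- length(x)
  if (T < 1L) stop("empty signal", call. = FALSE)
  n_frames <- if (T <= L) 1L else as.integer(ceiling((T - L) / M)) + 1L
  pad_to <- (n_frames - 1L) * M + L
  xp <- c(x, numeric(pad_to - T))
  idx <- outer((seq_len(n_frames) - 1L) * M, seq_len(L), `+`)
  frames <- matrix(xp[idx], nrow = n_frames, ncol = L)
  structure(list(frames = frames, L = L, M = M, source_length = T,
                 channel_id = channel_id),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames of L=%d, hop M=%d, source T=%d (%s)\n",
              nrow(x$frames), x$L, x$M, x$source_length, x$channel_id))
  invisible(x)
}

#' Extract the zero-padded context window of one frame
#'
#' The beamforming filters span inter-sensor delays of up to +/- `context_len`
#' samples, so each frame is extended by `context_len` samples on both sides;
#' positions outside the signal are exactly zero. Default `context_len = L`,
#' giving a 3L-sample reference context and 2L+1 filter taps.
#'
#' @param x numeric vector (one channel).
#' @param t 0-based frame index.
#' @param L frame length; @param M hop; @param context_len context half-span.
#' @return A `context_frame`: list with `values` (length `L + 2*context_len`)
#'   and `center_offset` (1-based index where the frame proper begins).
#' @export
extract_context <- function(x, t, L, M = L %/% 2L, context_len = L) {
  x <- as.numeric(x)
  t <- as.integer(t)
  n_frames <- if (length(x) <= L) 1L else as.integer(ceiling((length(x) - L) / M)) + 1L
  if (t < 0L || t >= n_frames) stop("frame index out of bounds", call. = FALSE)
  pos <- (t * M - context_len) + seq_len(L + 2L * context_len) - 1L  # 0-based
  inside <- pos >= 0L & pos < length(x)
  values <- numeric(length(pos))
  values[inside] <- x[pos[inside] + 1L]
  structure(list(values = values, center_offset = context_len + 1L,
                 L = L, context_len = context_len),
            class = "context_frame")
}

# All context windows of a channel as an n_frames x (L + 2*context_len)
# matrix; row t+1 equals extract_context(x, t, ...)$values.
context_matrix <- function(x, L, M = L %/% 2L, context_len = L) {
  x <- as.numeric(x)
  T <- length(x)
  n_frames <- if (T <= L) 1L else as.integer(ceiling((T - L) / M)) + 1L
  width <- L + 2L * context_len
  pad_to <- (n_frames - 1L) * M + L
  # 0-based sample position of column j of frame row t
  pos <- outer((seq_len(n_frames) - 1L) * M - context_len,
               seq_len(width) - 1L, `+`)
  xp <- c(numeric(context_len), x, numeric(pad_to + context_len - T))
  out <- matrix(xp[pos + context_len + 1L], nrow = n_frames, ncol = width)
  out * (pos >= 0L & pos < T)
}

#' Reconstruct a signal from hopped frames (overlap-add)
#'
#' Overlapping contributions are averaged by the per-sample overlap count,
#' which makes `overlap_add(frame_signal(x))` the identity for every valid
#' `(L, M)` and a proper reconstruction for modified (beamformed) frames.
#'
#' @param fs a `frame_set` (or a plain frames matrix together with `M` and
#'   `source_length`).
#' @param M,source_length required when `fs` is a bare matrix.
#' @return numeric vector of length `source_length`.
#' @export
overlap_add <- function(fs, M = NULL, source_length = NULL) {
  if (inherits(fs, "frame_set")) {
    frames <- fs$frames; M <- fs$M; source_length <- fs$source_length
  } else {
    frames <- fs
    if (is.null(M) || is.null(source_length)) {
      stop("M and source_length are required for bare frame matrices",
           call. = FALSE)
    }
  }
  L <- ncol(frames)
  n_frames <- nrow(frames)
  pad_to <- (n_frames - 1L) * M + L
  acc <- numeric(pad_to)
  cnt <- numeric(pad_to)
  for (t in seq_len(n_frames)) {
    sl <- (t - 1L) * M + seq_len(L)
    acc[sl] <- acc[sl] + frames[t, ]
    cnt[sl] <- cnt[sl] + 1
  }
  out <- acc / pmax(cnt, 1)
  out[seq_len(source_length)]
}

# index matrix mapping frame positions to sample positions plus the overlap
# count; used by the training loss to push sample-domain gradients back into
# frames. Returns list(idx = n_frames x L matrix of 1-based sample indices
# (may exceed source_length into the pad), count = per-sample overlap count).
ola_index <- function(n_frames, L, M) {
  idx <- outer((seq_len(n_frames) - 1L) * M, seq_len(L), `+`)
  pad_to <- (n_frames - 1L) * M + L
  cnt <- numeric(pad_to)
  for (t in seq_len(n_frames)) {
    sl <- (t - 1L) * M + seq_len(L)
    cnt[sl] <- cnt[sl] + 1
  }
  list(idx = idx, count = cnt)
}
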