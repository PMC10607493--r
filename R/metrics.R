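#' Scale-invariant signal-to-noise ratio
#'
#' Both signals are mean-centered; the estimate is decomposed into its
#' orthogonal projection onto the reference, `s = <e, r>/||r||^2 * r`, and
#' the residual `e - s`. Returns `10 log10(||s||^2 / ||e - s||^2)` in dB,
#' capped at +60 dB for numerically perfect reconstruction. Invariant to
#' positive rescaling of the estimate.
#'
#' @param est,ref numeric vectors of equal length; `ref` must have nonzero
#'   power after centering.
#' @return SI-SNR in dB (scalar). The attribute `capped` is `TRUE` when the
#'   +60 dB cap was applied.
#' @export
si_snr <- function(est, ref) {
  stopifnot(length(est) == length(ref))
  e <- est - mean(est)
  r <- ref - mean(ref)
  rr <- sum(r^2)
  if (rr <= 0) stop("reference has zero power", call. = FALSE)
  s <- (sum(e * r) / rr) * r
  ssq <- sum(s^2)
  esq <- sum((e - s)^2)
  val <- 10 * log10(ssq / esq)
  capped <- !is.finite(val) || val > 60
  structure(if (capped) 60 else val, capped = capped)
}

#' Orthogonal SDR decomposition
#'
#' Decomposes an estimate into four mutually orthogonal components by
#' successive least-squares projections: onto the reference
#' (`s_target`), onto the span of reference plus interferers minus the
#' first (`e_interf`), onto the additional span of the noise reference
#' (`e_noise`), and the remainder (`e_artif`). The components sum back to
#' the estimate, and `SDR = 10 log10(P_target / (P_interf + P_noise +
#' P_artif))`. Absent interferers/noise their components are zero.
#'
#' @param est,ref numeric vectors of equal length.
#' @param interferers optional list of interfering-source references.
#' @param noise optional noise reference vector.
#' @return An `sdr_decomposition`: list of the four component vectors,
#'   their powers `P_target`, `P_interf`, `P_noise`, `P_artif`, `sdr_db`
#'   and a `capped` flag.
#' @export
sdr_decompose <- function(est, ref, interferers = NULL, noise = NULL) {
  stopifnot(length(est) == length(ref))
  if (sum(ref^2) <= 0) stop("reference has zero power", call. = FALSE)
  proj_onto <- function(y, basis) {
    # least-squares projection of y onto the column span of basis
    qrb <- qr(basis)
    if (qrb$rank < ncol(basis)) {
      stop("rank-deficient reference set in SDR decomposition",
           call. = FALSE)
    }
    qr.fitted(qrb, y)
  }
  B1 <- matrix(ref, ncol = 1L)
  s_target <- proj_onto(est, B1)
  if (!is.null(interferers) && length(interferers) > 0L) {
    B2 <- cbind(B1, do.call(cbind, lapply(interferers, as.numeric)))
    p2 <- proj_onto(est, B2)
  } else {
    p2 <- s_target
  }
  e_interf <- p2 - s_target
  if (!is.null(noise)) {
    B3 <- cbind(if (exists("B2", inherits = FALSE)) B2 else B1,
                as.numeric(noise))
    p3 <- proj_onto(est, B3)
  } else {
    p3 <- p2
  }
  e_noise <- p3 - p2
  e_artif <- est - p3
  P_target <- sum(s_target^2)
  P_interf <- sum(e_interf^2)
  P_noise <- sum(e_noise^2)
  P_artif <- sum(e_artif^2)
  den <- P_interf + P_noise + P_artif
  val <- 10 * log10(P_target / den)
  capped <- !is.finite(val) || val > 60
  structure(
    list(s_target = s_target, e_interf = e_interf, e_noise = e_noise,
         e_artif = e_artif, P_target = P_target, P_interf = P_interf,
         P_noise = P_noise, P_artif = P_artif,
         sdr_db = if (capped) 60 else val, capped = capped),
    class = "sdr_decomposition"
  )
}

#' @export
print.sdr_decomposition <- function(x, ...) {
  cat(sprintf("<sdr_decomposition> SDR = %.2f dB%s (P_target %.3g, P_interf %.3g, P_noise %.3g, P_artif %.3g)\n",
              x$sdr_db, if (x$capped) " [capped]" else "", x$P_target,
              x$P_interf, x$P_noise, x$P_artif))
  invisible(x)
}

#' Score separated estimates against a scene manifest
#'
#' For every test-split row of the manifest, reads
#' `<estimates_dir>/<scene_id>.wav`, scores it against the clean reference
#' with [si_snr()] and [sdr_decompose()] (noise reference as the noise
#' basis), and aggregates. Missing estimates are reported and excluded.
#'
#' @param manifest manifest `data.frame` or CSV path (see
#'   [build_dataset()]).
#' @param estimates_dir directory of mono estimate WAVs named by scene id.
#' @param split which manifest split to score (default `"test"`).
#' @return An `evaluation_report`: list with `per_scene` data.frame
#'   (scene_id, si_snr_db, sdr_db, capped flags), `mean_si_snr_db`,
#'   `median_si_snr_db`, `mean_sdr_db` and `n_missing`.
#' @export
evaluate_pairs <- function(manifest, estimates_dir, split = "test") {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  rows <- manifest[manifest$split == split, , drop = FALSE]
  out <- list()
  n_missing <- 0L
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    ep <- file.path(estimates_dir, paste0(row$scene_id, ".wav"))
    if (!file.exists(ep)) {
      warning("missing estimate for ", row$scene_id, call. = FALSE)
      n_missing <- n_missing + 1L
      next
    }
    est <- read_multichannel_wav(ep)$samples[1, ]
    ref <- read_multichannel_wav(row$clean_path)$samples[1, ]
    noi <- read_multichannel_wav(row$noise_path)$samples[1, ]
    s <- si_snr(est, ref)
    d <- sdr_decompose(est, ref, noise = noi)
    out[[length(out) + 1L]] <- data.frame(
      scene_id = row$scene_id, si_snr_db = as.numeric(s),
      si_snr_capped = attr(s, "capped"), sdr_db = d$sdr_db,
      sdr_capped = d$capped, stringsAsFactors = FALSE)
  }
  per_scene <- if (length(out)) do.call(rbind, out) else
    data.frame(scene_id = character(0), si_snr_db = numeric(0),
               si_snr_capped = logical(0), sdr_db = numeric(0),
               sdr_capped = logical(0))
  per_scene <- per_scene[order(per_scene$scene_id), , drop = FALSE]
  structure(list(per_scene = per_scene,
                 mean_si_snr_db = mean(per_scene$si_snr_db),
                 median_si_snr_db = stats::median(per_scene$si_snr_db),
                 mean_sdr_db = mean(per_scene$sdr_db),
                 n_missing = n_missing),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d scene(s): mean SI-SNR %.2f dB, median %.2f dB, mean SDR %.2f dB; %d missing\n",
              nrow(x$per_scene), x$mean_si_snr_db, x$median_si_snr_db,
              x$mean_sdr_db, x$n_missing))
  invisible(x)
}
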