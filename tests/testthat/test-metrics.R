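# independent least-squares oracle: fit est ~ a * ref by lm() and read the
# SI-SNR off the fitted decomposition
sisnr_oracle <- function(est, ref) {
  e <- est - mean(est)
  r <- ref - mean(ref)
  fit <- stats::lm(e ~ r - 1)
  s <- stats::fitted(fit)
  10 * log10(sum(s^2) / sum(stats::residuals(fit)^2))
}

# brute-force Gram-matrix projection oracle for the SDR decomposition
sdr_oracle <- function(est, ref, noise) {
  proj <- function(y, B) {
    G <- crossprod(B)
    B %*% solve(G, crossprod(B, y))
  }
  s_t <- proj(est, cbind(ref))
  p3 <- proj(est, cbind(ref, noise))
  e_n <- p3 - s_t
  e_a <- est - p3
  c(P_target = sum(s_t^2), P_noise = sum(e_n^2), P_artif = sum(e_a^2))
}

test_that("si_snr equals the 20 dB constructed case exactly", {
  set.seed(61)
  ref <- rnorm(1000)
  ref <- ref - mean(ref)
  w <- rnorm(1000)
  w <- w - mean(w)
  w <- w - ref * sum(w * ref) / sum(ref^2)       # orthogonalize
  w <- w * sqrt(sum(ref^2) / (100 * sum(w^2)))   # power ratio 100
  expect_equal(as.numeric(si_snr(ref + w, ref)), 20, tolerance = 1e-6)
})

test_that("si_snr caps perfect reconstruction and is scale invariant", {
  set.seed(62)
  ref <- rnorm(500)
  v <- si_snr(ref, ref)
  expect_equal(as.numeric(v), 60)
  expect_true(attr(v, "capped"))
  est <- ref + 0.1 * rnorm(500)
  base <- as.numeric(si_snr(est, ref))
  for (a in c(0.1, 3, 100)) {
    expect_equal(as.numeric(si_snr(a * est, ref)), base, tolerance = 1e-9)
  }
  expect_error(si_snr(est, numeric(500)), "zero power")
})

test_that("si_snr matches the least-squares oracle on 100 random cases", {
  set.seed(63)
  for (r in 1:100) {
    ref <- rnorm(1000)
    est <- 0.7 * ref + rnorm(1000) * runif(1, 0.01, 2)
    expect_equal(as.numeric(si_snr(est, ref)), sisnr_oracle(est, ref),
                 tolerance = 1e-6)
  }
})

test_that("adding orthogonal noise strictly decreases si_snr", {
  set.seed(64)
  ref <- rnorm(800)
  est <- ref + 0.2 * rnorm(800)
  base <- as.numeric(si_snr(est, ref))
  w <- rnorm(800)
  w <- w - mean(w)
  w <- w - ref * sum(w * (ref - mean(ref))) / sum((ref - mean(ref))^2)
  worse <- as.numeric(si_snr(est + 0.5 * w, ref))
  expect_lt(worse, base)
})

test_that("sdr_decompose components recombine, are orthogonal, and match the
          Gram oracle", {
  set.seed(65)
  for (r in 1:100) {
    n <- 1000
    ref <- rnorm(n)
    noise <- rnorm(n)
    est <- runif(1, 0.2, 2) * ref + runif(1, 0.1, 1) * noise +
      0.3 * rnorm(n)
    d <- sdr_decompose(est, ref, noise = noise)
    recomb <- d$s_target + d$e_interf + d$e_noise + d$e_artif
    expect_lt(max(abs(recomb - est)), 1e-8)
    comps <- list(d$s_target, d$e_noise, d$e_artif)
    for (i in 1:2) for (j in (i + 1):3) {
      ni <- sqrt(sum(comps[[i]]^2)); nj <- sqrt(sum(comps[[j]]^2))
      if (ni > 0 && nj > 0) {
        expect_lt(abs(sum(comps[[i]] * comps[[j]])) / (ni * nj), 1e-6)
      }
    }
    o <- sdr_oracle(est, ref, noise)
    expect_equal(d$P_target, o[["P_target"]], tolerance = 1e-6 * o[["P_target"]])
    expect_equal(d$P_noise, o[["P_noise"]], tolerance = 1e-6 * max(1e-12, o[["P_noise"]]))
    expect_equal(d$P_artif, o[["P_artif"]], tolerance = 1e-6 * max(1e-12, o[["P_artif"]]))
  }
})

test_that("sdr degenerate and constructed cases", {
  set.seed(66)
  ref <- rnorm(400)
  d0 <- sdr_decompose(ref, ref)
  expect_equal(d0$P_interf, 0)
  expect_equal(d0$P_noise, 0)
  expect_true(d0$capped)
  expect_equal(d0$sdr_db, 60)
  # est = ref + a, a orthogonal to ref: SDR = 10 log10(P_target / P_artif)
  a <- rnorm(400)
  a <- a - ref * sum(a * ref) / sum(ref^2)
  est <- ref + a
  d1 <- sdr_decompose(est, ref)
  expect_equal(d1$sdr_db, 10 * log10(d1$P_target / d1$P_artif),
               tolerance = 1e-9)
  expect_error(sdr_decompose(est, ref, interferers = list(2 * ref)),
               "rank-deficient")
})

test_that("evaluate_pairs scores identity estimates at the cap and mixtures
          like direct si_snr", {
  dir <- withr::local_tempdir()
  est_dir <- withr::local_tempdir()
  manifest <- build_dataset(6, tiny_scene_spec(), dir, train_fraction = 0.5)
  test_rows <- manifest[manifest$split == "test", ]
  # identity estimates: copy the clean reference
  for (i in seq_len(nrow(test_rows))) {
    file.copy(test_rows$clean_path[i],
              file.path(est_dir, paste0(test_rows$scene_id[i], ".wav")))
  }
  rep1 <- evaluate_pairs(manifest, est_dir)
  expect_equal(nrow(rep1$per_scene), nrow(test_rows))
  expect_true(all(rep1$per_scene$si_snr_db == 60))
  expect_equal(rep1$mean_si_snr_db, 60)
  # mixture-as-estimate reproduces direct si_snr values
  est_dir2 <- withr::local_tempdir()
  for (i in seq_len(nrow(test_rows))) {
    mix <- read_multichannel_wav(test_rows$mixture_path[i])
    write_multichannel_wav(
      multichannel_recording(mix$samples[1, , drop = FALSE],
                             mix$sample_rate_hz),
      file.path(est_dir2, paste0(test_rows$scene_id[i], ".wav")))
  }
  rep2 <- evaluate_pairs(manifest, est_dir2)
  for (i in seq_len(nrow(test_rows))) {
    mix <- read_multichannel_wav(test_rows$mixture_path[i])
    ref <- read_multichannel_wav(test_rows$clean_path[i])
    direct <- as.numeric(si_snr(mix$samples[1, ], ref$samples[1, ]))
    row <- rep2$per_scene[rep2$per_scene$scene_id == test_rows$scene_id[i], ]
    expect_equal(row$si_snr_db, direct, tolerance = 1e-6)
  }
  # missing estimates are counted and excluded (one warning per scene)
  est_dir3 <- withr::local_tempdir()
  ws <- capture_warnings(rep3 <- evaluate_pairs(manifest, est_dir3))
  expect_true(all(grepl("missing", ws)))
  expect_length(ws, nrow(test_rows))
  expect_equal(rep3$n_missing, nrow(test_rows))
  expect_equal(nrow(rep3$per_scene), 0L)
})
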