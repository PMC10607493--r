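#' Training configuration
#'
#' Optimization settings for [train_multisams()]. Defaults follow the
#' reference protocol: learning rate 1e-3, up to 120 epochs, early stopping
#' after 10 epochs without validation improvement; Adam by default, SGD
#' available. The loss is the negative SI-SNR of the signal stream against
#' the clean reference; with `supervise_noise = TRUE` the residual stream
#' is additionally trained against the noise reference.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr learning rate (> 0).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs (`< max_epochs`).
#' @param batch_size scenes per gradient step.
#' @param loss loss label; only `"neg-si-snr"` is defined.
#' @param supervise_noise also supervise the residual stream.
#' @param seed RNG seed for shuffling and validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), lr = 1e-3,
                         max_epochs = 120L, patience = 10L,
                         batch_size = 4L, loss = "neg-si-snr",
                         supervise_noise = FALSE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, max_epochs >= 1L, patience >= 1L,
            patience < max_epochs, batch_size >= 1L,
            identical(loss, "neg-si-snr"))
  structure(list(optimizer = optimizer, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), loss = loss,
                 supervise_noise = isTRUE(supervise_noise),
                 seed = as.integer(seed)),
            class = "train_config")
}

# resolve a manifest (data.frame/path) or a build_scene_list() result into
# a uniform list of scenes with split labels
resolve_scenes <- function(data) {
  if (is.list(data) && !is.null(data$scenes) && !is.null(data$split)) {
    scenes <- lapply(seq_along(data$scenes), function(k) {
      sc <- data$scenes[[k]]
      list(mixture = sc$mixture, clean_reference = sc$clean_reference,
           noise_reference = sc$noise_reference,
           scene_id = sprintf("scene%04d", k), split = data$split[k])
    })
    return(scenes)
  }
  load_manifest_scenes(data)
}

#' Train MultiSAMS
#'
#' Minimizes the negative SI-SNR of the separated signal stream against the
#' clean reference with minibatch gradient descent. A seed-fixed 10% of the
#' training scenes is held out as a validation set for model selection and
#' early stopping; the returned weights are those of the best validation
#' epoch.
#'
#' @param config a [model_config()].
#' @param tcfg a [train_config()].
#' @param data a manifest `data.frame`/CSV path (see [build_dataset()]) or
#'   the result of [build_scene_list()].
#' @param weights optional starting weights (default [multisams_init()]).
#' @param verbose print per-epoch progress.
#' @return A `multisams_fit`: list with `weights` (best epoch), `history`
#'   data.frame (epoch, train_loss, val_si_snr_db), `best_epoch`,
#'   `best_val_si_snr_db`, `stop_reason` (`"early_stop"` or
#'   `"max_epochs"`), `config` and `train_config`.
#' @export
train_multisams <- function(config, tcfg, data, weights = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(config, "multisams_config"),
            inherits(tcfg, "train_config"))
  scenes <- resolve_scenes(data)
  tr <- which(vapply(scenes, function(s) s$split == "train", logical(1)))
  if (length(tr) < 2L) stop("need a non-empty training split", call. = FALSE)
  restore <- local_rng(tcfg$seed)
  on.exit(restore())
  n_val <- max(1L, round(0.1 * length(tr)))
  val <- sample(tr, n_val)
  tr <- setdiff(tr, val)
  # fixed-composition minibatches, featurized once; batch order is shuffled
  # every epoch
  batch_ids <- split(sample(tr), ceiling(seq_along(tr) / tcfg$batch_size))
  make_batch <- function(ids) {
    list(ids = ids,
         inp = prep_batch_input(lapply(scenes[ids],
                                       function(s) s$mixture), config),
         clean = lapply(scenes[ids], function(s) s$clean_reference),
         noise = lapply(scenes[ids], function(s) s$noise_reference))
  }
  batches <- lapply(batch_ids, make_batch)
  vbatches <- lapply(split(val, ceiling(seq_along(val) / 16L)), make_batch)
  if (is.null(weights)) weights <- multisams_init(config)
  state <- if (tcfg$optimizer == "adam") adam_init(weights) else NULL
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_si_snr_db = numeric(0))
  best_val <- -Inf
  best_weights <- weights
  best_epoch <- 0L
  stall <- 0L
  stop_reason <- "max_epochs"
  act <- if (tcfg$supervise_noise && config$n_sources >= 2L) c(1L, 2L) else 1L
  batch_loss <- function(w, bt) {
    inp <- bt$inp
    n_sc <- inp$n_sc
    fwd <- forward_full(w, inp, config, active_sources = act)
    loss <- 0
    dsrc <- vector("list", n_sc)
    for (q in seq_len(n_sc)) {
      l1 <- loss_neg_sisnr(fwd$sources[[q]][1, ], bt$clean[[q]])
      lq <- l1$loss
      dq <- matrix(0, config$n_sources, inp$T)
      dq[1, ] <- l1$grad
      if (tcfg$supervise_noise && config$n_sources >= 2L) {
        l2 <- loss_neg_sisnr(fwd$sources[[q]][2, ], bt$noise[[q]])
        lq <- 0.5 * (lq + l2$loss)
        dq[1, ] <- 0.5 * dq[1, ]
        dq[2, ] <- 0.5 * l2$grad
      }
      loss <- loss + lq / n_sc
      dsrc[[q]] <- dq / n_sc
    }
    if (!is.finite(loss)) {
      stop("training diverged (non-finite loss)", call. = FALSE)
    }
    list(loss = loss, grads = backward_full(w, inp, config, fwd, dsrc))
  }
  val_metric <- function(w) {
    vals <- unlist(lapply(vbatches, function(bt) {
      fwd <- forward_full(w, bt$inp, config, active_sources = 1L)
      vapply(seq_along(bt$ids), function(q) {
        as.numeric(si_snr(fwd$sources[[q]][1, ], bt$clean[[q]]))
      }, numeric(1))
    }))
    mean(vals)
  }
  for (epoch in seq_len(tcfg$max_epochs)) {
    set.seed(tcfg$seed + 7L * epoch)
    ep_loss <- 0
    for (b in sample(seq_along(batches))) {
      r <- batch_loss(weights, batches[[b]])
      grads <- r$grads
      if (tcfg$optimizer == "adam") {
        st <- adam_step(weights, grads, state, lr = tcfg$lr)
        cfg_attr <- attr(weights, "config")
        weights <- st$params
        attr(weights, "config") <- cfg_attr
        class(weights) <- "multisams_weights"
        state <- st$state
      } else {
        cfg_attr <- attr(weights, "config")
        weights <- sgd_step(weights, grads, lr = tcfg$lr)
        attr(weights, "config") <- cfg_attr
        class(weights) <- "multisams_weights"
      }
      ep_loss <- ep_loss + r$loss * length(batches[[b]]$ids)
    }
    ep_loss <- ep_loss / length(tr)
    vm <- val_metric(weights)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_si_snr_db = vm))
    if (verbose) {
      message(sprintf("epoch %3d: train loss %8.3f  val SI-SNR %7.3f dB",
                      epoch, ep_loss, vm))
    }
    if (vm > best_val) {
      best_val <- vm
      best_weights <- weights
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tcfg$patience) {
        stop_reason <- "early_stop"
        break
      }
    }
  }
  structure(list(weights = best_weights, history = hist,
                 best_epoch = best_epoch, best_val_si_snr_db = best_val,
                 stop_reason = stop_reason, config = config,
                 train_config = tcfg),
            class = "multisams_fit")
}

#' @export
print.multisams_fit <- function(x, ...) {
  cat(sprintf("<multisams_fit> %d epoch(s), best epoch %d (val SI-SNR %.2f dB), stopped: %s\n",
              nrow(x$history), x$best_epoch, x$best_val_si_snr_db,
              x$stop_reason))
  invisible(x)
}

#' Evaluate a model on a scene split
#'
#' Runs full separation on every scene of the chosen split and scores the
#' signal stream with [si_snr()] and [sdr_decompose()] (noise reference as
#' the noise basis); also reports the unprocessed reference-channel mixture
#' SI-SNR as the no-processing baseline.
#'
#' @param weights a `multisams_weights` object.
#' @param config the matching [model_config()].
#' @param data manifest or [build_scene_list()] result.
#' @param split split to evaluate (default `"test"`).
#' @return data.frame with scene_id, mixture_si_snr_db, si_snr_db, sdr_db.
#' @export
evaluate_model <- function(weights, config, data, split = "test") {
  scenes <- resolve_scenes(data)
  scenes <- Filter(function(s) s$split == split, scenes)
  groups <- split(seq_along(scenes), ceiling(seq_along(scenes) / 16L))
  rows <- lapply(groups, function(ids) {
    inp <- prep_batch_input(lapply(scenes[ids], function(s) s$mixture),
                            config)
    fwd <- forward_full(weights, inp, config, active_sources = 1L)
    do.call(rbind, lapply(seq_along(ids), function(q) {
      s <- scenes[[ids[q]]]
      est <- fwd$sources[[q]][1, ]
      data.frame(
        scene_id = s$scene_id,
        mixture_si_snr_db = as.numeric(si_snr(s$mixture$samples[1, ],
                                              s$clean_reference)),
        si_snr_db = as.numeric(si_snr(est, s$clean_reference)),
        sdr_db = sdr_decompose(est, s$clean_reference,
                               noise = s$noise_reference)$sdr_db,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, configuration, the initialization seed
#' and an optional manifest hash for provenance.
#'
#' @param weights a `multisams_weights` object (or a `multisams_fit`).
#' @param config the matching [model_config()]; taken from a fit if omitted.
#' @param path file path.
#' @param manifest optional manifest used for training (hashed).
#' @return `path` invisibly (save); checkpoint list (load).
#' @export
save_checkpoint <- function(weights, path, config = NULL, manifest = NULL) {
  if (inherits(weights, "multisams_fit")) {
    config <- weights$config
    weights <- weights$weights
  }
  if (is.null(config)) config <- attr(weights, "config")
  mhash <- if (!is.null(manifest)) {
    sum(utils::object.size(manifest)) + nrow(manifest)
  } else {
    NA
  }
  saveRDS(list(weights = weights, config = config, seed = config$seed,
               manifest_hash = mhash), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
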