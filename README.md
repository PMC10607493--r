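# multisams

Separation of wood-boring insect vibration signals from noisy
multi-sensor recordings by learned time-domain beamforming.

## The problem

Larvae of wood-boring beetles (e.g. the emerald ash borer) feed inside
tree trunks and emit brief substrate-borne vibration pulses with energy
concentrated around 6–12 kHz. Piezoelectric probes in the trunk can
record them, but outdoor recordings are swamped by environmental noise,
and a single probe far from the larva is often useless. With N ≥ 2 probes
the channels can be combined so that coherent boring-vibration energy
adds while noise does not. `multisams` is for researchers building such
acoustic pest-detection pipelines: it provides the separation model, a
seed-controlled scene simulator (real infested-trunk recordings are
rarely distributable), the evaluation metrics, and a training/experiment
harness.

## The model

MultiSAMS is a two-stage, time-domain filter-and-sum beamformer with
learned, per-frame filters. Each channel is framed
(x_t^i = x^i[tM : tM+L−1]) and extended to a ±L context window; the
beamformed frame is

    ŷ_t = Σ_i  z_t^i ⊛ x̂_t^i

where z_t^i are (2L+1)-tap filters estimated frame by frame by a neural
network from (a) learned frame embeddings Z = X D and (b) normalized
cross-correlation (NCC) features — per-lag cosine similarities between
the reference channel's context and the other channels' frames. The
filter-estimation network is a dual-path stack: bidirectional recurrent
layers (GRU/LSTM/RNN) applied alternately within and across chunks of the
frame sequence, each followed by multi-head self-attention
(softmax(QKᵀ/√d_k)V, h = 8 heads), a dimension-restoring linear layer,
layer norm and a residual connection, ending in a gated output
tanh(·)⊙σ(·). Stage 1 beamforms the reference channel; its estimate then
serves as the NCC cue for estimating the remaining channels' filters,
whose outputs are summed with it (stage 2). Training minimizes negative
scale-invariant SNR (SI-SNR) with Adam, early-stopped on a held-out
validation split. Evaluation uses SI-SNR and an orthogonal-projection SDR
decomposition (s_target + e_interf + e_noise + e_artif).

All forward and backward passes (the recurrent cells, attention, gating,
beamforming correlation) are implemented in this package with
RcppArmadillo kernels and are verified against finite differences and
brute-force oracles in the test suite. See the methods vignette
(`vignettes/multisams-methods.Rmd`) for the full model description,
simulator assumptions and design decisions.

## Worked example

Desk-scale end to end: simulate 120 four-probe scenes (1 s @ 8 kHz,
feeding pulses in pink noise at −5…10 dB SNR), train the small GRU
beamformer for two epochs, and score the 20 held-out scenes.

```r
library(multisams)

preset <- desk_preset(seed = 1)          # scene spec + model config
scenes <- build_scene_list(120, preset$scene, train_fraction = 5/6)

tc  <- train_config(optimizer = "adam", lr = 1e-3, max_epochs = 2,
                    patience = 1, batch_size = 8, seed = 1)
fit <- train_multisams(preset$model, tc, scenes, verbose = TRUE)
#> epoch   1: train loss   -0.568  val SI-SNR   7.260 dB
#> epoch   2: train loss   -9.423  val SI-SNR  10.368 dB

ev <- evaluate_model(fit$weights, preset$model, scenes, split = "test")
cat(sprintf("mean SI-SNR: mixture %.2f dB -> separated %.2f dB (+%.2f dB)\n",
            mean(ev$mixture_si_snr_db), mean(ev$si_snr_db),
            mean(ev$si_snr_db) - mean(ev$mixture_si_snr_db)))
#> mean SI-SNR: mixture 3.81 dB -> separated 12.27 dB (+8.46 dB)

res <- multisams_forward(scenes$scenes[[115]]$mixture, preset$model,
                         fit$weights)
res
#> <separation_result> 2 source(s) x 8000 samples @ 8000 Hz
si_snr(res$sources[1, ], scenes$scenes[[115]]$clean_reference)
#> [1] 14.90  (scene 115)
```

The training loss is the negative SI-SNR of the separated signal stream
against the clean reference, so −9.4 after epoch 2 means the model
reconstructs training scenes at about +9.4 dB SI-SNR. On the held-out
scenes the separated stream scores 12.27 dB SI-SNR on average against
3.81 dB for the raw reference-channel mixture — an 8.5 dB gain from two
epochs of training. `res$sources` holds the two output streams (boring
signal and residual) at full length.

A command-line interface over the same functions ships in
`inst/cli/multisams.R` with subcommands `synth`, `train`, `separate`,
`evaluate` and `grid`.

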