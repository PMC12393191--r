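# Shared fixtures, built once per test run.
#
# `fx$cfg64` is the desk-scale phantom protocol (64 echoes, 21 shifted,
# K = 10, 64 x 64); `fx$train64` its echo train with b-values; `fx$sigma50`
# the SNR-50 noise level; `fx$invivo` the Table-style in vivo protocol.

fx <- local({
  cfg64 <- es_protocol()
  invivo <- es_protocol(TR = 3000, n_slices = 23, n_echoes = 64,
                        n_shifted = 21, K = 10, flip_angle = 60,
                        matrix = c(240, 216), navigator_slots = c(16L, 49L))
  list(
    cfg64 = cfg64,
    train64 = build_echo_train(cfg64),
    phantom = build_figure2_phantom(cfg64),
    sigma50 = sigma_for_snr(cfg64, 50),
    tissues = es_tissue_defaults(),
    invivo = invivo
  )
})

tissue_row <- function(label) fx$tissues[fx$tissues$label == label, ]

# one noisy magnitude voxel under the forward model
noisy_voxel <- function(tissue, seed, sigma = fx$sigma50,
                        train = fx$train64, cfg = fx$cfg64) {
  Mod(simulate_voxel_signal(tissue, train, cfg, es_noise(sigma, seed = seed)))
}

# rectangular PGSE waveform sampled on a raster: two opposite rectangles of
# amplitude G (mT/m) and duration delta_ms separated by Delta_ms
pgse_samples <- function(G, delta_ms, Delta_ms, raster = 0.01,
                         total_ms = Delta_ms + 2 * delta_ms) {
  n <- round(total_ms / raster)
  g <- numeric(n)
  d_n <- round(delta_ms / raster)
  g[seq_len(d_n)] <- G
  st2 <- round(Delta_ms / raster)
  g[st2 + seq_len(d_n)] <- -G
  g
}

# Stejskal-Tanner closed form, s/mm^2 (the independent b-value oracle)
pgse_b_closed_form <- function(G, delta_ms, Delta_ms,
                               gamma = 267.52218744e6) {
  gamma^2 * (G * 1e-3)^2 * (delta_ms * 1e-3)^2 *
    (Delta_ms * 1e-3 - delta_ms * 1e-3 / 3) / 1e6
}
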