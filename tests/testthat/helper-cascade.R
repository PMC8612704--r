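# deterministic parameter set: every spread zero, no frame noise
noise_free_params <- function(crisis = 4, tau = 0.5, ...) {
  cascade_params(crisis_time = c(mean = crisis, sd = 0, min = crisis, max = crisis),
                 offset_mito_stop_to_ca = c(mean = 0.42, sd = 0),
                 offset_tmrm_to_ca_min = c(mean = 7.9, sd = 0),
                 offset_ca_to_ps = c(mean = 0.51, sd = 0),
                 offset_ca_to_degeneration = c(mean = 100 / 60, sd = 0),
                 fragmentation_delay = c(mean = 0.25, sd = 0),
                 atp = list(tau = tau, tau_sd = 0, arrest_level = 0.15,
                            onset_level = 0.9),
                 motility = list(baseline_fraction = 0.3, n_mito = 20,
                                 gamma = 0.5, gamma_sd = 0,
                                 stall_jitter_sd_h = 0,
                                 speed_um_per_bout = c(min = 6, max = 14),
                                 jitter_sd_um = 0.05),
                 frame_noise_cv = 0, ...)
}

# synthetic binary test image: one elongated strip plus nc discs of radius r
strip_and_discs <- function(nc = 0, r = 4, strip_rows = 15:18,
                            height = 64, width = 512) {
  m <- matrix(0, height, width)
  m[strip_rows, 1:round(width / 2)] <- 1
  if (nc > 0) {
    cx <- round(seq(width / 2 + 40, width - 20, length.out = nc))
    for (k in seq_len(nc)) {
      for (x in (cx[k] - r):(cx[k] + r)) for (y in (32 - r):(32 + r))
        if ((x - cx[k])^2 + (y - 32)^2 <= r^2) m[y, x] <- 1
    }
  }
  m
}
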