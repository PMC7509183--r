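# Shared fixtures, built in code at test time.

# Analytic half-cosine pulse with closed-form fiducials and features:
# baseline 1.0, upstroke 1.0 -> 2.0 over 0.2 s, descent back over 0.4 s.
# R-peak 0.1 s before the foot.  With the pulse starting at t0:
#   F = t0, M = t0 + 0.1, P = t0 + 0.2, M' = t0 + 0.4, F' = t0 + 0.6.
half_cosine_fixture <- function(fs = 250, lead_s = 1, tail_s = 1) {
  up_s <- 0.2; down_s <- 0.4
  n_lead <- round(lead_s * fs)
  t_up <- seq(0, up_s, by = 1 / fs)
  t_down <- seq(1 / fs, down_s, by = 1 / fs)
  pulse <- c(1.5 - 0.5 * cos(pi * t_up / up_s),
             1.5 + 0.5 * cos(pi * t_down / down_s))
  ppg <- c(rep(1, n_lead), pulse, rep(1, round(tail_s * fs)))
  f0 <- n_lead + 1L
  list(ppg = ppg, fs = fs,
       r_idx = f0 - round(0.1 * fs),
       f_idx = f0,
       m_idx = f0 + round(0.1 * fs),
       p_idx = f0 + round(0.2 * fs),
       mprime_idx = f0 + round(0.4 * fs),
       fprime_idx = f0 + round(0.6 * fs))
}

# Small noise-free sinus record used by several files (built once).
sinus_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(duration = 60, base_hr = 60, pvc_probability = 0,
                        svt_run_probability = 0, noise_sd_signal = 0,
                        seed = 3L)
      cache <<- c(simulate_record(cfg), list(config = cfg))
    }
    cache
  }
})

# Feature rows with known structure for model tests.
toy_feature_rows <- function(n = 40, seed = 1) {
  simulate_feature_cohort(n_patients = 1, n_beats = n, seed = seed)[[1]]
}
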