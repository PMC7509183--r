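test_that("R-peak detection is exact on noise-free simulated records", {
  sim <- sinus_sim()
  rp <- detect_r_peaks(sim$record$ecg, sim$config$fs)
  expect_equal(length(rp), nrow(sim$truth))
  expect_true(all(abs(rp - sim$truth$r_idx) <= 1))
})

test_that("flat or empty signals yield no R-peaks", {
  expect_equal(detect_r_peaks(rep(0, 1000), 250), integer(0))
  expect_equal(detect_r_peaks(rep(2.5, 1000), 250), integer(0))
  expect_error(detect_r_peaks(rep(0, 100), 250), "2 s")
})

test_that("R-peak sensitivity and precision stay high under noise", {
  cfg <- sim_config(duration = 120, pvc_probability = 0.1,
                    svt_run_probability = 0.06, noise_sd_signal = 0.05,
                    seed = 5)
  sim <- simulate_record(cfg)
  rp <- detect_r_peaks(sim$record$ecg, cfg$fs)
  tol <- round(0.02 * cfg$fs)
  tp <- sum(vapply(sim$truth$r_idx,
                   function(r) any(abs(rp - r) <= tol), logical(1)))
  expect_gte(tp / nrow(sim$truth), 0.98)   # sensitivity
  expect_gte(tp / length(rp), 0.98)        # precision
})

test_that("PPG fiducials of the half-cosine pulse match closed form", {
  fx <- half_cosine_fixture()
  fid <- locate_ppg_fiducials(fx$ppg, fx$r_idx, fx$fs)
  expect_equal(nrow(fid), 1)
  expect_lte(abs(fid$f_idx - fx$f_idx), 1)
  expect_lte(abs(fid$m_idx - fx$m_idx), 1)
  expect_lte(abs(fid$p_idx - fx$p_idx), 1)
  expect_lte(abs(fid$mprime_idx - fx$mprime_idx), 1)
  expect_lte(abs(fid$fprime_idx - fx$fprime_idx), 1)
})

test_that("fiducial ordering invariant holds on every returned beat", {
  cfg <- sim_config(duration = 120, pvc_probability = 0.1,
                    svt_run_probability = 0.06, noise_sd_signal = 0.03,
                    seed = 8)
  sim <- simulate_record(cfg)
  rp <- detect_r_peaks(sim$record$ecg, cfg$fs)
  fid <- locate_ppg_fiducials(sim$record$ppg, rp, cfg$fs)
  expect_gt(nrow(fid), 0)
  with(fid, {
    expect_true(all(r_idx < f_idx))
    expect_true(all(f_idx <= m_idx & m_idx <= p_idx))
    expect_true(all(p_idx <= mprime_idx & mprime_idx <= fprime_idx))
    expect_true(all(f_idx - r_idx >= 0.05 * cfg$fs))
    expect_true(all(f_idx - r_idx <= 0.5 * cfg$fs + 1))
  })
})

test_that("R-peaks with no following PPG pulse are skipped and counted", {
  fx <- half_cosine_fixture()
  # a second R-peak far in the flat tail has no pulse to pair with
  fid <- locate_ppg_fiducials(fx$ppg, c(fx$r_idx, length(fx$ppg) - 100L),
                              fx$fs)
  expect_equal(nrow(fid), 1)
  expect_equal(attr(fid, "skipped"), 1L)
})

test_that("IBP cycle delimitation needs a closing trough", {
  fs <- 250
  # two beats, but the pressure keeps rising after the second trough:
  # only the first cycle closes
  t <- (0:(3 * fs - 1)) / fs
  ibp <- 90 + 20 * sin(2 * pi * t)          # troughs at 0.75 s and 1.75 s
  ibp[t > 2] <- ibp[t > 2][1] + 10 * (t[t > 2] - 2)
  r_peaks <- c(round(0.55 * fs), round(1.55 * fs))
  cyc <- detect_ibp_cycles(ibp, r_peaks, fs)
  expect_lte(nrow(cyc), 1)
  expect_error(detect_ibp_cycles(ibp, r_peaks[1], fs), "two R-peaks")
  # constant pressure: no troughs, no cycles
  expect_equal(nrow(detect_ibp_cycles(rep(90, 3 * fs), r_peaks, fs)), 0)
})

test_that("quality filter excludes exactly the outlying-energy beat", {
  # ten beats whose segment energies are [1,1,...,1,100]
  energies <- c(rep(1, 9), 100)
  seg_len <- 4L
  ppg <- numeric(0)
  beats <- NULL
  for (e in energies) {
    a <- sqrt(e / seg_len)
    f <- length(ppg) + 1L
    ppg <- c(ppg, rep(c(-a, a), seg_len / 2))
    beats <- rbind(beats, data.frame(
      beat_index = length(energies), r_idx = f, f_idx = f,
      m_idx = f + 1L, p_idx = f + 1L, mprime_idx = f + 2L,
      fprime_idx = f + seg_len))
  }
  beats$beat_index <- seq_along(energies)
  qf <- ppg_quality_filter(ppg, beats)
  expect_equal(qf$energy, energies)
  expect_equal(qf$excluded$beat_index, 10L)
  expect_equal(nrow(qf$kept), 9)
  expect_equal(nrow(qf$kept) + nrow(qf$excluded), nrow(beats))
})

test_that("equal energies exclude nothing and tiny inputs error", {
  ppg <- rep(c(-1, 1), 20)
  beats <- data.frame(beat_index = 1:5, r_idx = seq(1, 33, by = 8),
                      f_idx = seq(1, 33, by = 8),
                      m_idx = seq(2, 34, by = 8), p_idx = seq(2, 34, by = 8),
                      mprime_idx = seq(3, 35, by = 8),
                      fprime_idx = seq(9, 41, by = 8))
  qf <- ppg_quality_filter(ppg, beats)
  expect_equal(nrow(qf$excluded), 0)
  expect_error(ppg_quality_filter(ppg, beats[1:2, ]), "insufficient beats")
})
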