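fx <- half_cosine_fixture()
fid <- list(r_idx = fx$r_idx, f_idx = fx$f_idx, m_idx = fx$m_idx,
            p_idx = fx$p_idx, mprime_idx = fx$mprime_idx,
            fprime_idx = fx$fprime_idx)
tol_t <- 2 / fx$fs  # two-sample quantisation

test_that("transit times are exact index arithmetic", {
  p <- compute_ptts(list(r_idx = 0, f_idx = 30, m_idx = 55, p_idx = 80), 250)
  expect_equal(p, list(PTTrf = 0.12, PTTrm = 0.22, PTTrp = 0.32))
  expect_error(compute_ptts(list(r_idx = 30, f_idx = 30, m_idx = 55,
                                 p_idx = 80), 250), "ordering")
  p2 <- compute_ptts(fid, fx$fs)
  expect_equal(p2$PTTrf, 0.1, tolerance = tol_t)
  expect_equal(p2$PTTrm, 0.2, tolerance = tol_t)
  expect_equal(p2$PTTrp, 0.3, tolerance = tol_t)
})

test_that("ascending-edge features match the half-cosine closed form", {
  a <- compute_ascending(fx$ppg, fid, fx$fs)
  expect_equal(a$AT, 0.2, tolerance = tol_t)
  expect_equal(a$AS, 5.0, tolerance = 0.15)
  expect_equal(a$FAS, 5.0, tolerance = 0.15)
  # integral of (I - I_F) over the upstroke is 0.1 intensity-seconds
  expect_equal(a$SYSAREA, 0.1 * fx$fs, tolerance = 0.02 * 0.1 * fx$fs)
  expect_false(a$degenerate)
})

test_that("descending-edge features match the half-cosine closed form", {
  d <- compute_descending(fx$ppg, fid, fx$fs)
  expect_equal(d$DT, 0.4, tolerance = tol_t)
  expect_equal(d$DS, 2.5, tolerance = 0.1)
  expect_equal(d$FDS, 2.5, tolerance = 0.1)
  expect_equal(d$DIAAREA, 0.2 * fx$fs, tolerance = 0.02 * 0.2 * fx$fs)
  expect_false(d$degenerate)
})

test_that("a linear ramp has unit slope and symmetric pulses equal slopes", {
  fs <- 100
  ramp <- c(rep(1, 10), 1 + (1:fs) / fs, rep(2, 10))
  rfid <- list(f_idx = 10L, m_idx = 60L, p_idx = 110L)
  expect_equal(compute_ascending(ramp, rfid, fs)$AS, 1.0, tolerance = 0.02)
  # symmetric triangle: DS equals AS
  tri <- c(rep(1, 5), 1 + (1:50) / 50, 2 - (1:50) / 50, rep(1, 5))
  tfid <- list(f_idx = 5L, m_idx = 30L, p_idx = 55L,
               mprime_idx = 80L, fprime_idx = 105L)
  expect_equal(compute_ascending(tri, tfid, fs)$AS,
               compute_descending(tri, tfid, fs)$DS)
})

test_that("flat edges are flagged degenerate", {
  flat <- rep(1, 120)
  ffid <- list(f_idx = 10L, m_idx = 30L, p_idx = 50L,
               mprime_idx = 70L, fprime_idx = 90L)
  expect_true(compute_ascending(flat, ffid, 100)$degenerate)
  expect_true(compute_descending(flat, ffid, 100)$degenerate)
})

test_that("ratio, width, rate and shape features follow their definitions", {
  s <- compute_scalar_features(fx$ppg, fid, NULL, fx$fs)
  expect_equal(s$PIR, 2.0, tolerance = 0.02)
  expect_equal(s$PW, 0.3, tolerance = tol_t)
  expect_true(is.na(s$HR))       # first beat: no preceding peak
  expect_equal(s$K, 0.5, tolerance = 0.02)
  prev <- list(p_idx = fid$p_idx - 250L)
  expect_equal(compute_scalar_features(fx$ppg, fid, prev, 250)$HR, 1.0)
  neg <- fx$ppg - 2
  expect_error(compute_scalar_features(neg, fid, NULL, fx$fs),
               "non-positive baseline")
})

test_that("scaling the PPG leaves ratios and times unchanged and scales slopes and areas", {
  c0 <- 3.7
  scaled <- 1 + c0 * (fx$ppg - 1)  # scale pulse about zero-intensity origin
  # PIR/K are ratio features: scale the whole signal instead
  a1 <- compute_ascending(fx$ppg, fid, fx$fs)
  a2 <- compute_ascending(c0 * fx$ppg, fid, fx$fs)
  d1 <- compute_descending(fx$ppg, fid, fx$fs)
  d2 <- compute_descending(c0 * fx$ppg, fid, fx$fs)
  expect_equal(a2$AT, a1$AT)
  expect_equal(d2$DT, d1$DT)
  expect_equal(a2$AS, c0 * a1$AS)
  expect_equal(a2$FAS, c0 * a1$FAS)
  expect_equal(a2$SYSAREA, c0 * a1$SYSAREA)
  expect_equal(d2$DS, c0 * d1$DS)
  expect_equal(d2$FDS, c0 * d1$FDS)
  expect_equal(d2$DIAAREA, c0 * d1$DIAAREA)
  s1 <- compute_scalar_features(fx$ppg, fid, NULL, fx$fs)
  s2 <- compute_scalar_features(c0 * fx$ppg, fid, NULL, fx$fs)
  expect_equal(s2$PIR, s1$PIR)
  expect_equal(s2$K, s1$K)
  expect_equal(s2$PW, s1$PW)
})

test_that("time-shifting all channels changes no feature", {
  shift <- 37L
  ppg2 <- c(rep(1, shift), fx$ppg)
  fid2 <- lapply(fid, function(i) i + shift)
  expect_equal(compute_ptts(fid2, fx$fs), compute_ptts(fid, fx$fs))
  expect_equal(compute_ascending(ppg2, fid2, fx$fs),
               compute_ascending(fx$ppg, fid, fx$fs))
  expect_equal(compute_descending(ppg2, fid2, fx$fs),
               compute_descending(fx$ppg, fid, fx$fs))
})

test_that("feature table covers every paired beat except the first", {
  sim <- sinus_sim()
  ft <- extract_beat_features(
    sim$record,
    beat_labels = data.frame(time_s = sim$truth$beat_time,
                             beat_type = sim$truth$beat_type))
  expect_equal(nrow(ft), nrow(sim$truth) - 1)  # first beat lacks HR
  expect_true(all(ft$PTTrf > 0 & ft$PTTrf < ft$PTTrm & ft$PTTrm < ft$PTTrp))
  expect_true(all(ft$AT > 0 & ft$DT > 0 & ft$PW > 0 & ft$HR > 0))
  expect_true(all(ft$SYSAREA >= 0 & ft$DIAAREA >= 0))
  expect_true(all(ft$PIR > 0 & ft$K > 0 & ft$K < 1))
  expect_true(all(ft$beat_type == "sinus"))
  # measured transit time tracks the generative one
  expect_lt(max(abs(ft$PTTrf - sim$truth$true_ptt[ft$beat_index])),
            2 / sim$config$fs + 1e-9)
})

test_that("empty beat list errors", {
  sim <- sinus_sim()
  empty <- data.frame(beat_index = integer(0))
  expect_error(build_feature_table(sim$record, empty, empty), "empty")
})
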