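test_that("sliding RMS is a causal window RMS with partial warm-up", {
  expect_equal(sliding_rms(rep(3, 100), 100, 0.1), rep(3, 100))
  expect_equal(sliding_rms(rep(0, 50), 100, 0.1), rep(0, 50))
  # unit sinusoid over an integer number of periods -> 1/sqrt(2)
  fs <- 1000
  x <- sin(2 * pi * 10 * (0:1999) / fs)   # window 0.1 s = 1 period
  r <- sliding_rms(x, fs, 0.1)
  expect_lt(max(abs(r[200:2000] - 1 / sqrt(2))), 1e-3)
  expect_error(sliding_rms(numeric(0), 100, 0.1), "empty")
  # causality: output at t depends only on x[1..t]
  x2 <- x; x2[1500:2000] <- 5
  expect_equal(sliding_rms(x2, fs, 0.1)[1:1499], r[1:1499])
})

test_that("onset detection applies threshold, sides and refractory period", {
  cfg <- labeling_config(threshold_left = 1)
  fs <- 250
  silent <- rep(0.2, 1000)
  expect_equal(nrow(detect_onsets(silent, silent, fs, cfg)), 0)
  # two crossings 200 ms apart under a 300 ms refractory -> one event
  rms <- rep(0.2, 1000)
  rms[301:320] <- 2    # crossing at sample 301
  rms[351:370] <- 2    # 50 samples = 200 ms later
  ev <- detect_onsets(rms, rep(0.2, 1000), fs, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 300 / fs)
  expect_equal(ev$side, "LEFT")
  # sides follow the trace that crossed
  ev2 <- detect_onsets(rep(0.2, 1000), rms, fs, cfg)
  expect_equal(ev2$side, "RIGHT")
  expect_error(detect_onsets(rms, rms[-1], fs, cfg), "equal length")
  expect_error(labeling_config(threshold_left = 0), "> 0")
})

test_that("detected events on random bursty traces respect the refractory gap", {
  cfg <- labeling_config(threshold_left = 1, refractory_s = 0.3)
  set.seed(13)
  for (rep in 1:20) {
    rms_l <- abs(rnorm(2000, sd = 0.3))
    rms_r <- abs(rnorm(2000, sd = 0.3))
    burst_at <- sample(100:1900, 12)
    for (b in burst_at) rms_l[b:(b + 5)] <- 3
    ev <- detect_onsets(rms_l, rms_r, 250, cfg)
    if (nrow(ev) > 1) expect_gte(min(diff(ev$onset_s)), 0.3 - 1e-9)
  }
})

test_that("movement epochs cover [-pre, +post) and drop boundary events", {
  fs <- 250
  rec <- recording(matrix(seq_len(3 * 3000), 3, 3000, byrow = TRUE), fs,
                   c("C3", "C4", "EMGL"), c("EEG", "EEG", "EMG"))
  cfg <- labeling_config(threshold_left = 1)
  ev <- data.frame(onset_s = 10, side = "LEFT")
  es <- extract_movement_epochs(rec, ev, cfg)
  expect_equal(dim(es$epochs), c(1, 2, 100))  # EEG channels only, 0.4 s
  # window starts at onset - 0.1 s: sample index round(9.9 * 250) + 1
  expect_equal(es$epochs[1, 1, 1], rec$data[1, round(9.9 * fs) + 1])
  expect_equal(es$labels, 1L)
  ev2 <- data.frame(onset_s = c(0.05, 10), side = c("LEFT", "RIGHT"))
  expect_warning(es2 <- extract_movement_epochs(rec, ev2, cfg), "dropped")
  expect_equal(dim(es2$epochs)[1], 1)
  expect_equal(es2$labels, 2L)
  es0 <- extract_movement_epochs(rec, data.frame(onset_s = numeric(0),
                                                 side = character(0)), cfg)
  expect_equal(dim(es0$epochs)[1], 0)
  rec_no_eeg <- recording(matrix(0, 1, 100), fs, "EMGL", "EMG")
  expect_error(extract_movement_epochs(rec_no_eeg, ev, cfg), "EEG")
})

test_that("rest epochs tile quiet intervals away from movements", {
  fs <- 250
  rec <- recording(matrix(rnorm(2 * 2500), 2, 2500), fs, c("C3", "EMGL"),
                   c("EEG", "EMG"))
  cfg <- labeling_config(threshold_left = 1)
  no_events <- data.frame(onset_s = numeric(0), side = character(0))
  rest <- extract_rest_epochs(rec, no_events, cfg)
  expect_equal(dim(rest$epochs)[1], floor(10 / 0.4))   # counting oracle
  expect_equal(rest$class_names, "NO_MOVEMENT")
  # events every 0.6 s leave no quiet interval of 0.5 s
  busy <- data.frame(onset_s = seq(0.3, 9.9, by = 0.6),
                     side = "LEFT")
  expect_equal(dim(extract_rest_epochs(rec, busy, cfg)$epochs)[1], 0)
  # one event at 5 s: rest only from [0, 4.5] and [5.5, 10]
  one <- data.frame(onset_s = 5, side = "LEFT")
  r1 <- extract_rest_epochs(rec, one, cfg)
  n1 <- dim(r1$epochs)[1]
  expect_equal(n1, floor(4.5 / 0.4) + floor(4.5 / 0.4))
  # subsampling caps the count deterministically
  r2 <- extract_rest_epochs(rec, one, cfg, max_epochs = 5, seed = 3)
  expect_equal(dim(r2$epochs)[1], 5)
  expect_identical(extract_rest_epochs(rec, one, cfg, max_epochs = 5,
                                       seed = 3)$epochs, r2$epochs)
})

test_that("epoch sets combine into fixed 2- or 3-class order", {
  fs <- 250
  mov <- epoch_set(array(rnorm(4 * 2 * 100), dim = c(4, 2, 100)),
                   c(1, 2, 1, 2), c("LEFT", "RIGHT"), fs, c(0.1, 0.3),
                   c("C3", "C4"))
  rest <- epoch_set(array(rnorm(3 * 2 * 100), dim = c(3, 2, 100)),
                    rep(1, 3), "NO_MOVEMENT", fs, c(0.1, 0.3),
                    c("C3", "C4"))
  two <- build_epochset(mov, include_rest = FALSE)
  expect_equal(two$class_names, c("LEFT", "RIGHT"))
  three <- build_epochset(mov, rest, include_rest = TRUE)
  expect_equal(three$class_names, c("LEFT", "RIGHT", "NO_MOVEMENT"))
  expect_equal(dim(three$epochs)[1], 7)                # conservation
  expect_equal(tabulate(three$labels), c(2, 2, 3))
  empty_rest <- subset_epochs(rest, integer(0))
  expect_error(build_epochset(mov, empty_rest, include_rest = TRUE),
               "more movement-free data")
  bad <- rest; bad$channel_names <- c("C3", "Cz")
  expect_error(build_epochset(mov, bad, include_rest = TRUE),
               "different channel sets")
})

test_that("labeling recovers planted squeezes from a synthetic stream", {
  sim <- synth_stream(62, list(left = seq(2, 60, 4), right = seq(4, 60, 4)),
                      synth_config(seed = 31))
  out <- label_recording(sim$recording,
                         labeling_config(threshold_left = 2))
  expect_equal(nrow(out$events), nrow(sim$events))
  err_ms <- vapply(seq_len(nrow(sim$events)), function(i) {
    same <- out$events$onset_s[out$events$side == sim$events$side[i]]
    min(abs(same - sim$events$onset_s[i])) * 1000
  }, numeric(1))
  expect_lt(max(err_ms), 20)
  expect_equal(sort(table(out$epochs$labels)), sort(table(sim$events$side)),
               ignore_attr = TRUE)
})
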