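test_that("EDF files written by the package read back correctly", {
  rec <- recording(matrix(sin(seq_len(3000) / 7), 3, 1000, byrow = TRUE) *
                     c(5, 20, 80), 250, c("C3", "C4", "Cz"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  r2 <- read_edf(path)
  expect_equal(r2$fs, 250)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(dim(r2$data), dim(rec$data))
  # values round-trip to 16-bit quantization of the per-channel range
  for (ch in 1:3) {
    rng <- diff(range(rec$data[ch, ]))
    expect_lt(max(abs(r2$data[ch, ] - rec$data[ch, ])), rng / 65535 + 1e-9)
  }
})

test_that("malformed EDF files raise format errors", {
  empty <- withr::local_tempfile(fileext = ".edf")
  writeLines("", empty)
  expect_error(read_edf(empty), "format error")
  expect_error(read_edf("no/such/file.edf"), "not found")
  # duplicate channel labels: patch the second label to match the first
  rec <- recording(matrix(rnorm(200), 2, 100), 100, c("A", "B"))
  dup <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, dup)
  con <- file(dup, "r+b")
  seek(con, 256 + 16, rw = "write")                 # second 16-byte label
  writeChar(formatC("A", width = 16, flag = "-"), con, eos = NULL)
  close(con)
  expect_error(read_edf(dup), "duplicate")
})

test_that("epoch container round-trips losslessly", {
  set.seed(8)
  for (rep in 1:100) {
    es <- rand_epoch_set(n = sample(1:6, 1), n_channels = sample(1:4, 1),
                         n_samples = sample(c(5, 8, 10), 1),
                         n_classes = sample(2:3, 1), seed = rep)
    path <- tempfile()
    write_epochs(es, path)
    es2 <- read_epochs(path)
    expect_identical(es2$epochs, es$epochs)       # bit-exact arrays
    expect_identical(es2$labels, es$labels)
    expect_identical(es2$class_names, es$class_names)
    expect_identical(es2$window, es$window)
    expect_identical(es2$channel_names, es$channel_names)
    file.remove(path)
  }
})

test_that("epoch container handles degenerate and malformed inputs", {
  es0 <- epoch_set(array(0, dim = c(0, 2, 5)), integer(0), c("A", "B"),
                   10, c(0, 0.5), c("X", "Y"))
  path <- withr::local_tempfile()
  write_epochs(es0, path)
  back <- read_epochs(path)
  expect_equal(dim(back$epochs), c(0, 2, 5))
  # missing labels field
  bad <- withr::local_tempfile()
  con <- file(bad, "wb")
  writeChar(bcinet:::EPOCHS_MAGIC, con, eos = NULL)
  hdr <- charToRaw('{"dims":[0,1,1]}')
  writeBin(as.numeric(length(hdr)), con, size = 8, endian = "little")
  writeBin(hdr, con)
  close(con)
  expect_error(read_epochs(bad), "missing field")
  # wrong magic
  txt <- withr::local_tempfile()
  writeLines("not an epoch container", txt)
  expect_error(read_epochs(txt), "magic")
})

test_that("band-pass plus notch suppresses mains and passes the band", {
  fs <- 1000
  t <- (0:3999) / fs
  mid <- 1500:2500
  r50 <- recording(matrix(sin(2 * pi * 50 * t), 1), fs, "A")
  r10 <- recording(matrix(sin(2 * pi * 10 * t), 1), fs, "A")
  f50 <- bandpass_notch(r50, 0.5, 100, 50)
  f10 <- bandpass_notch(r10, 0.5, 100, 50)
  att50 <- 20 * log10(sd(f50$data[1, mid]) / sd(r50$data[1, mid]))
  att10 <- 20 * log10(sd(f10$data[1, mid]) / sd(r10$data[1, mid]))
  expect_lt(att50, -40)       # mains removed
  expect_gt(att10, -1)        # pass band intact
  z <- bandpass_notch(recording(matrix(0, 1, 2000), fs, "A"), 0.5, 100, 50)
  expect_equal(max(abs(z$data)), 0)
  expect_error(bandpass_notch(r50, 0, 100, 50), "low_hz")
  expect_error(bandpass_notch(r50, 1, 600, 50), "low_hz")
})

test_that("decimation preserves constants and sub-Nyquist tones", {
  rc <- recording(matrix(3.5, 1, 4000), 1000, "A")
  dc <- decimate_recording(rc, 250)
  expect_equal(dc$fs, 250)
  expect_equal(ncol(dc$data), 1000)
  expect_lt(max(abs(dc$data[1, 100:900] - 3.5)), 1e-6)
  t <- (0:3999) / 1000
  ds <- decimate_recording(recording(matrix(sin(2 * pi * 10 * t), 1),
                                     1000, "A"), 250)
  ref <- sin(2 * pi * 10 * (0:999) / 250)
  expect_lt(max(abs(ds$data[1, 100:900] - ref[100:900])), 0.02)
  # identity when target equals current rate
  expect_identical(decimate_recording(rc, 1000), rc)
  expect_error(decimate_recording(rc, 300), "integer factor")
})

test_that("decimation keeps tone frequencies to within one spectral bin", {
  set.seed(5)
  for (rep in 1:5) {
    f0 <- sample(5:40, 1)
    t <- (0:7999) / 1000
    rec <- recording(matrix(sin(2 * pi * f0 * t), 1), 1000, "A")
    dec <- decimate_recording(rec, 250)
    n <- ncol(dec$data)
    spec <- Mod(fft(dec$data[1, ]))[1:(n / 2)]
    f_peak <- (which.max(spec) - 1) * 250 / n
    expect_lt(abs(f_peak - f0), 250 / n + 1e-9)
  }
})

test_that("epoch demeaning removes means, preserves variance, idempotent", {
  es <- rand_epoch_set(n = 4, n_channels = 3, n_samples = 10, seed = 2)
  es$epochs[1, 1, ] <- 1:10 + 100        # strong DC offset
  dm <- demean_epochs(es)
  expect_lt(max(abs(apply(dm$epochs, c(1, 2), mean))), 1e-10)
  expect_equal(apply(dm$epochs, c(1, 2), var),
               apply(es$epochs, c(1, 2), var))
  expect_equal(demean_epochs(dm)$epochs, dm$epochs)   # idempotent
  expect_equal(dm$epochs[1, 1, ], (1:10) - 5.5)
  # global mode removes one mean per epoch only
  gl <- demean_epochs(es, per_channel = FALSE)
  expect_lt(max(abs(apply(gl$epochs, 1, mean))), 1e-10)
})
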