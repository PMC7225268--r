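test_that("templates scale exactly to the requested peak-to-peak amplitude", {
  tpl <- make_template("biphasic", 100, 3)
  expect_equal(max(tpl$waveform) - min(tpl$waveform), 100)
  expect_length(tpl$waveform, 37)

  t50 <- make_template("biphasic", 50, 1)
  t100 <- make_template("biphasic", 100, 1)
  expect_equal(t100$waveform, 2 * t50$waveform)

  # trough on the detection-alignment sample for both shapes
  expect_equal(which.min(make_template("triphasic", 80, 7)$waveform), 13)
  expect_equal(which.min(tpl$waveform), 13)

  expect_error(make_template("biphasic", -5, 1), class = "imetk_invalid_parameter")
  expect_error(make_template("biphasic", 50, 1, neighbor_attenuation = 1),
               class = "imetk_invalid_parameter")
})

test_that("unit-free sessions reproduce the requested noise SD", {
  ss <- simulate_session(session_spec(duration = 60, n_channels = 2,
                                      noise_sd = 5, seed = 11))
  expect_equal(nrow(ss$truth$spikes), 0)
  for (ch in 1:2)
    expect_lt(abs(sd(ss$session$traces[ch, ]) - 5) / 5, 0.02)
})

test_that("simulation is seed-deterministic, bit for bit", {
  spec <- session_spec(duration = 2, noise_sd = 4,
                       units = list(list(template = make_template("biphasic", 80, 1),
                                         rate = 5)),
                       artifact_rate = 10, seed = 99)
  a <- simulate_session(spec)
  b <- simulate_session(spec)
  expect_identical(a$session$traces, b$session$traces)
  expect_identical(a$truth, b$truth)
})

test_that("spike counts follow the Poisson law up to the refractory correction", {
  spec <- session_spec(duration = 60, n_channels = 1, noise_sd = 5,
                       units = list(list(template = make_template("biphasic", 80, 1),
                                         rate = 5)),
                       seed = 21)
  n <- nrow(simulate_session(spec)$truth$spikes)
  # Poisson(300) 99% interval
  expect_gt(n, qpois(0.005, 300) - 5)  # small slack for refractory thinning
  expect_lt(n, qpois(0.995, 300))

  # dispersion at low rate over repeated short sessions
  counts <- vapply(1:40, function(i) {
    s <- session_spec(duration = 10, n_channels = 1, noise_sd = 5,
                      units = list(list(template = make_template("biphasic", 80, 1),
                                        rate = 2)),
                      seed = 300 + i)
    nrow(simulate_session(s)$truth$spikes)
  }, 1L)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.5)
  expect_lt(disp, 1.6)
})

test_that("inserted spikes land where the ground truth says", {
  tpl <- make_template("biphasic", 200, 1)
  spec <- session_spec(duration = 4, n_channels = 1, noise_sd = 1,
                       units = list(list(template = tpl, rate = 4)), seed = 31)
  ss <- simulate_session(spec)
  for (s in ss$truth$spikes$sample) {
    w <- ss$session$traces[1, (s - 12):(s + 24) + 1]
    expect_lt(abs(min(w) - min(tpl$waveform)), 6)   # trough present at site
  }
})

test_that("artifact transients are recorded as disjoint half-open windows", {
  ss <- simulate_session(session_spec(duration = 10, noise_sd = 5,
                                      artifact_rate = 30, seed = 41))
  w <- ss$truth$artifact_windows
  expect_gt(nrow(w), 0)
  expect_true(all(w[, 2] > w[, 1]))
  if (nrow(w) > 1) expect_true(all(w[-1, 1] >= w[-nrow(w), 2]))
  expect_true(all(w >= 0 & w <= 10 * 24400))
})

test_that("recording binary + sidecar roundtrip preserves traces to float32", {
  ss <- simulate_session(session_spec(duration = 0.5, n_channels = 3,
                                      noise_sd = 5, seed = 51))
  path <- withr::local_tempfile()
  write_recording(ss$session, path, meta = list(seed = 51))
  rt <- read_recording(path)
  expect_equal(rt$sampling_rate, 24400)
  expect_equal(dim(rt$traces), dim(ss$session$traces))
  expect_lt(max(abs(rt$traces - ss$session$traces)), 1e-4)

  gt_path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(ss$truth, gt_path)
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  expect_equal(gt$noise_sd, rep(5, 3))
})

test_that("invalid session specs are rejected", {
  expect_error(session_spec(duration = 0), class = "imetk_invalid_parameter")
  expect_error(session_spec(duration = 1, noise_sd = 0),
               class = "imetk_invalid_parameter")
  long_tpl <- make_template("biphasic", 50, 1, snippet_length = 200000,
                            align_sample = 100000)
  expect_error(
    simulate_session(session_spec(duration = 0.01, n_channels = 1,
                                  units = list(list(template = long_tpl,
                                                    rate = 1)), seed = 1)),
    class = "imetk_invalid_parameter")
})
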