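channel_row <- function(channel, working, n_units, noise_level, amp) {
  tibble::tibble(channel = channel, working = working, n_units = n_units,
                 noise_level = noise_level, amp = amp)
}

test_that("working-channel classification applies the noise band", {
  set.seed(6)
  tr <- matrix(rnorm(16 * 30000, sd = 5), 16)
  s <- recording_session(tr, 24400)
  expect_true(all(classify_working_channels(s)))

  dead <- s
  dead$traces[3, ] <- rnorm(30000, sd = 0.1)
  expect_false(classify_working_channels(dead)[3])
  expect_true(all(classify_working_channels(dead)[-3]))

  loud <- s
  loud$traces[9, ] <- rnorm(30000, sd = 60)
  expect_false(classify_working_channels(loud)[9])

  expect_error(classify_working_channels(s, noise_floor = 10, noise_ceiling = 5),
               class = "imetk_invalid_parameter")
})

test_that("the five session metrics match hand computation", {
  tbl <- channel_row(1:4, c(TRUE, TRUE, TRUE, FALSE), c(2L, 0L, 1L, 5L),
                     c(10, 12, 8, 100),
                     list(c(100, 60), numeric(0), 50, c(1, 1, 1, 1, 1)))
  m <- compute_session_metrics(tbl)
  expect_equal(m$pct_channels_with_units, 100 * 2 / 3)
  expect_equal(m$units_per_channel, 1)
  expect_equal(m$noise_level, 10)
  # metric 4: per-channel mean then mean over unit-bearing channels
  expect_equal(m$max_amplitude, mean(c(mean(c(100, 60)), 50)))
  # metric 5: per-unit amplitude / own channel noise, averaged across units
  expect_equal(m$snr, mean(c(100 / 10, 60 / 10, 50 / 8)))
  expect_equal(m$n_working, 3L)

  # single unit: snr = amplitude / noise level exactly
  one <- channel_row(1L, TRUE, 1L, 10, list(100))
  expect_equal(compute_session_metrics(one)$snr, 10)

  # no units anywhere: metrics 4 and 5 are NA, not zero
  none <- channel_row(1:2, TRUE, c(0L, 0L), c(10, 10),
                      list(numeric(0), numeric(0)))
  m0 <- compute_session_metrics(none)
  expect_true(is.na(m0$max_amplitude) && is.na(m0$snr))
  expect_equal(m0$pct_channels_with_units, 0)

  expect_error(compute_session_metrics(channel_row(1L, FALSE, 0L, 10,
                                                   list(numeric(0)))),
               class = "imetk_degenerate_input")
})

test_that("noise metric is unbiased: 2x the true SD on unit-free noise", {
  set.seed(7)
  lvls <- replicate(60, {
    tr <- rnorm(24400, sd = 5)
    2 * estimate_noise_sd(tr)
  })
  expect_lt(abs(mean(lvls) - 10) / 10, 0.02)
})

test_that("active-window selection maximizes the sum with smallest-start ties", {
  expect_equal(select_active_window(c(1, 0, 3, 2, 0, 1), 3), 2)  # channels 2-4
  expect_equal(select_active_window(rep(0, 8), 3), 1)
  expect_equal(select_active_window(1:5, 5), 1)
  expect_error(select_active_window(1:4, 5), class = "imetk_invalid_parameter")
})

test_that("window selection equals brute force on random arrays", {
  set.seed(8)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    w <- sample(1:n, 1)
    a <- round(runif(n, 0, 3), 1)   # rounded to force frequent ties
    expect_identical(select_active_window(a, w), brute_force_window(a, w))
  }
})

test_that("weeks map to total/acute/chronic bins", {
  expect_setequal(assign_time_bins(1), c("total", "acute"))
  expect_setequal(assign_time_bins(2), c("total", "acute"))
  expect_setequal(assign_time_bins(3), c("total", "chronic"))
  expect_setequal(assign_time_bins(5), c("total", "chronic"))
  expect_setequal(assign_time_bins(8), c("total", "chronic"))
  expect_error(assign_time_bins(9), class = "imetk_invalid_parameter")
  expect_error(assign_time_bins(0), class = "imetk_invalid_parameter")
})

test_that("study table restricts metrics to each animal's fixed window", {
  # 2 animals x 2 weeks x 2 sessions -> 8 rows
  spec <- study_spec(groups = c(rat = 1L, mouse = 1L), weeks = 2, seed = 10)
  tbl <- build_study_table(study_channel_truth(simulate_study(spec)))
  expect_equal(nrow(tbl), 8)
  expect_equal(length(unique(tbl$window_start[tbl$animal == "rat_01"])), 1)

  # a unit-rich channel outside the window must not leak into the metrics
  ct <- tibble::tibble(
    group = "rat", animal = "r1", week = rep(1:2, each = 16),
    session = 1L, channel = rep(1:16, 2), working = TRUE,
    n_units = rep(c(rep(2L, 10), 0L, 0L, 0L, 0L, 0L, 9L), 2),
    noise_level = 10,
    amp = rep(c(rep(list(c(50, 70)), 10), rep(list(numeric(0)), 5),
                list(rep(400, 9))), 2))
  tb <- build_study_table(ct, windows = c(rat = 10L))
  expect_equal(unique(tb$window_start), 1)
  expect_equal(unique(tb$units_per_channel), 2)
  expect_equal(unique(tb$max_amplitude), 60)   # the 400 uV channel is outside

  expect_error(build_study_table(ct, windows = c(mouse = 8L)),
               class = "imetk_invalid_parameter")
})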