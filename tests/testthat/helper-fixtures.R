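# Shared fixtures, all generated in code.

# a session with known units on known channels; amplitudes all >= 7x noise SD
recovery_session <- function(seed, duration = 6, noise_sd = 5) {
  chs <- c(2, 5, 9, 12, 14)
  amps <- list(120, c(60, 180), 90, 75, 140)
  units <- list()
  k <- 0
  for (i in seq_along(chs)) for (a in amps[[i]]) {
    k <- k + 1
    units[[k]] <- list(
      template = make_template(if (k %% 2) "biphasic" else "triphasic",
                               amplitude_pp = a, primary_channel = chs[i]),
      rate = 6 + (k %% 4))
  }
  simulate_session(session_spec(duration = duration, n_channels = 16,
                                noise_sd = noise_sd, units = units,
                                seed = seed))
}

# detection recall against ground truth, tolerance in samples
detection_recall <- function(channels_tbl, truth, tol = 12) {
  crossings <- sort(unlist(channels_tbl$detections))
  if (nrow(truth$spikes) == 0) return(NA_real_)
  mean(vapply(truth$spikes$sample,
              function(s) any(abs(crossings - s) <= tol), TRUE))
}

# small uniform box + materials for elasticity fixtures
box_fixture <- function(l = 100, n = 3, E = 6e3, nu = 0.43) {
  mesh <- mesh_box(l, l, l, n, n, n)
  sys <- assemble_elasticity(mesh, list(tissue = list(young_modulus = E,
                                                      poisson_ratio = nu)))
  list(mesh = mesh, sys = sys)
}

boundary_nodes <- function(mesh, l) {
  tol <- 1e-9
  which(apply(mesh$nodes, 1, function(p)
    any(p < tol) || any(abs(p - l) < tol)))
}

# brute-force window maximizer used as the oracle for select_active_window
brute_force_window <- function(avg_units, window) {
  n <- length(avg_units)
  sums <- round(vapply(seq_len(n - window + 1),
                       function(s) sum(avg_units[s:(s + window - 1)]), 1.0), 9)
  which(sums == max(sums))[1]
}

# normal-theory metric observations for GLM calibration tests (fast path,
# independent of the study generator)
normal_observations <- function(seed, n_a = 6, n_b = 14, sessions = 16,
                                animal_sd = 0.4, session_sd = 0.4,
                                effect_a = 0) {
  set.seed(seed)
  rows <- list()
  for (g in c("a", "b")) {
    n_g <- if (g == "a") n_a else n_b
    for (i in seq_len(n_g)) {
      mu <- rnorm(1, 0, animal_sd) + if (g == "a") effect_a else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, animal = paste0(g, i),
        value = mu + rnorm(sessions, 0, session_sd))
    }
  }
  dplyr::bind_rows(rows)
}
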