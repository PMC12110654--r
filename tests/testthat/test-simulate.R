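test_that("simulation is deterministic under a fixed seed", {
  cfg <- td_sim_config(duration_s = 60, seed = 101)
  s1 <- simulate_dyad(cfg)
  s2 <- simulate_dyad(cfg)
  expect_identical(s1$speaker$az, s2$speaker$az)
  expect_identical(s1$listener$ax, s2$listener$ax)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dyad(td_sim_config(duration_s = 60, seed = 102))
  expect_false(identical(s1$speaker$az, s3$speaker$az))
})

test_that("config validation enforces rates, probabilities and separation", {
  expect_error(dyad_sim_config(speaker_nod_rate_per_min = 80),
               "density too high")
  expect_error(dyad_sim_config(response_prob = 1.2), "response_prob")
  expect_error(dyad_sim_config(nod_amplitude_z = 1.5), "nod_amplitude_z")
  expect_error(dyad_sim_config(noise_sd = 0), "noise_sd")
})

test_that("an unresponsive listener yields zero matched events end to end", {
  cfg <- dyad_sim_config(duration_s = 60, response_prob = 0,
                         spontaneous_listener_rate_per_min = 0, seed = 103)
  sim <- simulate_dyad(cfg)
  expect_length(sim$truth$listener_event_times, 0)
  fit <- dyad_synchrony(sim$speaker, sim$listener)
  expect_equal(fit$features$n_events, 0)
  expect_equal(fit$features$density_per_min, 0)
})

test_that("the detector recovers the planted events (recall/precision)", {
  for (s in c(104, 105, 106)) {
    sim <- simulate_dyad(td_sim_config(duration_s = 300, seed = s))
    fit <- dyad_synchrony(sim$speaker, sim$listener)
    for (side in c("speaker", "listener")) {
      truth <- sim$truth[[paste0(side, "_event_times")]]
      det <- fit[[paste0(side, "_peaks")]]$peak_times
      hits <- vapply(truth, function(e) any(abs(det - e) < 0.25), logical(1))
      expect_gte(mean(hits), 0.95)                       # recall
      fp <- length(det) - sum(vapply(truth, function(e)
        sum(abs(det - e) < 0.25), numeric(1)))
      expect_lte(fp / max(1, length(truth)), 0.05)       # false positives
    }
  }
})

test_that("matched lags track the planted response lags", {
  sim <- simulate_dyad(td_sim_config(duration_s = 600, seed = 107))
  fit <- dyad_synchrony(sim$speaker, sim$listener)
  cp <- sim$truth$coupled_pairs
  # locate the detected speaker peak nearest each coupled speaker event and
  # read off the matched lag recovered by the pipeline
  pd <- match_peaks(fit$speaker_peaks, fit$listener_peaks,
                    dyad_id = "x", duration_min = 10)
  sp <- fit$speaker_peaks$peak_times
  lp <- fit$listener_peaks$peak_times
  rec <- vapply(seq_len(nrow(cp)), function(k) {
    i <- which.min(abs(sp - cp$speaker_time[k]))
    j <- which.min(abs(lp - cp$listener_time[k]))
    (lp[j] - sp[i]) * 1000
  }, numeric(1))
  keep <- abs(rec) <= 1000
  expect_gt(cor(rec[keep], cp$true_lag_ms[keep]), 0.9)
})

test_that("pipeline output converges to the generative parameters", {
  # density: rate * response_prob with no spontaneous nods
  cfg <- dyad_sim_config(duration_s = 1200, response_prob = 0.41,
                         spontaneous_listener_rate_per_min = 0, seed = 108)
  sim <- simulate_dyad(cfg)
  fit <- dyad_synchrony(sim$speaker, sim$listener)
  expect_lt(abs(fit$features$density_per_min - 23.3 * 0.41), 1.5)

  # lag mean and jitter: tight low-noise regime over a long session
  cfg2 <- dyad_sim_config(duration_s = 1800, response_prob = 0.8,
                          response_lag_mean_ms = 90, response_lag_sd_ms = 50,
                          spontaneous_listener_rate_per_min = 0, seed = 109)
  sim2 <- simulate_dyad(cfg2)
  fit2 <- dyad_synchrony(sim2$speaker, sim2$listener)
  expect_lt(abs(fit2$features$mean_ms - 90), 10)
  expect_lt(abs(fit2$features$sd_ms - 50), 15)
})

test_that("group study corpora are written, readable and byte-stable", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg_td <- td_sim_config(duration_s = 20)
  cfg_asd <- asd_sim_config(duration_s = 20)
  res <- simulate_group_study(cfg_td, cfg_asd, n_dyads_per_group = 2,
                              seed = 9, out_dir = dir1)
  expect_length(res$dyads, 4)
  expect_equal(sum(grepl("_speaker|_listener",
                         list.files(dir1, pattern = "csv$"))), 8)
  m <- read_manifest(file.path(dir1, "manifest.yaml"))
  expect_length(m, 4)
  expect_setequal(vapply(m, `[[`, "", "group"), c("TD", "ASD"))

  simulate_group_study(cfg_td, cfg_asd, n_dyads_per_group = 2, seed = 9,
                       out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = paste("md5 of", f))
  }
  # ground truth sidecar exists and parses
  gt <- jsonlite::fromJSON(file.path(dir1, "ground_truth.json"))
  expect_setequal(names(gt), res$dyad_ids)
})

test_that("in-memory corpora separate the two regimes on density", {
  res <- simulate_group_study(td_sim_config(duration_s = 240),
                              asd_sim_config(duration_s = 240),
                              n_dyads_per_group = 6, seed = 10,
                              out_dir = NULL)
  feats <- do.call(rbind, lapply(seq_along(res$dyads), function(i) {
    d <- res$dyads[[i]]
    fit <- dyad_synchrony(d$speaker, d$listener, dyad_id = d$dyad_id)
    cbind(data.frame(dyad_id = d$dyad_id, group = res$groups[i]),
          as.data.frame(fit$features)[-1])
  }))
  td <- feats$density[feats$group == "TD"]
  asd <- feats$density[feats$group == "ASD"]
  expect_gt(mean(td), mean(asd))
})
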