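test_that("dyad_synchrony returns a coherent fitted object", {
  sim <- simulate_dyad(td_sim_config(duration_s = 120, seed = 201))
  fit <- dyad_synchrony(sim$speaker, sim$listener, dyad_id = "demo")
  expect_s3_class(fit, "dyad_synchrony")
  expect_named(coef(fit), c("density", "mean_ms", "sd_ms", "kurtosis"))
  expect_equal(fit$features$n_events, length(fit$phase_diffs$diffs_ms))
  expect_equal(fit$duration_min, 2, tolerance = 0.01)
  expect_output(print(fit), "demo")
  s <- summary(fit)
  expect_output(print(s), "events within")
  expect_true(s$central_mass >= 0 && s$central_mass <= 1)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  h <- plot(fit)
  expect_s3_class(h, "phase_histogram")
})

test_that("an explicit window trims both traces before fitting", {
  sim <- simulate_dyad(td_sim_config(duration_s = 120, seed = 202))
  fit <- dyad_synchrony(sim$speaker, sim$listener, window = c(10, 70))
  expect_equal(fit$duration_min, 1)
  expect_true(all(fit$speaker_peaks$peak_times >= 10 &
                    fit$speaker_peaks$peak_times < 70))
})

test_that("simulate() on a fit draws dyads at the fitted parameters", {
  sim <- simulate_dyad(td_sim_config(duration_s = 300, seed = 203))
  fit <- dyad_synchrony(sim$speaker, sim$listener)
  reps <- simulate(fit, nsim = 2, seed = 99)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "dyad_sim")
  reps2 <- simulate(fit, nsim = 2, seed = 99)
  expect_identical(reps[[1]]$speaker$az, reps2[[1]]$speaker$az)
})

test_that("cmd_analyze processes a manifest and tolerates failing sessions", {
  dir <- withr::local_tempdir()
  corpus <- simulate_group_study(td_sim_config(duration_s = 60),
                                 asd_sim_config(duration_s = 60),
                                 n_dyads_per_group = 2, seed = 30,
                                 out_dir = dir)
  out <- withr::local_tempdir()
  feats <- cmd_analyze(corpus$manifest_path, out)
  expect_equal(nrow(feats), 4)
  expect_equal(attr(feats, "exit_code"), 0L)
  expect_true(file.exists(file.path(out, "features.csv")))
  expect_true(file.exists(file.path(out, "run.log")))
  expect_length(list.files(out, pattern = "_histogram.csv$"), 4)

  # identical rerun gives identical outputs
  out2 <- withr::local_tempdir()
  cmd_analyze(corpus$manifest_path, out2)
  expect_identical(readLines(file.path(out, "features.csv")),
                   readLines(file.path(out2, "features.csv")))

  # a missing file fails that session only, with exit code 2
  m <- read_manifest(corpus$manifest_path)
  m[[2]]$speaker_file <- file.path(dir, "nope.csv")
  feats2 <- cmd_analyze(m, out_dir = NULL)
  expect_equal(nrow(feats2), 3)
  expect_named(attr(feats2, "failures"), m[[2]]$dyad_id)
  expect_equal(attr(feats2, "exit_code"), 2L)
})

test_that("cmd_compare reports the four features and honors exclusions", {
  set.seed(31)
  feats <- data.frame(dyad_id = sprintf("D%02d", 1:20),
                      group = rep(c("TD", "ASD"), each = 10),
                      n_events = rpois(20, 50),
                      density = c(rnorm(10, 9.6, 2), rnorm(10, 6, 2)),
                      mean_ms = rnorm(20, 90, 60),
                      sd_ms = c(rnorm(10, 310, 50), rnorm(10, 385, 80)),
                      kurtosis = rnorm(20, 0.5, 0.9))
  tab <- cmd_compare(feats)
  expect_setequal(names(tab), c("density", "mean_ms", "sd_ms", "kurtosis"))
  expect_equal(tab$density$df, 18)
  # identical groups give t ~= 0
  same <- feats
  same[11:20, c("density", "mean_ms", "sd_ms", "kurtosis")] <-
    same[1:10, c("density", "mean_ms", "sd_ms", "kurtosis")]
  tab0 <- cmd_compare(same)
  expect_equal(tab0$density$t_stat, 0, tolerance = 1e-9)
  # exclusion drops one dyad from its group
  tab_ex <- cmd_compare(feats, exclude = "D03")
  expect_equal(tab_ex$density$df, 17)
  # JSON/text report files
  out <- withr::local_tempdir()
  cmd_compare(feats, out_json = file.path(out, "stats.json"),
              out_txt = file.path(out, "stats.txt"))
  js <- jsonlite::fromJSON(file.path(out, "stats.json"))
  expect_equal(js$density$df, 18)
  expect_gt(length(readLines(file.path(out, "stats.txt"))), 2)
})

test_that("cmd_simulate drives the generator from a scenario list", {
  out <- withr::local_tempdir()
  res <- cmd_simulate(list(td = list(duration_s = 20),
                           asd = list(duration_s = 20),
                           n_dyads_per_group = 2, seed = 5), out)
  expect_length(res$dyads, 4)
  expect_true(file.exists(file.path(out, "manifest.yaml")))
})
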