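# Scenario-level behaviour on reduced networks (30-60 neurons per level)
# keeps these checks fast; the full-size regime checks live in
# test-acceptance.R.

test_that("identical seed and configuration give identical results", {
  a <- run_scenario("subthreshold", seed = 6, n_per_level = 30, warmup = 50,
                    n_cycles = 2)
  b <- run_scenario("subthreshold", seed = 6, n_per_level = 30, warmup = 50,
                    n_cycles = 2)
  expect_identical(a$hr_trace, b$hr_trace)
  expect_identical(a$activity_map, b$activity_map)
  expect_identical(a$on_mask, b$on_mask)
})

test_that("the baseline scenario has no ON intervals and classifies none", {
  r <- run_scenario("baseline", seed = 2, n_per_level = 30, warmup = 50,
                    n_cycles = 2)
  expect_false(any(r$on_mask))
  expect_identical(r$classification, "none")
  expect_true(all(r$activity_map >= 0 & r$activity_map <= 1))
  expect_equal(dim(r$activity_map),
               c(nrow(r$network$neurons), length(r$on_mask)))
})

test_that("turning the direct component off recovers the sympathetic-threshold trace", {
  # parasympathetic threshold differs from sympathetic threshold only
  # through the direct pathway
  sy <- run_scenario("sympathetic_threshold", seed = 3, n_per_level = 30,
                     warmup = 50, n_cycles = 2)
  pa_proto <- scenario_preset("parasympathetic_threshold", n_cycles = 2)
  pa_proto$direct_increment <- 0
  ablated <- run_scenario("custom", seed = 3, protocol = pa_proto,
                          n_per_level = 30, warmup = 50)
  expect_identical(ablated$hr_by_interval, sy$hr_by_interval)
  expect_identical(ablated$activity_map, sy$activity_map)
})

test_that("with a_r = 0 the trace is independent of the direct pathway state", {
  p0 <- vns_parameters(a_r = 0, beta_H_direct = 0.5, beta_D_direct = 0.5)
  p1 <- vns_parameters(a_r = 0, beta_H_direct = 0, beta_D_direct = 0)
  a <- run_scenario("baseline", seed = 1, n_per_level = 30, warmup = 40,
                    n_cycles = 1, parameters = p0)
  b <- run_scenario("baseline", seed = 1, n_per_level = 30, warmup = 40,
                    n_cycles = 1, parameters = p1)
  expect_identical(a$hr_by_interval, b$hr_by_interval)
})

test_that("response classification thresholds the ON-OFF mean difference", {
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  expect_identical(classify_response(rep(0.4, 4), mask), "none")
  expect_identical(classify_response(c(0.5, 0.5, 0.3, 0.3), mask),
                   "tachycardia")
  expect_identical(classify_response(c(0.2, 0.2, 0.5, 0.5), mask),
                   "bradycardia")
  # margin is respected
  expect_identical(classify_response(c(0.41, 0.41, 0.4, 0.4), mask), "none")
  # degenerate masks classify none
  expect_identical(classify_response(rep(0.9, 3), rep(FALSE, 3)), "none")
  expect_identical(classify_response(rep(0.9, 3), rep(TRUE, 3)), "none")
  expect_error(classify_response(1:3 / 10, c(TRUE, FALSE)), "length")
})

test_that("activity difference maps are antisymmetric and zero on identical runs", {
  a <- run_scenario("baseline", seed = 5, n_per_level = 30, warmup = 40,
                    n_cycles = 1)
  b <- run_scenario("subthreshold", seed = 5, n_per_level = 30, warmup = 40,
                    n_cycles = 1)
  expect_true(all(activity_difference_map(a, a) == 0))
  d_ab <- activity_difference_map(a, b)
  expect_equal(d_ab, -activity_difference_map(b, a))
  expect_true(all(d_ab >= -1 & d_ab <= 1))
  # a stimulated run differs from its same-seed baseline
  expect_gt(mean(abs(d_ab)), 0)
  small <- run_scenario("baseline", seed = 5, n_per_level = 12, warmup = 40,
                        n_cycles = 1)
  expect_error(activity_difference_map(a, small), "dimensions")
})

test_that("the scenario summary reports ranges and per-level means consistently", {
  r <- run_scenario("sympathetic_threshold", seed = 2, n_per_level = 30,
                    warmup = 50, n_cycles = 2)
  s <- summary(r)
  expect_identical(s$classification, r$classification)
  expect_equal(s$hr_delta, s$hr_mean_on - s$hr_mean_off)
  lm <- s$level_means$mean_activity
  expect_true(all(lm[!is.na(lm)] >= 0 & lm[!is.na(lm)] <= 1))
  # hand-computed per-level mean on the toy fixture
  toy <- toy_network(seed = 1)
  rt <- run_scenario("baseline", seed = 1, network = toy, warmup = 10,
                     n_cycles = 1)
  st <- summary(rt)
  post <- seq_along(rt$on_mask) > 10
  sel <- toy$neurons$branch == "sympathetic" & toy$neurons$level == 2
  expect_equal(
    st$level_means$mean_activity[st$level_means$branch == "sympathetic" &
                                   st$level_means$level == 2],
    mean(rt$activity_map[sel, post]))
})

test_that("scenario exports and the config document round-trip on disk", {
  r <- run_scenario("subthreshold", seed = 7, n_per_level = 12, warmup = 20,
                    n_cycles = 1)
  dir <- withr::local_tempdir()
  write_scenario(r, dir)
  expect_true(all(file.exists(file.path(dir,
    c("hr_trace.csv", "hr_by_interval.csv", "activity_map.tsv",
      "summary.json", "config.yaml", "run_log.txt")))))
  tr <- read.csv(file.path(dir, "hr_trace.csv"))
  expect_equal(tr$H_scaled, r$hr_trace$H_scaled)
  # config document round-trip
  cfg <- run_config(protocol = vns_protocol(delta_H_sens = 0.003),
                    seed = 7, network_args = list(n_per_level = 12))
  path <- file.path(dir, "cfg.yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$parameters, cfg$parameters)
  expect_equal(back$protocol, cfg$protocol)
  # a run driven by the config equals the directly-specified run
  r1 <- run_from_config(path, warmup = 20)
  r2 <- run_scenario("custom", seed = 7,
                     protocol = vns_protocol(delta_H_sens = 0.003),
                     n_per_level = 12, warmup = 20)
  expect_identical(r1$hr_by_interval, r2$hr_by_interval)
})
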