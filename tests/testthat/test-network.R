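test_that("networking increment is the weighted sum of neighbour differences", {
  net <- two_neuron_net(w = 0.5)
  st <- network_state(net, activity = c(0.6, 0.8))
  expect_equal(networking_delta(net, st, 1), 0.5 * (0.8 - 0.6))  # 0.1
  # neuron 2 has no outgoing edges
  expect_identical(networking_delta(net, st, 2), 0)
  # equal activities: differences vanish
  st_eq <- network_state(net, activity = 0.7)
  expect_identical(networking_delta(net, st_eq, 1), 0)
  # zero weights
  net0 <- two_neuron_net(w = 0)
  expect_identical(networking_delta(net0, st, 1), 0)
  expect_error(networking_delta(net, st, 99), "unknown neuron identifier")
})

test_that("heart-rate and blood-demand increments follow the branch-signed forms", {
  # zero sensitivity gives zero increment
  expect_identical(heart_rate_delta("sympathetic", 0, 0.3, 0.9), 0)
  expect_identical(blood_demand_delta("parasympathetic_indirect", 0, 0.3, 0.9), 0)
  # balanced input: driving input equal to the network-mean reference
  expect_equal(heart_rate_delta("sympathetic", 1, 0.4, 0.4), 0)
  # independent transcription: symp -beta_H*(H_d - M), parasym mirrored
  expect_equal(heart_rate_delta("sympathetic", 1, 0.7, 0.4), -(0.7 - 0.4))
  expect_equal(heart_rate_delta("parasympathetic_indirect", 1, 0.7, 0.4),
               +(0.7 - 0.4))
  expect_equal(blood_demand_delta("sympathetic", 0.3, 0.6, 0.2),
               0.3 * (0.6 - 0.2))
  # linear scaling in the sensitivity
  expect_equal(blood_demand_delta("sympathetic", 0.6, 0.6, 0.2),
               2 * blood_demand_delta("sympathetic", 0.3, 0.6, 0.2))
  # branch opposition for identical inputs
  for (h in c(0.1, 0.5, 0.9)) {
    ds <- heart_rate_delta("sympathetic", 0.2, h, 0.33)
    dp <- heart_rate_delta("parasympathetic_indirect", 0.2, h, 0.33)
    expect_equal(ds, -dp)
  }
})

test_that("one network step equals the per-neuron brute-force sum of the three increments", {
  net <- toy_network(seed = 7)
  st <- network_state(net, activity = seq(0.05, 0.95, length.out = 12))
  H_d <- 0.35; D <- 0.22
  new <- update_network(st, net, H_d, D)
  expect_identical(new$activity, oracle_step(net, st$activity, H_d, D))
  expect_identical(new$k, st$k + 1L)
})

test_that("activities stay in [0,1] and clip at the bounds", {
  net <- toy_network(seed = 3, beta_H = 0.5, beta_D = 0.5, w0 = 0.3)
  st <- network_state(net, activity = rep(c(0.02, 0.98), 6))
  for (k in 1:50) {
    st <- update_network(st, net, H_delayed = 0.9, D = 0.1)
    expect_true(all(st$activity >= 0 & st$activity <= 1))
  }
  # a neuron already at 1 receiving a positive total increment stays at 1
  net1 <- two_neuron_net(w = 0)
  st1 <- network_state(net1, activity = c(1, 1))
  new <- update_network(st1, net1, H_delayed = 0, D = 1)  # symp HR excited
  expect_equal(new$activity[1], 1)
})

test_that("zero sensitivities and weights make the update the identity", {
  net <- toy_network(seed = 2, beta_H = 0, beta_D = 0, w0 = 0)
  x0 <- seq(0.13, 0.91, length.out = 12)
  st <- network_state(net, activity = x0)
  new <- update_network(st, net, 0.7, 0.1)
  expect_identical(new$activity, x0)
})

test_that("with zero weights each neuron's trajectory ignores the others only through the mean", {
  # with w0 = 0 and beta = 0 for all but one neuron, permuting the other
  # neurons' activities (keeping the network mean fixed) leaves that
  # neuron's trajectory unchanged
  net <- toy_network(seed = 2, beta_H = 0.2, beta_D = 0.2, w0 = 0)
  x <- seq(0.1, 0.65, length.out = 12)
  st1 <- network_state(net, activity = x)
  x_perm <- x; x_perm[2:12] <- x[c(12:3, 2)]   # same mean, same multiset
  st2 <- network_state(net, activity = x_perm)
  n1 <- update_network(st1, net, 0.5, 0.2)
  n2 <- update_network(st2, net, 0.5, 0.2)
  expect_equal(n1$activity[1], n2$activity[1])
})

test_that("mean cardiac activity averages level-1 neurons of the requested branch", {
  neurons <- data.frame(
    id = 1:4, level = c(1L, 1L, 1L, 2L), index = c(1:3, 1L),
    branch = c(rep("sympathetic", 3), "parasympathetic_indirect"),
    class = "heart_rate", beta_H = 0.1, beta_D = 0,
    stringsAsFactors = FALSE)
  net <- vnsnet:::as_vns_network(neurons,
                                 data.frame(from = integer(0),
                                            to = integer(0),
                                            weight = numeric(0)))
  st <- network_state(net, activity = c(0.2, 0.4, 0.9, 0.5))
  expect_equal(mean_cardiac_activity(st, net, "sympathetic"), 0.5)
  st1 <- network_state(net, activity = c(1, 1, 1, 0))
  expect_equal(mean_cardiac_activity(st1, net, "sympathetic"), 1)
  st0 <- network_state(net, activity = 0)
  expect_equal(mean_cardiac_activity(st0, net, "sympathetic"), 0)
  # no parasympathetic neuron at level 1 here
  expect_error(mean_cardiac_activity(st, net, "parasympathetic_indirect"),
               "cardiac level")
})

test_that("neuron table invariants are enforced", {
  neurons <- data.frame(
    id = 1:2, level = c(1L, 3L), index = c(1L, 1L),
    branch = "sympathetic", class = c("heart_rate", "blood_demand"),
    beta_H = c(0.1, 0.2), beta_D = c(0, 0.1), stringsAsFactors = FALSE)
  # blood-demand neuron with beta_H != 0
  expect_error(vnsnet:::as_vns_network(
    neurons, data.frame(from = integer(0), to = integer(0),
                        weight = numeric(0))), "beta_H = 0")
  neurons$beta_H <- c(0.1, 0)
  # edge across two levels
  expect_error(vnsnet:::as_vns_network(
    neurons, data.frame(from = 1L, to = 2L, weight = 0.1)),
    "adjacent level")
})

test_that("network round-trips through TSV", {
  net <- toy_network(seed = 5)
  stem <- file.path(withr::local_tempdir(), "net")
  write_network_tsv(net, stem)
  back <- read_network_tsv(stem)
  expect_equal(back$neurons, net$neurons)
  expect_equal(back$edges, net$edges)
  expect_equal(as.matrix(back$W), as.matrix(net$W))
})
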