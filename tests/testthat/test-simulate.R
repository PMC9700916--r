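empty_model <- function(lambda = 1) {
  hill_model(data.frame(regulator = character(), target = character(),
                        sign = numeric(), b = numeric(), K = numeric()),
             gene_names = c("a", "b"), lambda = lambda)
}

test_that("Euler decay matches the closed form with O(dt) error that halves", {
  m <- empty_model()
  err <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    ts <- simulate_hill(m, c(1, 1), times = c(0, 1), dt_int = dt)
    abs(ts$values[2, 1] - exp(-1))
  }, numeric(1))
  expect_lt(err[2], 0.005)
  # halving dt halves the error (within 20%)
  expect_gt(err[1] / err[2], 2 * 0.8)
  expect_lt(err[1] / err[2], 2 * 1.2)
  expect_gt(err[2] / err[3], 2 * 0.8)
  expect_lt(err[2] / err[3], 2 * 1.2)
})

test_that("constant synthesis settles at the fixed point f / lambda", {
  # single activator at saturation supplies f ~ b, so steady state ~ b
  m <- hill_model(data.frame(regulator = "a", target = "b", sign = 1,
                             b = 0.8, K = 0.01),
                  gene_names = c("a", "b"), clamped = "a", lambda = 1)
  ts <- simulate_hill(m, c(5, 0), times = seq(0, 30, 5), input = 5)
  expect_equal(unname(ts$values[7, "b"]), 0.8, tolerance = 1e-3)
})

test_that("clamped genes follow the imposed trajectory exactly", {
  m <- hill_model(data.frame(regulator = "a", target = "b", sign = 1,
                             b = 1, K = 1),
                  gene_names = c("a", "b"), clamped = "a")
  input <- function(t) 0.3 + 0.1 * sin(t)
  ts <- simulate_hill(m, c(0.3, 0), times = seq(0, 10), input = input)
  expect_equal(ts$values[, "a"], vapply(ts$times, input, numeric(1)))
  # with every gene clamped the output is exactly the imposed trajectories
  m2 <- hill_model(data.frame(regulator = character(), target = character(),
                              sign = numeric(), b = numeric(), K = numeric()),
                   gene_names = c("a", "b"), clamped = c("a", "b"))
  inp2 <- function(t) c(1 + t / 10, 2 - t / 10)
  ts2 <- simulate_hill(m2, c(1, 2), times = seq(0, 5), input = inp2)
  expect_equal(unname(ts2$values),
               t(vapply(ts2$times, inp2, numeric(2))))
})

test_that("integration reports the first non-finite step", {
  m <- hill_model(data.frame(regulator = "a", target = "b", sign = 1,
                             b = 1, K = 1),
                  gene_names = c("a", "b"), clamped = "a")
  bad_basal <- function(t) c(0, if (t >= 0.5) Inf else 0)
  expect_error(
    simulate_hill(m, c(1, 0), times = c(0, 2), input = 1, basal = bad_basal),
    "non-finite state at integration step"
  )
})

test_that("adaptation scoring reads baseline, peak and residual offset", {
  tt <- 0:20
  g <- c(rep(1, 5), 1, 3, 2.2, 1.6, 1.3, rep(1.2, 11))
  ts <- expression_ts(cbind(out = g, other = rep(2, 21)), tt)
  s <- score_adaptation(ts, "out", stimulus_time = 5)
  expect_equal(s$baseline, 1)
  expect_equal(s$sensitivity, 2)
  expect_equal(s$adaptation_error, 0.2)
  expect_equal(s$peak_time, 6)
  expect_true(s$settled)
  # constant trajectory: no response at all
  ts0 <- expression_ts(cbind(out = rep(2, 21), other = rep(1, 21)), tt)
  s0 <- score_adaptation(ts0, "out", stimulus_time = 5)
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$adaptation_error, 0)
  # invariant to adding an all-constant gene
  ts1 <- expression_ts(cbind(out = g, other = rep(2, 21), pad = rep(7, 21)), tt)
  expect_equal(score_adaptation(ts1, "out", 5), s)
  # unsettled trajectories are flagged
  ts2 <- expression_ts(cbind(out = seq(1, 3, length.out = 21),
                             other = rep(1, 21)), tt)
  expect_false(score_adaptation(ts2, "out", 5)$settled)
  expect_error(score_adaptation(ts, "nope", 5), "unknown")
  expect_error(score_adaptation(ts, "out", 99), "inside the time grid")
})

test_that("preset circuits respond to an input pulse and recover", {
  m <- make_preset_circuit("adapt_feedback")
  times <- seq(0, 120, by = 1)
  input <- function(t) if (t >= 40 && t < 70) 1 else 0.5
  ts <- simulate_hill(m, c(0.5, 0, 0), times = times, input = input)
  s <- score_adaptation(ts, "g3", 40)
  expect_gt(s$sensitivity, 0.1)
  expect_lt(s$adaptation_error, 0.05 * s$sensitivity)
  # the adaptive-IFFL preset adapts even while the stimulus persists
  m2 <- make_preset_circuit("iffl_adaptive")
  ts2 <- simulate_hill(m2, c(0.5, 0, 0), times = times,
                       input = function(t) if (t < 40) 0.5 else 1)
  s2 <- score_adaptation(ts2, "g3", 40)
  expect_gt(s2$sensitivity, 0.2)
  expect_lt(s2$adaptation_error, 0.1 * s2$sensitivity)
})

test_that("the enumeration screen is deterministic and respects reachability", {
  # no path from input to output: output cannot respond
  topo <- matrix(0L, 3, 3)
  topo[2, 3] <- 1L  # only an internal edge; input g1 disconnected
  expect_equal(as.integer(topology_success_count(topo, 500, seed = 1)), 0L)
  # same seed, same count
  iffl <- topology(make_preset_circuit("iffl_minimal"))
  c1 <- topology_success_count(iffl, 3000, seed = 4)
  c2 <- topology_success_count(iffl, 3000, seed = 4)
  expect_identical(as.integer(c1), as.integer(c2))
  expect_equal(attr(c1, "rate"), as.integer(c1) / 3000)
})
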