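test_that("link knockout deltas obey identity and independence", {
  m <- make_preset_circuit("adapt_feedback")
  set.seed(2)
  states <- matrix(rexp(30), 10, 3)
  # mu = 1 is the identity discount
  expect_identical(link_knockout_delta(m, states, "g1", "g3", mu = 1), 0)
  # a model independent of the regulator gives delta 0
  m1 <- hill_model(data.frame(regulator = "a", target = "b", sign = 1,
                              b = 1, K = 1),
                   gene_names = c("a", "b", "c"))
  expect_equal(link_knockout_delta(m1, states, "c", "b", mu = 0), 0)
  # activator knocked out at mu = 0: delta is the activation term times the
  # inhibition product, evaluated in closed form
  st <- c(1.2, 0.4, 0.3)
  d <- link_knockout_delta(m, matrix(st, 1), "g1", "g3", mu = 0)
  expect_equal(d, hill_activation(1.2, 4.242, 1.198, 2) *
                    hill_inhibition(0.3, 0.231, 2), tolerance = 1e-12)
  expect_error(link_knockout_delta(m, states, "g1", "g3", mu = 1.2), "mu")
})

test_that("full-knockout magnitude dominates partial discounts on Hill oracles", {
  for (sd in 1:3) {
    rg <- generate_random_grn(n_genes = 6, density = 0.25, seed = sd)
    truth <- topology(rg$model)
    e <- which(truth != 0, arr.ind = TRUE)
    set.seed(sd)
    states <- matrix(rexp(60), 10, 6)
    for (r in seq_len(min(4, nrow(e)))) {
      ds <- vapply(c(0, 0.25, 0.5, 0.75), function(mu) {
        abs(link_knockout_delta(rg$model, states, e[r, 1], e[r, 2], mu = mu))
      }, numeric(1))
      expect_true(all(ds[1] >= ds - 1e-12))
    }
  }
})

test_that("knockout signs match the true topology on random Hill oracles", {
  hits <- 0
  for (sd in 1:20) {
    rg <- generate_random_grn(n_genes = 10, density = 0.15, seed = sd)
    truth <- topology(rg$model)
    set.seed(sd + 1000)
    states <- matrix(rexp(300), 30, 10)
    D <- knockout_deltas(rg$model, states, mu = 0)
    e <- which(truth != 0, arr.ind = TRUE)
    hits <- hits + all(sign(D[e]) == truth[e])
  }
  expect_equal(hits, 20)
})

test_that("network inference ranks, signs and thresholds candidate pairs", {
  m <- make_preset_circuit("adapt_feedback")
  series <- fb_series()
  net <- infer_network(m, series)
  # shape contract: all ordered pairs except those targeting the clamped input
  expect_equal(nrow(net), 3 * 2)
  expect_false(any(net$target == "g1"))
  expect_true(all(diff(net$weight) <= 0))
  # the oracle recovers the tabulated circuit's signed edges
  ed <- tidy(net)
  get_sign <- function(r, t) ed$sign[ed$regulator == r & ed$target == t]
  expect_equal(get_sign("g1", "g3"), 1L)
  expect_equal(get_sign("g3", "g3"), -1L)
  expect_equal(get_sign("g3", "g2"), -1L)
  # a constant (edge-free) model yields an all-zero, uncalled ranking
  m0 <- hill_model(data.frame(regulator = character(), target = character(),
                              sign = numeric(), b = numeric(), K = numeric()),
                   gene_names = c("a", "b"))
  net0 <- infer_network(m0, list(expression_ts(cbind(a = c(1, 2, 1), b = c(2, 1, 2)),
                                               0:2)))
  expect_true(all(net0$weight == 0))
  expect_true(all(net0$sign == 0L))
  # top-k binarisation calls exactly k edges
  net2 <- infer_network(m, series, top_k = 2)
  expect_equal(sum(net2$sign != 0), 2)
})

test_that("structure recovery holds on the noiseless adaptive-IFFL fixture", {
  # top-|true edges| inferred pairs equal the true signed edge set
  m <- iffl_circuit()
  truth <- topology(m)
  good <- 0
  for (sd in 1:3) {
    series <- generate_timeseries(m, n_series = 8, n_timepoints = 41,
                                  dt = 1, seed = sd)
    nn <- build_synthesis_model(c("g1", "g2", "g3"), seed = sd + 100,
                                clamped = "g1")
    nn <- train_synthesis(nn, series, epochs = 1200)
    ed <- tidy(infer_network(nn, series))[1:3, ]
    ok <- all(truth[cbind(match(ed$regulator, rownames(truth)),
                          match(ed$target, rownames(truth)))] ==
                sign(ed$delta))
    good <- good + ok
  }
  expect_gte(good, 2)
})

test_that("mutant simulation reproduces wild type at mu = 1 and signs effects", {
  m <- iffl_circuit()
  times <- seq(0, 30)
  input <- function(t) if (t >= 10) 1 else 0.5
  wt <- simulate_hill(m, c(0.5, 0, 0), times = times, input = input)
  same <- simulate_mutant(m, c("g2", "g3"), mu = 1,
                          initial_state = c(0.5, 0, 0), times = times,
                          input = input)
  expect_equal(same$values, wt$values)
  # knocking out the inhibitory edge raises the target everywhere
  ko <- simulate_mutant(m, c("g2", "g3"), mu = 0,
                        initial_state = c(0.5, 0, 0), times = times,
                        input = input)
  expect_true(all(ko$values[, "g3"] >= wt$values[, "g3"] - 1e-9))
  expect_gt(max(ko$values[, "g3"] - wt$values[, "g3"]), 0.1)
})

test_that("learned dynamics track the Hill truth and agree on mutant direction", {
  nn <- iffl_model()
  m <- iffl_circuit()
  obs <- unlist(lapply(iffl_series(), function(s) s$values[, "g1"]))
  lo <- unname(quantile(obs, 0.1)); hi <- unname(quantile(obs, 0.9))
  pre <- simulate_hill(m, c(lo, 0, 0), times = c(0, 30), input = lo)
  init <- pre$values[2, ]
  times <- seq(0, 40)
  input_raw <- function(t) if (t >= 10 && t < 25) hi else lo
  wt_h <- simulate_hill(m, init, times = times, input = input_raw)
  nrm <- function(v, g) (v - nn$norm$min[g]) / nn$norm$range[g]
  inp_n <- matrix(vapply(times, function(t) nrm(input_raw(t), "g1"),
                         numeric(1)), ncol = 1)
  init_n <- pmax(vapply(c("g1", "g2", "g3"), function(g) nrm(init[g], g),
                        numeric(1)), 0)
  wt_n <- rollout_synthesis(nn, init_n, n_steps = 40, input = inp_n)
  # wild-type rollout stays within 0.1 normalised units of the ground truth
  expect_lt(max(abs(wt_n$values[, "g3"] - nrm(wt_h$values[, "g3"], "g3"))), 0.1)
  # knocking the inhibitory edge raises the output in both models
  mu_h <- simulate_mutant(m, c("g2", "g3"), mu = 0, initial_state = init,
                          times = times, input = input_raw)
  mu_n <- simulate_mutant(nn, c("g2", "g3"), mu = 0, init = init_n,
                          n_steps = 40, input = inp_n)
  expect_true(all(mu_h$values[, "g3"] >= wt_h$values[, "g3"] - 1e-9))
  expect_gt(mean(mu_n$values[, "g3"] > wt_n$values[, "g3"]), 0.9)
})

test_that("pruning removes only dispensable links and never adds any", {
  nn <- iffl_model()
  pp <- prune_network(nn, iffl_series(), output_gene = "g3",
                      protocol = "step")
  trace <- tidy(pp)
  # edge counts are strictly decreasing along the path
  expect_true(all(diff(trace$n_edges) < 0))
  # function preserved within the declared tolerances at every step
  s0 <- trace$sensitivity[1]; e0 <- trace$adaptation_error[1]
  expect_true(all(trace$sensitivity >= (1 - 0.3) * s0))
  expect_true(all(trace$adaptation_error <= e0 + 0.15 * s0))
  # terminates at the 3-edge incoherent feed-forward motif, correctly signed
  fin <- pp$networks[[length(pp$networks)]]
  expect_equal(nrow(fin), 3)
  key <- paste(fin$regulator, fin$target, fin$sign)
  expect_setequal(key, c("g1 g3 1", "g1 g2 1", "g2 g3 -1"))
})

test_that("repeated vote tabulates a partition and injected oracles are unanimous", {
  series <- fb_series()
  m <- fb_circuit()
  res <- repeated_vote(series, n_repeats = 5, seed = 1,
                       train_fn = function(ts, seed) m)
  v <- res$votes
  expect_true(all(v$activated + v$absent + v$inhibited == 5))
  # a deterministic injected model votes identically every repeat
  expect_true(all(v$activated %in% c(0L, 5L) & v$inhibited %in% c(0L, 5L)))
  net <- res$network
  expect_s3_class(net, "grn_network")
  expect_true(all(net$weight == 1))
  # plurality calls
  expect_identical(plurality_call(39L, 0L, 1L), 1L)
  expect_identical(plurality_call(0L, 1L, 39L), -1L)
  expect_identical(plurality_call(5L, 5L, 0L), 0L)
  expect_identical(plurality_call(c(4L, 0L), c(1L, 1L), c(0L, 4L)), c(1L, -1L))
})
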