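#' Built-in adaptive three-gene circuits
#'
#' Returns one of the calibrated Hill circuits used throughout the package as
#' ground truth (Hill coefficient 2, degradation rate 1, gene `g1` clamped as
#' the input signal):
#'
#' * `"adapt_feedback"` — input activates both downstream genes; the
#'   intermediate `g2` activates the output `g3` and itself; the output
#'   inhibits the intermediate and itself (adaptation through negative
#'   feedback with a buffer node).
#' * `"adapt_iffl"` — input activates intermediate and output; the output
#'   activates the intermediate; both downstream genes self-inhibit and the
#'   intermediate inhibits the output (adaptation through an incoherent
#'   feed-forward path).
#' * `"iffl_minimal"` — the minimal 3-edge incoherent feed-forward loop:
#'   input activates output and intermediate, intermediate inhibits output
#'   (unit parameters; typically re-sampled by the enumeration screen).
#' * `"iffl_adaptive"` — the same 3-edge motif with a unit-exponential
#'   parameter draw calibrated by the package's enumeration screen: the
#'   output adapts to a sustained step of the input (sensitivity about 0.4,
#'   adaptation error below 5 percent of the peak for a 0.5 -> 1.0 step).
#'
#' @param name Preset name.
#' @return A `hill_model`.
#' @export
make_preset_circuit <- function(name) {
  g <- c("g1", "g2", "g3")
  edges <- switch(
    name,
    adapt_feedback = data.frame(
      regulator = c("g1", "g1", "g2", "g2", "g3", "g3"),
      target    = c("g3", "g2", "g3", "g2", "g2", "g3"),
      sign      = c(1, 1, 1, 1, -1, -1),
      b         = c(4.242, 0.691, 0.496, 1.499, NA, NA),
      K         = c(1.198, 0.708, 0.664, 1.300, 0.166, 0.231)
    ),
    adapt_iffl = data.frame(
      regulator = c("g1", "g1", "g3", "g3", "g2", "g2"),
      target    = c("g3", "g2", "g2", "g3", "g3", "g2"),
      sign      = c(1, 1, 1, -1, -1, -1),
      b         = c(2.148, 0.161, 0.178, NA, NA, NA),
      K         = c(1.573, 0.091, 0.051, 1.977, 0.976, 1.278)
    ),
    iffl_minimal = data.frame(
      regulator = c("g1", "g1", "g2"),
      target    = c("g3", "g2", "g3"),
      sign      = c(1, 1, -1),
      b         = c(1, 1, NA),
      K         = c(1, 1, 1)
    ),
    iffl_adaptive = data.frame(
      regulator = c("g1", "g1", "g2"),
      target    = c("g3", "g2", "g3"),
      sign      = c(1, 1, -1),
      b         = c(4.318, 3.115, NA),
      K         = c(0.752, 1.686, 0.684)
    ),
    stop("unknown preset circuit: ", name, call. = FALSE)
  )
  hill_model(edges, gene_names = g, hill_n = 2, lambda = 1, clamped = "g1")
}

#' Generate a random sparse regulatory network
#'
#' Erdos-Renyi-style signed topology over the (TF, gene) candidate space,
#' excluding self-edges, with an exact edge count of
#' `round(density * n_candidates)`. Roughly `inhibitory_frac` of edges are
#' inhibitory, except that every regulated gene keeps at least one activating
#' input (its first in-edge by regulator index): in the Hill formalism a gene
#' with only inhibitory inputs has synthesis rate identically zero, which
#' would silence those links. Parameters are drawn from the unit-rate
#' exponential via [sample_hill_parameters()]. The returned gold standard
#' matches the topology exactly.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription factors (the first `n_tfs` genes are
#'   the allowed regulators; default all genes).
#' @param density Target edge density in (0, 1).
#' @param inhibitory_frac Fraction of inhibitory edges (default 0.25).
#' @param seed Integer seed; the same seed reproduces the network exactly.
#' @param hill_n,lambda Hill model constants.
#' @return List with `model` (a `hill_model`) and `gold` (a
#'   [gold_standard()]).
#' @export
generate_random_grn <- function(n_genes = 100, n_tfs = n_genes,
                                density = 0.02, inhibitory_frac = 0.25,
                                seed = 1, hill_n = 2, lambda = 1) {
  if (density <= 0 || density >= 1) stop("`density` must be in (0, 1)", call. = FALSE)
  stopifnot(n_tfs <= n_genes)
  gene_names <- paste0("G", seq_len(n_genes))
  tfs <- gene_names[seq_len(n_tfs)]
  cand <- expand.grid(regulator = seq_len(n_tfs), target = seq_len(n_genes),
                      KEEP.OUT.ATTRS = FALSE)
  cand <- cand[cand$regulator != cand$target, ]
  m <- max(1L, as.integer(round(density * nrow(cand))))
  set.seed(as.integer(seed))
  pick <- cand[sample.int(nrow(cand), m), ]
  pick <- pick[order(pick$target, pick$regulator), ]
  sign <- ifelse(stats::runif(m) < inhibitory_frac, -1, 1)
  first_in <- !duplicated(pick$target)
  sign[first_in] <- 1
  topo <- matrix(0L, n_genes, n_genes, dimnames = list(gene_names, gene_names))
  topo[cbind(pick$regulator, pick$target)] <- as.integer(sign)
  model <- sample_hill_parameters(topo, hill_n = hill_n, lambda = lambda,
                                  seed = as.integer(seed) + 1L)
  gold <- gold_standard(
    tibble::tibble(regulator = gene_names[pick$regulator],
                   target = gene_names[pick$target]),
    gene_names = gene_names, tfs = tfs
  )
  list(model = model, gold = gold)
}

#' Generate perturbation time series from a Hill model
#'
#' Emulates the benchmark protocol in which a perturbation is applied and
#' later removed: each series starts at the unperturbed steady state, a
#' random perturbation acts over the first half of the horizon and is then
#' removed, and the trajectory is sampled on a uniform grid.
#'
#' For circuits with a clamped input gene the perturbation is a step of the
#' input: the baseline level is drawn from `baseline_range`, the step size
#' from `step_range`, and optional Gaussian white noise (`noise_sd`, held
#' piecewise constant between sample points and clipped at zero) is added to
#' the input trajectory. For autonomous networks the perturbation adds a
#' constant basal synthesis rate (drawn from `step_range`) to a random subset
#' of `perturb_frac` of the genes.
#'
#' @param model A `hill_model`.
#' @param n_series Number of independent series.
#' @param n_timepoints Samples per series (>= 2).
#' @param dt Sampling interval (time units).
#' @param noise_sd Standard deviation of Gaussian white noise on the clamped
#'   input signal (0 = noiseless).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param perturb_frac Fraction of genes perturbed per series for autonomous
#'   networks (default 0.3).
#' @param step_range,baseline_range Uniform ranges for perturbation sizes and
#'   input baselines.
#' @param dt_int Euler step of the simulator.
#' @param settle_time Pre-simulation horizon used to reach the initial steady
#'   state for input-driven circuits.
#' @return A list of [expression_ts].
#' @export
generate_timeseries <- function(model, n_series = 8, n_timepoints = 41,
                                dt = 1, noise_sd = 0, seed = 1,
                                perturb_frac = 0.3,
                                step_range = c(0.5, 1),
                                baseline_range = c(0.2, 0.6),
                                dt_int = 0.01, settle_time = 20) {
  stopifnot(inherits(model, "hill_model"), n_timepoints >= 2, n_series >= 1)
  set.seed(as.integer(seed))
  times <- seq(0, by = dt, length.out = n_timepoints)
  t_half <- times[length(times)] / 2
  out <- vector("list", n_series)
  for (s in seq_len(n_series)) {
    if (length(model$clamped)) {
      nc <- length(model$clamped)
      I0 <- stats::runif(nc, baseline_range[1], baseline_range[2])
      I1 <- I0 + stats::runif(nc, step_range[1], step_range[2])
      # settle at baseline, then step on for the first half, off for the rest
      pre <- simulate_hill(model, numeric(model$n_genes),
                           times = c(0, settle_time), input = I0,
                           dt_int = dt_int)
      init <- pre$values[2, ]
      base_input <- t(vapply(times, function(t) if (t < t_half) I1 else I0,
                             numeric(nc)))
      if (nc == 1) base_input <- matrix(base_input, ncol = 1)
      # draw standard normals and scale so the RNG stream is identical for
      # every noise level (noise_sd = 0 reproduces the noiseless series)
      noise <- matrix(stats::rnorm(n_timepoints * nc), n_timepoints, nc) *
        noise_sd
      input <- pmax(base_input + noise, 0)
      out[[s]] <- simulate_hill(model, init, times = times, input = input,
                                dt_int = dt_int)
    } else {
      n_pert <- max(1L, as.integer(round(perturb_frac * model$n_genes)))
      pert <- sample.int(model$n_genes, n_pert)
      amp <- stats::runif(n_pert, step_range[1], step_range[2])
      basal_vec <- numeric(model$n_genes)
      basal_vec[pert] <- amp
      basal <- function(t) if (t < t_half) basal_vec else numeric(model$n_genes)
      out[[s]] <- simulate_hill(model, numeric(model$n_genes), times = times,
                                basal = basal, dt_int = dt_int)
    }
  }
  out
}
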