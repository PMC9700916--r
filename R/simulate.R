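#' Simulate a Hill circuit by forward Euler
#'
#' Integrates `dg_i/dt = f_i(g) - lambda * g_i` with an internal forward-Euler
#' step `dt_int`, clipping states at zero after each step (concentrations are
#' non-negative and Euler can overshoot). Clamped genes follow their imposed
#' input trajectory exactly; the output is sub-sampled onto the requested
#' grid `times`.
#'
#' @param model A `hill_model`.
#' @param initial_state Numeric vector of initial concentrations (length
#'   `n_genes`), non-negative.
#' @param times Output time grid (uniform, increasing; starts the clock).
#' @param input Imposed trajectory for the clamped genes: a function of time
#'   returning a vector of length `length(model$clamped)`, a single constant,
#'   or a matrix `length(times) x n_clamped` held piecewise constant between
#'   grid points.
#' @param dt_int Internal Euler step (default 0.01 time units).
#' @param basal Optional extra synthesis: function of time returning a vector
#'   of per-gene rates added to `f` (used for perturbation protocols).
#' @param knockout Optional list `list(regulator =, target =, mu =)`
#'   discounting one regulatory link inside the dynamics: only in the
#'   computation of that target's synthesis rate, the regulator's
#'   concentration is replaced by `mu * g` at every step.
#' @return An [expression_ts] sampled at `times`.
#' @export
simulate_hill <- function(model, initial_state, times, input = NULL,
                          dt_int = 0.01, basal = NULL, knockout = NULL) {
  stopifnot(inherits(model, "hill_model"))
  if (dt_int <= 0) stop("`dt_int` must be > 0", call. = FALSE)
  if (length(initial_state) != model$n_genes) {
    stop("`initial_state` must have one entry per gene", call. = FALSE)
  }
  if (any(initial_state < 0)) stop("`initial_state` must be >= 0", call. = FALSE)
  clamped <- model$clamped
  input_fn <- make_input_fn(input, times, length(clamped))
  if (length(clamped) && is.null(input_fn)) {
    stop("model has clamped genes; `input` is required", call. = FALSE)
  }
  scale_act <- scale_inh <- NULL
  if (!is.null(knockout)) {
    reg <- resolve_gene(knockout$regulator, model$gene_names, "regulator")
    tgt <- resolve_gene(knockout$target, model$gene_names, "target")
    mu <- knockout$mu %||% 0
    if (mu < 0 || mu >= 1) stop("knockout `mu` must be in [0, 1)", call. = FALSE)
    scale_act <- rep(1, nrow(model$act))
    scale_inh <- rep(1, nrow(model$inh))
    scale_act[model$act$regulator == reg & model$act$target == tgt] <- mu
    scale_inh[model$inh$regulator == reg & model$inh$target == tgt] <- mu
  }
  pc <- hill_precomp(model)
  free <- setdiff(seq_len(model$n_genes), clamped)
  t0 <- times[1]
  n_steps <- as.integer(round((times[length(times)] - t0) / dt_int))
  rec_steps <- as.integer(round((times - t0) / dt_int))
  out <- matrix(NA_real_, length(times), model$n_genes,
                dimnames = list(NULL, model$gene_names))
  S <- matrix(initial_state, 1, model$n_genes)
  rec_ptr <- 1L
  for (k in 0:n_steps) {
    t_k <- t0 + k * dt_int
    if (length(clamped)) S[, clamped] <- pmax(input_fn(t_k), 0)
    if (rec_ptr <= length(rec_steps) && k == rec_steps[rec_ptr]) {
      out[rec_ptr, ] <- S
      rec_ptr <- rec_ptr + 1L
    }
    if (k < n_steps) {
      f <- hill_rates(S, pc, scale_act = scale_act, scale_inh = scale_inh)
      if (!is.null(basal)) f <- f + rep(basal(t_k), each = 1)
      S[, free] <- pmax(S[, free] + (f[, free] - model$lambda * S[, free]) * dt_int, 0)
      if (!all(is.finite(S))) {
        stop("non-finite state at integration step ", k + 1,
             " (t = ", format(t_k + dt_int), ")", call. = FALSE)
      }
    }
  }
  expression_ts(out, times, clamped = model$gene_names[clamped])
}

# Normalise the `input` argument into function(t) -> vector(n_clamped).
make_input_fn <- function(input, times, n_clamped) {
  if (n_clamped == 0 || is.null(input)) return(NULL)
  if (is.function(input)) return(input)
  if (is.matrix(input)) {
    stopifnot(nrow(input) == length(times), ncol(input) == n_clamped)
    return(function(t) {
      i <- findInterval(t + 1e-12, times)
      input[max(1L, min(i, nrow(input))), ]
    })
  }
  if (is.numeric(input) && length(input) %in% c(1L, n_clamped)) {
    v <- rep_len(as.numeric(input), n_clamped)
    return(function(t) v)
  }
  stop("`input` must be a function, constant, or length(times) x n_clamped matrix",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score adaptation of a trajectory
#'
#' Quantifies the adaptive response of one output gene to a sustained
#' stimulus: the baseline is the output level immediately before the
#' stimulus, the sensitivity is the peak absolute deviation from baseline
#' after the stimulus, and the adaptation error is the absolute difference
#' between the baseline and the fully adapted (final) level. The trajectory
#' is flagged as unsettled when the output still drifts by more than
#' `settle_tol` over the last `settle_frac` of the horizon.
#'
#' @param ts An [expression_ts].
#' @param output_gene Name (or index) of the output gene.
#' @param stimulus_time Time at which the stimulus is applied; must lie
#'   inside the grid. Values at `t <= stimulus_time` are treated as
#'   pre-stimulus.
#' @param settle_frac,settle_tol Settling check: fraction of the horizon and
#'   maximal allowed drift (defaults 0.1 and 1e-3).
#' @return One-row tibble: `baseline`, `sensitivity`, `adaptation_error`,
#'   `peak_time`, `settled`.
#' @export
score_adaptation <- function(ts, output_gene, stimulus_time,
                             settle_frac = 0.1, settle_tol = 1e-3) {
  stopifnot(inherits(ts, "expression_ts"))
  j <- resolve_gene(output_gene, ts$gene_names, "output gene")
  tt <- ts$times
  if (stimulus_time < tt[1] || stimulus_time > tt[length(tt)]) {
    stop("`stimulus_time` must lie inside the time grid", call. = FALSE)
  }
  g <- ts$values[, j]
  pre <- which(tt <= stimulus_time)
  if (!length(pre)) pre <- 1L
  baseline <- g[max(pre)]
  post <- which(tt >= stimulus_time)
  dev <- abs(g[post] - baseline)
  peak <- which.max(dev)
  tail_n <- max(2L, ceiling(settle_frac * length(tt)))
  tail_vals <- g[(length(g) - tail_n + 1L):length(g)]
  tibble::tibble(
    baseline = baseline,
    sensitivity = dev[peak],
    adaptation_error = abs(g[length(g)] - baseline),
    peak_time = tt[post[peak]],
    settled = (max(tail_vals) - min(tail_vals)) < settle_tol
  )
}

#' Count adapting parameter sets for a topology
#'
#' The enumeration screen: for a fixed signed topology, `n_samples` parameter
#' sets are drawn with every `b` and `K` i.i.d. from the unit-rate
#' exponential, each set is simulated under a step increase of the clamped
#' input (baseline until steady, then stepped), and the number of sets whose
#' output adapts is returned. A set passes when the response peak is at least
#' `sens_frac` of the input step and the residual offset between baseline and
#' the fully adapted level is at most `err_frac` of the peak. A topology is
#' conventionally called successful when at least 2 of 100,000 sets pass.
#'
#' All trajectories in a chunk are integrated simultaneously (vectorised
#' Euler), so the screen runs in minutes on one core.
#'
#' @param topology Signed adjacency matrix (regulator x target).
#' @param n_samples Number of parameter sets to draw.
#' @param seed Integer seed for the parameter draw.
#' @param input_gene,output_gene Index (or name) of the clamped input and the
#'   scored output gene. Defaults: first and last gene.
#' @param hill_n,lambda Hill coefficient and degradation rate (defaults 2, 1).
#' @param input_baseline,input_step Pre-stimulus input level and step size
#'   (defaults 0.5 and 0.5, i.e. a step from 0.5 to 1.0).
#' @param sens_frac,err_frac Screen thresholds (defaults 0.2 and 0.1).
#' @param t_pre,t_post Pre-stimulus settling horizon and post-stimulus
#'   response horizon in time units (defaults 30 and 50).
#' @param dt_int Euler step (default 0.01).
#' @param chunk_size Trajectories integrated per vectorised chunk.
#' @param details If `TRUE`, also return per-sample sensitivity/error.
#' @return Integer count of passing parameter sets (attribute `rate` holds
#'   the empirical pass rate); with `details = TRUE`, a list with the count
#'   and a tibble of per-sample metrics.
#' @export
topology_success_count <- function(topology, n_samples, seed = 1,
                                   input_gene = 1,
                                   output_gene = nrow(topology),
                                   hill_n = 2, lambda = 1,
                                   input_baseline = 0.5, input_step = 0.5,
                                   sens_frac = 0.2, err_frac = 0.1,
                                   t_pre = 30, t_post = 50, dt_int = 0.01,
                                   chunk_size = 25000L, details = FALSE) {
  stopifnot(is.matrix(topology), nrow(topology) == ncol(topology))
  gene_names <- rownames(topology)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(nrow(topology)))
  in_i <- resolve_gene(input_gene, gene_names, "input gene")
  out_i <- resolve_gene(output_gene, gene_names, "output gene")
  ng <- nrow(topology)
  idx <- which(topology != 0, arr.ind = TRUE)
  sgn <- topology[idx]
  # template model with placeholder parameters; per-sample values override
  template <- hill_model(
    data.frame(regulator = idx[, 1], target = idx[, 2], sign = as.numeric(sgn),
               b = ifelse(sgn > 0, 1, NA), K = 1),
    gene_names = gene_names, hill_n = hill_n, lambda = lambda, clamped = in_i
  )
  pc <- hill_precomp(template)
  n_act <- length(pc$act_reg)
  n_inh <- length(pc$inh_reg)
  free <- setdiff(seq_len(ng), in_i)
  set.seed(as.integer(seed))
  total <- 0L
  sens_all <- err_all <- numeric(0)
  remaining <- as.integer(n_samples)
  while (remaining > 0L) {
    nt <- min(remaining, as.integer(chunk_size))
    remaining <- remaining - nt
    b_mat <- matrix(stats::rexp(nt * n_act), nt, n_act)
    Kn_act <- matrix(stats::rexp(nt * n_act), nt, n_act)^hill_n
    Kn_inh <- matrix(stats::rexp(nt * n_inh), nt, n_inh)^hill_n
    S <- matrix(0, nt, ng)
    S[, in_i] <- input_baseline
    step_euler <- function(S, n_steps, track = FALSE, baseline = NULL) {
      peak <- if (track) numeric(nt) else NULL
      for (k in seq_len(n_steps)) {
        f <- hill_rates(S, pc, b_mat = b_mat, Kn_act_mat = Kn_act,
                        Kn_inh_mat = Kn_inh)
        S[, free] <- pmax(S[, free] + (f[, free] - lambda * S[, free]) * dt_int, 0)
        if (track) peak <- pmax(peak, abs(S[, out_i] - baseline))
      }
      list(S = S, peak = peak)
    }
    S <- step_euler(S, as.integer(round(t_pre / dt_int)))$S
    baseline <- S[, out_i]
    S[, in_i] <- input_baseline + input_step
    resp <- step_euler(S, as.integer(round(t_post / dt_int)),
                       track = TRUE, baseline = baseline)
    sens <- resp$peak
    err <- abs(resp$S[, out_i] - baseline)
    pass <- (sens >= sens_frac * abs(input_step)) & (err <= err_frac * sens)
    total <- total + sum(pass)
    if (details) {
      sens_all <- c(sens_all, sens)
      err_all <- c(err_all, err)
    }
  }
  count <- as.integer(total)
  attr(count, "rate") <- total / n_samples
  if (details) {
    return(list(count = count,
                metrics = tibble::tibble(sensitivity = sens_all,
                                         adaptation_error = err_all)))
  }
  count
}
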