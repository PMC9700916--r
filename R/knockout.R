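#' Link-knockout effect of one regulator on one target
#'
#' The in-silico link knockout statistic: for each evaluation state `g`,
#' `Delta = f_target(g) - f_target(g with g_regulator replaced by mu * g_regulator)`,
#' averaged across states. A positive mean means removing the input lowers
#' the target's synthesis (activation); a negative mean means inhibition.
#' `mu = 0` is a full knockout; `mu = 1` is the identity and gives exactly 0.
#'
#' @param model A `hill_model` or trained `mlp_synthesis`.
#' @param states Matrix of evaluation states (rows), in the model's native
#'   space — typically the observed trajectory states.
#' @param regulator,target Gene names or indices.
#' @param mu Discount factor in `[0, 1]`.
#' @return The mean signed effect (single number).
#' @export
link_knockout_delta <- function(model, states, regulator, target, mu = 0) {
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]", call. = FALSE)
  i <- resolve_gene(regulator, model$gene_names, "regulator")
  j <- resolve_gene(target, model$gene_names, "target")
  X <- as_state_matrix(states, model$n_genes, model$gene_names)
  f0 <- synthesis_rates(model, X)[, j]
  Xm <- X
  Xm[, i] <- mu * Xm[, i]
  fm <- synthesis_rates(model, Xm)[, j]
  mean(f0 - fm)
}

#' Full matrix of link-knockout effects
#'
#' @inheritParams link_knockout_delta
#' @return Numeric matrix `Delta[regulator, target]` of mean signed effects
#'   over all evaluation states.
#' @export
knockout_deltas <- function(model, states, mu = 0) {
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]", call. = FALSE)
  X <- as_state_matrix(states, model$n_genes, model$gene_names)
  f0 <- synthesis_rates(model, X)
  ng <- model$n_genes
  D <- matrix(0, ng, ng, dimnames = list(model$gene_names, model$gene_names))
  for (i in seq_len(ng)) {
    Xm <- X
    Xm[, i] <- mu * Xm[, i]
    D[i, ] <- colMeans(f0 - synthesis_rates(model, Xm))
  }
  D
}

new_grn_network <- function(edges, gene_names, clamped, provenance) {
  tibble::new_tibble(edges, gene_names = gene_names, clamped = clamped,
                     provenance = provenance,
                     nrow = nrow(edges), class = "grn_network")
}

#' Infer a signed regulatory network by link knockout
#'
#' Computes the link-knockout effect of every candidate regulator on every
#' non-clamped target over all observed timepoints of all series, ranks
#' ordered pairs by effect magnitude, and calls each edge activating,
#' inhibitory, or absent. Self-edges are retained as self-activation /
#' self-inhibition calls. Binarisation is either top-k or a relative
#' magnitude threshold (an edge is called absent when its weight falls below
#' `rel_threshold` times the largest weight).
#'
#' @param model A trained `mlp_synthesis` (or a `hill_model` used as a
#'   ground-truth oracle).
#' @param ts The time series the model was trained on ([expression_ts] or
#'   list); states are normalised with the model's stored constants.
#' @param mu Knockout discount factor (default 0 = full knockout).
#' @param top_k If given, exactly the `min(top_k, n_candidates)`
#'   highest-weight pairs receive a signed call.
#' @param rel_threshold Relative null band when `top_k` is absent
#'   (default 0.05).
#' @return A `grn_network`: a tibble with one row per candidate ordered pair,
#'   columns `regulator`, `target`, `delta` (signed mean effect), `weight`
#'   (`|delta|`, the edge confidence) and `sign` (+1/-1/0), sorted by
#'   decreasing weight (ties broken by regulator then target index).
#' @export
infer_network <- function(model, ts, mu = 0, top_k = NULL, rel_threshold = 0.05) {
  states <- prepare_states(model, ts)
  if (is.null(states) || nrow(states) == 0) {
    stop("empty time series", call. = FALSE)
  }
  D <- knockout_deltas(model, states, mu = mu)
  g <- model$gene_names
  clamped <- as.character(if (inherits(model, "hill_model")) {
    g[model$clamped]
  } else {
    model$clamped
  })
  targets <- setdiff(g, clamped)
  cand <- expand.grid(regulator = g, target = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand$delta <- D[cbind(match(cand$regulator, g), match(cand$target, g))]
  cand$weight <- abs(cand$delta)
  ord <- order(-cand$weight, match(cand$regulator, g), match(cand$target, g))
  cand <- cand[ord, ]
  call_sign <- sign(cand$delta)
  if (!is.null(top_k)) {
    k <- min(max(0L, as.integer(top_k)), nrow(cand))
    if (k < nrow(cand)) call_sign[(k + 1):nrow(cand)] <- 0
  } else {
    wmax <- max(cand$weight)
    if (wmax > 0) call_sign[cand$weight < rel_threshold * wmax] <- 0
    else call_sign[] <- 0
  }
  cand$sign <- as.integer(call_sign)
  new_grn_network(tibble::as_tibble(cand), gene_names = g, clamped = clamped,
                  provenance = if (inherits(model, "hill_model")) "Hill-truth"
                               else "NN-knockout")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network> (", attr(x, "provenance"), ") ",
      sum(x$sign != 0), " called edge(s) of ", nrow(x), " candidate pairs\n",
      sep = "")
  NextMethod()
}

#' Simulate a mutant with one regulatory link knocked out
#'
#' Rolls out the dynamics where, only in the computation of the target's
#' synthesis rate, the regulator's concentration is replaced by
#' `mu * g_regulator` at every step. With `mu = 1` the trajectory is the
#' wild type.
#'
#' @param model A `hill_model` or trained `mlp_synthesis`.
#' @param edge List or vector `c(regulator, target)` naming the knocked link.
#' @param mu Discount factor in `[0, 1]`.
#' @param ... Passed to the underlying simulator: [simulate_hill()] arguments
#'   (`initial_state`, `times`, `input`, `dt_int`) for Hill models;
#'   [rollout_synthesis()] arguments (`init`, `n_steps`, `input`) for neural
#'   models.
#' @return An [expression_ts] of the mutant trajectory.
#' @export
simulate_mutant <- function(model, edge, mu = 0, ...) {
  UseMethod("simulate_mutant")
}

#' @export
simulate_mutant.hill_model <- function(model, edge, mu = 0, ...) {
  if (mu == 1) return(simulate_hill(model, ...))
  simulate_hill(model, ...,
                knockout = list(regulator = edge[[1]], target = edge[[2]], mu = mu))
}

#' @export
simulate_mutant.mlp_synthesis <- function(model, edge, mu = 0, ...) {
  i <- resolve_gene(edge[[1]], model$gene_names, "regulator")
  j <- resolve_gene(edge[[2]], model$gene_names, "target")
  mask <- model$mask %||% matrix(1, model$n_genes, model$n_genes)
  mask[i, j] <- mu
  m2 <- model
  m2$mask <- mask
  rollout_synthesis(m2, ...)
}

# ---- functional evaluation used by pruning ---------------------------------

#' Stimulus-response adaptation metrics of a trained model
#'
#' Rolls the learned dynamics to steady state under a low input level and
#' scores the output gene's response to a stimulus with
#' [score_adaptation()]: the baseline is the pre-stimulus steady level, the
#' sensitivity is the response peak, and the adaptation error is the
#' baseline-vs-fully-adapted offset at the end of the horizon.
#'
#' Two stimulus protocols are supported. `"pulse"` applies the input step
#' for `t_stim` steps and removes it again — the applied-then-removed
#' protocol of the training data; here the adaptation error measures failure
#' to return once the stimulus is gone (a knockout that latches the output
#' in its stimulated state shows up as a large error). `"step"` keeps the
#' stimulus on; the error then measures genuine adaptation to a sustained
#' input, the defining property of adaptive motifs.
#'
#' @param model A trained `mlp_synthesis` with a clamped input gene.
#' @param output_gene Output gene to score.
#' @param init Normalised initial state (defaults to all zeros).
#' @param input_low,input_high Normalised input levels outside/inside the
#'   stimulus.
#' @param t_pre,t_stim,t_recover Steps rolled before, during and (for the
#'   pulse protocol) after the stimulus.
#' @param protocol `"pulse"` or `"step"`.
#' @return One-row tibble as returned by [score_adaptation()].
#' @export
model_adaptation <- function(model, output_gene, init = NULL,
                             input_low = 0.1, input_high = 0.9,
                             t_pre = 15, t_stim = 15, t_recover = 25,
                             protocol = c("pulse", "step")) {
  stopifnot(inherits(model, "mlp_synthesis"))
  protocol <- match.arg(protocol)
  if (!length(model$clamped)) {
    stop("model has no clamped input gene", call. = FALSE)
  }
  if (is.null(init)) init <- numeric(model$n_genes)
  input <- c(rep(input_low, t_pre + 1),
             rep(input_high, if (protocol == "pulse") t_stim else
                               t_stim + t_recover),
             if (protocol == "pulse") rep(input_low, t_recover))
  ts <- rollout_synthesis(model, init, n_steps = t_pre + t_stim + t_recover,
                          input = matrix(input, ncol = 1))
  score_adaptation(ts, output_gene, stimulus_time = t_pre * model$dt,
                   settle_tol = 1e-2)
}

#' Prune a trained network to a minimal functional topology
#'
#' Iteratively removes regulatory links from the inferred network while the
#' learned dynamics keep their function. At each step every surviving link is
#' tentatively knocked out (`mu = 0`) and the step-response adaptation
#' metrics of the mutant are computed; candidates are ranked by how little
#' they change `(sensitivity, adaptation_error)` (ties broken
#' lexicographically by regulator then target index). The best candidate is
#' knocked out permanently, the network is retrained with that link's input
#' forced to zero for its target (at a reduced epoch budget), and the
#' retrained model is kept only if its metrics stay within tolerance of the
#' step-0 metrics: sensitivity not below `(1 - sens_tol)` times the initial
#' sensitivity and adaptation error not above the initial error plus
#' `err_tol` times the initial sensitivity. When no candidate survives —
#' before the network has too few links to keep the function — pruning stops.
#'
#' @param model A trained `mlp_synthesis` with a clamped input gene.
#' @param ts Training series (used for inference states and retraining).
#' @param output_gene Output gene carrying the target function.
#' @param input_low,input_high,t_pre,t_stim,t_recover,protocol
#'   Stimulus-response protocol passed to [model_adaptation()];
#'   `input_low`/`input_high` default to the 0.1/0.9 quantiles of the
#'   observed normalised input. Use `protocol = "step"` when the preserved
#'   function is adaptation to a sustained stimulus.
#' @param mu Knockout discount (default 0).
#' @param sens_tol Maximal tolerated fractional drop in sensitivity
#'   (default 0.3).
#' @param err_tol Maximal tolerated growth of the adaptation error, as a
#'   fraction of the initial sensitivity (default 0.15).
#' @param rel_threshold Null band of the initial inference (default 0.05).
#' @param retrain_frac Retraining epoch budget as a fraction of the epochs
#'   already trained (default 0.25).
#' @param max_steps Cap on the number of removals.
#' @return A `pruning_path`: list with `steps` (per-step tibble via
#'   [tidy.pruning_path()]), `networks` (list of surviving edge tibbles),
#'   `metrics` (list of adaptation tibbles), `final_model`, `final_mask`.
#' @export
prune_network <- function(model, ts, output_gene,
                          input_low = NULL, input_high = NULL,
                          t_pre = 15, t_stim = 15, t_recover = 25,
                          protocol = c("pulse", "step"), mu = 0,
                          sens_tol = 0.3, err_tol = 0.15,
                          rel_threshold = 0.05, retrain_frac = 0.25,
                          max_steps = Inf) {
  stopifnot(inherits(model, "mlp_synthesis"))
  if (!length(model$clamped)) stop("pruning needs a clamped input gene", call. = FALSE)
  ts <- as_ts_list(ts)
  g <- model$gene_names
  ci <- match(model$clamped[1], g)
  obs_input <- pool_states(normalize_ts(model, ts))[, ci]
  if (is.null(input_low)) input_low <- unname(stats::quantile(obs_input, 0.1))
  if (is.null(input_high)) input_high <- unname(stats::quantile(obs_input, 0.9))
  protocol <- match.arg(protocol)
  adapt <- function(m) model_adaptation(m, output_gene,
                                        input_low = input_low,
                                        input_high = input_high,
                                        t_pre = t_pre, t_stim = t_stim,
                                        t_recover = t_recover,
                                        protocol = protocol)
  net0 <- infer_network(model, ts, mu = mu, rel_threshold = rel_threshold)
  edges <- net0[net0$sign != 0, c("regulator", "target", "sign", "weight")]
  met0 <- adapt(model)
  if (met0$sensitivity < 1e-3) {
    stop("target function already absent before pruning (no step response)",
         call. = FALSE)
  }
  epochs0 <- max(model$epochs_trained, 1L)
  retrain_epochs <- max(1L, as.integer(round(retrain_frac * epochs0)))
  mask <- model$mask %||% matrix(1, model$n_genes, model$n_genes)
  networks <- list(tibble::as_tibble(edges))
  metrics <- list(met0)
  removed <- tibble::tibble(regulator = NA_character_, target = NA_character_)
  cur <- model
  step <- 0L
  while (nrow(edges) > 1 && step < max_steps) {
    # tentative knockouts, no retraining: rank candidates by smallest change
    cand <- edges
    cand$change <- NA_real_
    cur_met <- metrics[[length(metrics)]]
    for (r in seq_len(nrow(cand))) {
      m_try <- cur
      mk <- mask
      mk[match(cand$regulator[r], g), match(cand$target[r], g)] <- mu
      m_try$mask <- mk
      met <- adapt(m_try)
      cand$change[r] <- abs(met$sensitivity - cur_met$sensitivity) +
        abs(met$adaptation_error - cur_met$adaptation_error)
    }
    ord <- order(cand$change, match(cand$regulator, g), match(cand$target, g))
    accepted <- FALSE
    for (r in ord) {
      mk <- mask
      mk[match(cand$regulator[r], g), match(cand$target[r], g)] <- mu
      m_new <- train_synthesis(cur, ts, epochs = retrain_epochs,
                               learning_rate = cur$learning_rate %||% 1e-3,
                               seed = cur$seed + step + 1L, mask = mk,
                               keep_norm = TRUE)
      met_new <- adapt(m_new)
      ok <- met_new$sensitivity >= (1 - sens_tol) * met0$sensitivity &&
        met_new$adaptation_error <= met0$adaptation_error +
          err_tol * met0$sensitivity
      if (ok) {
        mask <- mk
        cur <- m_new
        drop_r <- cand$regulator[r] == edges$regulator &
          cand$target[r] == edges$target
        removed <- dplyr::bind_rows(removed,
                                    tibble::tibble(regulator = cand$regulator[r],
                                                   target = cand$target[r]))
        edges <- edges[!drop_r, ]
        networks[[length(networks) + 1]] <- tibble::as_tibble(edges)
        metrics[[length(metrics) + 1]] <- met_new
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    step <- step + 1L
  }
  structure(
    list(networks = networks, metrics = metrics, removed = removed,
         initial_model = model, final_model = cur, final_mask = mask,
         tolerances = c(sens_tol = sens_tol, err_tol = err_tol)),
    class = "pruning_path"
  )
}

#' @export
print.pruning_path <- function(x, ...) {
  cat("<pruning_path> ", length(x$networks), " topologies, ",
      nrow(x$networks[[1]]), " -> ", nrow(x$networks[[length(x$networks)]]),
      " edges\n", sep = "")
  print(tidy.pruning_path(x))
  invisible(x)
}

#' Aggregate repeated trainings by majority vote
#'
#' Trains `n_repeats` independently initialised synthesis networks on the
#' same series, calls every ordered gene pair activated / absent / inhibited
#' per repeat by link knockout, tabulates the three-way counts, and colours
#' the majority network by plurality (ties are called absent).
#'
#' @param ts An [expression_ts] or list of them.
#' @param n_repeats Number of independent trainings (>= 1).
#' @param seed Base seed; repeat `r` uses `seed + r - 1`.
#' @param clamped,hidden,lambda,dt Model configuration (see
#'   [build_synthesis_model()]).
#' @param epochs,learning_rate Training configuration.
#' @param mu,rel_threshold Edge-calling configuration (see
#'   [infer_network()]).
#' @param train_fn Optional hook `function(ts, seed)` returning a trained
#'   model, replacing the built-in build-and-train (used to inject oracles).
#' @return List with `votes` (tibble: `regulator`, `target`, `activated`,
#'   `absent`, `inhibited`, `call`) and `network` (majority `grn_network`
#'   whose weight is the plurality fraction).
#' @export
repeated_vote <- function(ts, n_repeats = 40, seed = 1,
                          clamped = character(), hidden = c(64, 64),
                          lambda = 1, dt = 1,
                          epochs = 2000, learning_rate = 1e-3,
                          mu = 0, rel_threshold = 0.05,
                          train_fn = NULL) {
  stopifnot(n_repeats >= 1)
  ts <- as_ts_list(ts)
  gene_names <- ts[[1]]$gene_names
  if (is.null(train_fn)) {
    train_fn <- function(ts, seed) {
      m <- build_synthesis_model(gene_names, hidden = hidden, seed = seed,
                                 lambda = lambda, dt = dt, clamped = clamped)
      train_synthesis(m, ts, epochs = epochs, learning_rate = learning_rate,
                      seed = seed)
    }
  }
  counts <- NULL
  for (r in seq_len(n_repeats)) {
    m <- train_fn(ts, as.integer(seed) + r - 1L)
    net <- infer_network(m, ts, mu = mu, rel_threshold = rel_threshold)
    calls <- tibble::tibble(regulator = net$regulator, target = net$target,
                            activated = as.integer(net$sign > 0),
                            absent = as.integer(net$sign == 0),
                            inhibited = as.integer(net$sign < 0))
    counts <- if (is.null(counts)) calls else {
      stopifnot(identical(counts$regulator, calls$regulator),
                identical(counts$target, calls$target))
      dplyr::mutate(counts,
                    activated = .data$activated + calls$activated,
                    absent = .data$absent + calls$absent,
                    inhibited = .data$inhibited + calls$inhibited)
    }
  }
  counts$call <- plurality_call(counts$activated, counts$absent, counts$inhibited)
  clamped_out <- if (length(clamped)) as.character(clamped) else
    setdiff(gene_names, unique(counts$target))
  maj <- tibble::tibble(
    regulator = counts$regulator, target = counts$target,
    delta = (counts$activated - counts$inhibited) / n_repeats,
    weight = pmax(counts$activated, counts$absent, counts$inhibited) / n_repeats,
    sign = counts$call
  )
  maj <- maj[order(-maj$weight, match(maj$regulator, gene_names),
                   match(maj$target, gene_names)), ]
  list(
    votes = counts,
    network = new_grn_network(maj, gene_names = gene_names,
                              clamped = clamped_out, provenance = "vote"),
    n_repeats = as.integer(n_repeats)
  )
}

#' Plurality edge call from three-way vote counts
#'
#' @param activated,absent,inhibited Integer count vectors.
#' @return Integer vector of calls: +1, 0 or -1 (ties go to 0).
#' @export
plurality_call <- function(activated, absent, inhibited) {
  out <- integer(length(activated))
  out[activated > absent & activated > inhibited] <- 1L
  out[inhibited > absent & inhibited > activated] <- -1L
  out
}
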