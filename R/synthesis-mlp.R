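#' Build an untrained synthesis-rate network
#'
#' Constructs the four-layer fully connected network that emulates the gene
#' synthesis-rate term of the ODE `dg/dt = f(g) - lambda * g`: an input layer
#' of width `n_genes`, two ReLU hidden layers, and a sigmoid output layer of
#' width `n_genes`, so every component of `f` lies strictly in (0, 1).
#' Weights are Glorot-uniform initialised, reproducibly per seed.
#'
#' @param genes Gene names (character) or a gene count (names become
#'   `G1, G2, ...`).
#' @param hidden Widths of the two hidden layers (default `c(64, 64)`).
#' @param seed Integer seed for the weight initialisation.
#' @param lambda Degradation rate used in the one-step update (default 1).
#' @param dt Time step between consecutive samples, in grid units
#'   (default 1; with `lambda = 1`, `dt = 1` the one-step prediction reduces
#'   to `g_hat(t+1) = f(g(t))`).
#' @param clamped Names of clamped input-signal genes: fed as inputs, never
#'   predicted, and excluded from the training loss.
#' @return An object of class `mlp_synthesis`.
#' @export
build_synthesis_model <- function(genes, hidden = c(64, 64), seed = 1,
                                  lambda = 1, dt = 1, clamped = character()) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- paste0("G", seq_len(genes))
  }
  genes <- as.character(genes)
  ng <- length(genes)
  if (ng < 2) stop("need at least 2 genes", call. = FALSE)
  stopifnot(length(hidden) == 2, all(hidden >= 1))
  clamped <- as.character(clamped)
  bad <- setdiff(clamped, genes)
  if (length(bad)) stop("unknown clamped genes: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  set.seed(as.integer(seed))
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  params <- list(
    W1 = glorot(ng, hidden[1]), b1 = numeric(hidden[1]),
    W2 = glorot(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
    W3 = glorot(hidden[2], ng), b3 = numeric(ng)
  )
  structure(
    list(gene_names = genes, n_genes = ng, hidden = as.integer(hidden),
         params = params, norm = NULL, lambda = lambda, dt = dt,
         clamped = clamped, mask = NULL, seed = as.integer(seed),
         epochs_trained = 0L, report = NULL, final_loss = NA_real_),
    class = "mlp_synthesis"
  )
}

#' @export
print.mlp_synthesis <- function(x, ...) {
  cat("<mlp_synthesis> ", x$n_genes, " genes, hidden ",
      paste(x$hidden, collapse = "/"), ", lambda = ", x$lambda,
      ", dt = ", x$dt, "\n", sep = "")
  cat("  ", if (x$epochs_trained > 0) {
    paste0("trained ", x$epochs_trained, " epochs, final loss ",
           signif(x$final_loss, 4))
  } else "untrained", "\n", sep = "")
  if (!is.null(x$mask)) {
    cat("  ", sum(x$mask == 0), " link(s) forced knocked out\n", sep = "")
  }
  invisible(x)
}

mlp_forward <- function(p, X) {
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  H1 <- Z1 * (Z1 > 0)
  Z2 <- sweep(H1 %*% p$W2, 2, p$b2, "+")
  H2 <- Z2 * (Z2 > 0)
  O <- stats::plogis(sweep(H2 %*% p$W3, 2, p$b3, "+"))
  list(X = X, H1 = H1, H2 = H2, O = O)
}

mlp_backward <- function(p, cache, dO) {
  dZ3 <- dO * cache$O * (1 - cache$O)
  dH2 <- tcrossprod(dZ3, p$W3)
  dZ2 <- dH2 * (cache$H2 > 0)
  dH1 <- tcrossprod(dZ2, p$W2)
  dZ1 <- dH1 * (cache$H1 > 0)
  list(W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
       W2 = crossprod(cache$H1, dZ2), b2 = colSums(dZ2),
       W3 = crossprod(cache$H2, dZ3), b3 = colSums(dZ3))
}

# Group target genes by identical mask columns so a forced link knockout
# (mu-scaled inputs for specific targets) costs one extra forward pass per
# distinct input pattern rather than one per gene.
mask_groups <- function(mask, n_genes) {
  if (is.null(mask)) {
    return(list(list(cols = seq_len(n_genes), scale = NULL)))
  }
  key <- apply(mask, 2, paste, collapse = ",")
  lapply(unique(key), function(k) {
    cols <- which(key == k)
    sc <- mask[, cols[1]]
    list(cols = cols, scale = if (all(sc == 1)) NULL else sc)
  })
}

# Full synthesis-rate matrix under an optional per-link discount mask.
mlp_rates <- function(model, X, mask = model$mask) {
  groups <- mask_groups(mask, model$n_genes)
  if (length(groups) == 1 && is.null(groups[[1]]$scale)) {
    return(mlp_forward(model$params, X)$O)
  }
  f <- matrix(NA_real_, nrow(X), model$n_genes)
  for (g in groups) {
    Xs <- if (is.null(g$scale)) X else sweep(X, 2, g$scale, "*")
    f[, g$cols] <- mlp_forward(model$params, Xs)$O[, g$cols, drop = FALSE]
  }
  f
}

#' @rdname synthesis_rates
#' @export
synthesis_rates.mlp_synthesis <- function(model, states, mask = NULL, ...) {
  X <- as_state_matrix(states, model$n_genes, model$gene_names)
  f <- mlp_rates(model, X, mask = mask %||% model$mask)
  colnames(f) <- model$gene_names
  f
}

# ---- normalisation ---------------------------------------------------------

#' Fit per-gene min-max normalisation from time series
#'
#' Records, per gene, the minimum and range over all provided series. The
#' sigmoid output bounds f in (0, 1); with `dt = 1`, `lambda = 1` the one-step
#' update reduces to `g_hat(t+1) = f(g(t))`, so training targets must live in
#' `[0, 1]`. Constant genes get range 1 (they map to 0).
#'
#' @param ts An [expression_ts] or list of them.
#' @return List with numeric vectors `min` and `range`.
#' @export
fit_normalization <- function(ts) {
  V <- pool_states(ts)
  lo <- apply(V, 2, min)
  hi <- apply(V, 2, max)
  rng <- hi - lo
  rng[rng < 1e-12] <- 1
  list(min = lo, range = rng)
}

#' Normalise time series into a model's unit scale
#'
#' @param model A trained `mlp_synthesis` (with stored normalisation).
#' @param ts An [expression_ts] or list of them.
#' @return The series with values mapped gene-wise to `[0, 1]`.
#' @export
normalize_ts <- function(model, ts) {
  stopifnot(inherits(model, "mlp_synthesis"))
  if (is.null(model$norm)) stop("model has no stored normalisation", call. = FALSE)
  one <- function(s) {
    v <- sweep(sweep(s$values, 2, model$norm$min[s$gene_names], "-"),
               2, model$norm$range[s$gene_names], "/")
    expression_ts(pmax(v, 0), s$times, clamped = s$clamped)
  }
  if (inherits(ts, "expression_ts")) one(ts) else lapply(ts, one)
}

# States for knockout/inference in the model's native space.
prepare_states <- function(model, ts) UseMethod("prepare_states")

#' @export
prepare_states.mlp_synthesis <- function(model, ts) {
  pool_states(normalize_ts(model, ts))
}

#' @export
prepare_states.hill_model <- function(model, ts) {
  pool_states(ts)
}

# ---- training --------------------------------------------------------------

# Consecutive-pair design matrices, pooled across series; no pairs span
# series boundaries.
training_pairs <- function(ts, gene_names) {
  ts <- as_ts_list(ts)
  Xs <- list()
  Ys <- list()
  for (s in ts) {
    if (!identical(s$gene_names, gene_names)) {
      stop("series gene names do not match the model", call. = FALSE)
    }
    nt <- nrow(s$values)
    if (nt < 2) stop("each series needs at least 2 timepoints", call. = FALSE)
    Xs[[length(Xs) + 1]] <- s$values[-nt, , drop = FALSE]
    Ys[[length(Ys) + 1]] <- s$values[-1, , drop = FALSE]
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

#' Train the synthesis network by one-step-ahead prediction
#'
#' Minimises the Euclidean one-step loss
#' `Loss = sqrt( sum_t || g_hat(t+dt) - g(t+dt) ||^2 )` over all consecutive
#' sample pairs of all series, where
#' `g_hat(t+dt) = g(t) + (f(g(t)) - lambda * g(t)) * dt` and `f` is the
#' network output. Series are min-max normalised per gene before training;
#' clamped input-signal genes are fed as inputs but excluded from the loss.
#' Optimisation is full-batch Adam. Training is deterministic for a fixed
#' seed.
#'
#' @param model An `mlp_synthesis` (untrained or previously trained; training
#'   continues from the current weights).
#' @param ts An [expression_ts] or list of them (multiple perturbation
#'   series are pooled as independent consecutive-pair samples).
#' @param epochs Number of full-batch epochs (default 2000). `epochs = 0`
#'   returns the model unchanged with an empty report.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed (defaults to the model's seed).
#' @param mask Optional regulator x target discount matrix forced during
#'   training (used when retraining after a permanent link knockout).
#' @param keep_norm Keep the model's stored normalisation instead of
#'   refitting from `ts` (default: refit unless already present).
#' @return The trained model; per-epoch losses are available via
#'   [tidy.mlp_synthesis()] and summary statistics via
#'   [glance.mlp_synthesis()].
#' @export
train_synthesis <- function(model, ts, epochs = 2000, learning_rate = 1e-3,
                            seed = model$seed, mask = model$mask,
                            keep_norm = !is.null(model$norm)) {
  stopifnot(inherits(model, "mlp_synthesis"))
  ts <- as_ts_list(ts)
  if (!keep_norm || is.null(model$norm)) model$norm <- fit_normalization(ts)
  model$mask <- mask
  nts <- normalize_ts(model, ts)
  pairs <- training_pairs(nts, model$gene_names)
  X <- pairs$X
  Y <- pairs$Y
  free <- which(!(model$gene_names %in% model$clamped))
  groups <- mask_groups(mask, model$n_genes)
  dt <- model$dt
  lam <- model$lambda
  p <- model$params
  epochs <- as.integer(epochs)
  if (epochs == 0) {
    model$report <- tibble::tibble(epoch = integer(), loss = numeric())
    return(model)
  }
  set.seed(as.integer(seed))
  # Adam state
  mstate <- lapply(p, function(w) w * 0)
  vstate <- lapply(p, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  losses <- numeric(epochs)
  best <- list(p = p, loss = Inf)
  eval_pass <- function(p) {
    caches <- vector("list", length(groups))
    O <- matrix(NA_real_, nrow(X), model$n_genes)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      Xs <- if (is.null(g$scale)) X else sweep(X, 2, g$scale, "*")
      caches[[gi]] <- mlp_forward(p, Xs)
      O[, g$cols] <- caches[[gi]]$O[, g$cols, drop = FALSE]
    }
    Ghat <- X + (O - lam * X) * dt
    E <- Ghat[, free, drop = FALSE] - Y[, free, drop = FALSE]
    list(caches = caches, E = E, loss = sqrt(sum(E * E)))
  }
  for (ep in seq_len(epochs)) {
    ev <- eval_pass(p)
    if (!is.finite(ev$loss)) {
      warning("non-finite loss at epoch ", ep, "; reverting to last good weights",
              call. = FALSE)
      p <- best$p
      losses[ep:epochs] <- best$loss
      break
    }
    if (ev$loss < best$loss) best <- list(p = p, loss = ev$loss)
    dGhat <- ev$E / max(ev$loss, 1e-12)
    dO <- matrix(0, nrow(X), model$n_genes)
    dO[, free] <- dGhat * dt
    grads <- NULL
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      dOg <- matrix(0, nrow(X), model$n_genes)
      dOg[, g$cols] <- dO[, g$cols, drop = FALSE]
      gr <- mlp_backward(p, ev$caches[[gi]], dOg)
      grads <- if (is.null(grads)) gr else Map(`+`, grads, gr)
    }
    t_adam <- ep
    for (nm in names(p)) {
      mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
      vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mstate[[nm]] / (1 - beta1^t_adam)
      vhat <- vstate[[nm]] / (1 - beta2^t_adam)
      p[[nm]] <- p[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
    losses[ep] <- ev$loss
  }
  final <- {
    model_tmp <- model; model_tmp$params <- p
    synthesis_loss(model_tmp, ts)
  }
  if (final > best$loss) {
    p <- best$p
    final <- best$loss
  }
  model$params <- p
  model$epochs_trained <- model$epochs_trained + epochs
  model$report <- tibble::tibble(epoch = seq_len(epochs), loss = losses)
  model$final_loss <- final
  model$learning_rate <- learning_rate
  model
}

#' One-step Euclidean loss of a synthesis model on data
#'
#' Independent recomputation of the training objective
#' `sqrt( sum_t || g_hat(t+dt) - g(t+dt) ||^2 )` over all consecutive pairs,
#' clamped genes excluded.
#'
#' @param model A trained `mlp_synthesis`.
#' @param ts An [expression_ts] or list of them (raw scale; normalised with
#'   the model's stored constants).
#' @return The loss (single number).
#' @export
synthesis_loss <- function(model, ts) {
  nts <- normalize_ts(model, as_ts_list(ts))
  pairs <- training_pairs(nts, model$gene_names)
  free <- which(!(model$gene_names %in% model$clamped))
  f <- mlp_rates(model, pairs$X)
  Ghat <- pairs$X + (f - model$lambda * pairs$X) * model$dt
  E <- Ghat[, free, drop = FALSE] - pairs$Y[, free, drop = FALSE]
  sqrt(sum(E * E))
}

# ---- prediction ------------------------------------------------------------

#' One-step-ahead prediction
#'
#' `g_hat(t+dt) = g(t) + (f(g(t)) - lambda * g(t)) * dt` for the free genes;
#' clamped genes are copied from `clamped_next` (or carried over when not
#' supplied), never predicted.
#'
#' @param model A trained `mlp_synthesis`.
#' @param state Normalised state vector (or matrix of states in rows).
#' @param clamped_next Values of the clamped genes at the next timepoint.
#' @return Predicted next state(s), same shape as `state`.
#' @export
one_step_predict <- function(model, state, clamped_next = NULL) {
  X <- as_state_matrix(state, model$n_genes, model$gene_names)
  f <- mlp_rates(model, X)
  Ghat <- X + (f - model$lambda * X) * model$dt
  Ghat <- pmax(Ghat, 0)
  ci <- match(model$clamped, model$gene_names)
  if (length(ci)) {
    Ghat[, ci] <- if (is.null(clamped_next)) X[, ci] else clamped_next
  }
  if (is.null(dim(state))) Ghat[1, ] else Ghat
}

#' Roll out a trained synthesis model
#'
#' Iterates [one_step_predict()] from an initial state, imposing the clamped
#' input trajectory at every step, to simulate the learned dynamics.
#'
#' @param model A trained `mlp_synthesis`.
#' @param init Normalised initial state vector.
#' @param n_steps Number of prediction steps.
#' @param input Clamped-gene trajectory: matrix `(n_steps + 1) x n_clamped`,
#'   a single constant, or a function of the step index (0-based).
#' @return An [expression_ts] in normalised units with times
#'   `0, dt, ..., n_steps * dt`.
#' @export
rollout_synthesis <- function(model, init, n_steps, input = NULL) {
  stopifnot(inherits(model, "mlp_synthesis"))
  ci <- match(model$clamped, model$gene_names)
  input_fn <-
    if (is.null(input)) {
      if (length(ci)) stop("model has clamped genes; `input` is required",
                           call. = FALSE)
      NULL
    } else if (is.function(input)) {
      input
    } else if (is.matrix(input)) {
      stopifnot(nrow(input) >= n_steps + 1)
      function(k) input[k + 1, ]
    } else {
      v <- rep_len(as.numeric(input), length(ci))
      function(k) v
    }
  out <- matrix(NA_real_, n_steps + 1, model$n_genes,
                dimnames = list(NULL, model$gene_names))
  state <- as.numeric(init)
  if (length(ci)) state[ci] <- input_fn(0)
  out[1, ] <- state
  for (k in seq_len(n_steps)) {
    state <- one_step_predict(model, state,
                              clamped_next = if (length(ci)) input_fn(k) else NULL)
    out[k + 1, ] <- state
  }
  expression_ts(out, seq(0, by = model$dt, length.out = n_steps + 1),
                clamped = model$clamped)
}

#' Cross-section of a synthesis function
#'
#' Evaluates the synthesis rate of one target gene along a grid of values of
#' one varied gene, all other inputs held at `fixed_state` — the
#' cross-sectional view used to read regulatory logic off a trained network.
#'
#' @param model A `hill_model` or trained `mlp_synthesis`.
#' @param target Target gene whose synthesis rate is evaluated.
#' @param varied Gene varied along the grid.
#' @param at Grid of values for the varied gene.
#' @param fixed_state State vector at which the other genes are held.
#' @return Tibble with columns `varied`, `value`, `rate`.
#' @export
cross_section <- function(model, target, varied, at, fixed_state) {
  tgt <- resolve_gene(target, model$gene_names, "target gene")
  var_i <- resolve_gene(varied, model$gene_names, "varied gene")
  X <- matrix(rep(as.numeric(fixed_state), each = length(at)),
              length(at), model$n_genes)
  X[, var_i] <- at
  f <- synthesis_rates(model, X)
  tibble::tibble(varied = model$gene_names[var_i], value = at, rate = f[, tgt])
}
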