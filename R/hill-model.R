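#' Hill activation kinetics
#'
#' Saturating activation term `h+(g) = b * g^n / (K^n + g^n)`: zero at
#' `g = 0`, half-maximal at `g = K`, approaching the maximal rate `b` as the
#' regulator saturates.
#'
#' @param g Regulator concentration(s), non-negative.
#' @param b Maximal synthesis rate, positive.
#' @param K Half-saturation constant, positive.
#' @param n Hill coefficient, integer >= 1 (default 2).
#' @return Synthesis rate(s) in `[0, b)`, non-decreasing in `g`.
#' @export
hill_activation <- function(g, b, K, n = 2) {
  if (any(g < 0)) stop("regulator concentration `g` must be >= 0", call. = FALSE)
  if (any(b <= 0) || any(K <= 0)) stop("`b` and `K` must be > 0", call. = FALSE)
  if (any(n < 1)) stop("Hill coefficient `n` must be >= 1", call. = FALSE)
  gn <- g^n
  b * gn / (K^n + gn)
}

#' Hill inhibition kinetics
#'
#' Repression factor `h-(g) = K^n / (K^n + g^n)`: equal to 1 with no
#' inhibitor, 1/2 at `g = K`, and vanishing as the inhibitor saturates.
#'
#' @inheritParams hill_activation
#' @return Multiplicative factor in `(0, 1]`, non-increasing in `g`.
#' @export
hill_inhibition <- function(g, K, n = 2) {
  if (any(g < 0)) stop("regulator concentration `g` must be >= 0", call. = FALSE)
  if (any(K <= 0)) stop("`K` must be > 0", call. = FALSE)
  if (any(n < 1)) stop("Hill coefficient `n` must be >= 1", call. = FALSE)
  Kn <- K^n
  Kn / (Kn + g^n)
}

#' Hill-function gene circuit model
#'
#' Builds the ground-truth nonlinear ODE model
#' `dg_i/dt = f_i(g) - lambda * g_i`, where the synthesis rate of each gene is
#' a sum of Hill activation terms over its activators times a product of Hill
#' inhibition factors over its repressors. A gene with no activators has
#' `f_i = 0`. Clamped genes are input signals: their trajectories are imposed
#' externally and neither synthesis nor degradation is applied to them.
#'
#' @param edges Tibble/data frame with columns `regulator`, `target` (gene
#'   names or 1-based indices), `sign` (+1 activation, -1 inhibition), `K`
#'   (half-saturation, > 0) and `b` (maximal rate, > 0 for activating edges,
#'   `NA` allowed on inhibitory edges).
#' @param gene_names Character vector naming the genes. Defaults to the names
#'   appearing in `edges`.
#' @param hill_n Hill coefficient, integer >= 1.
#' @param lambda First-order degradation rate, >= 0.
#' @param clamped Names (or indices) of clamped input-signal genes. Edges
#'   targeting a clamped gene are not allowed.
#' @return An object of class `hill_model`.
#' @export
hill_model <- function(edges, gene_names = NULL, hill_n = 2, lambda = 1,
                       clamped = character()) {
  edges <- as.data.frame(edges)
  need <- c("regulator", "target", "sign", "K")
  if (!all(need %in% names(edges))) {
    stop("`edges` needs columns regulator, target, sign, K (and b for activations)",
         call. = FALSE)
  }
  if (is.null(gene_names)) {
    gene_names <- unique(c(as.character(edges$regulator), as.character(edges$target)))
  }
  reg <- resolve_gene(edges$regulator, gene_names, "regulator")
  tgt <- resolve_gene(edges$target, gene_names, "target")
  clamped_i <- resolve_gene(clamped, gene_names, "clamped gene")
  if (anyDuplicated(cbind(reg, tgt))) stop("duplicate edges in `edges`", call. = FALSE)
  if (!all(edges$sign %in% c(-1, 1))) stop("edge `sign` must be +1 or -1", call. = FALSE)
  if (hill_n < 1) stop("`hill_n` must be >= 1", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (any(tgt %in% clamped_i)) {
    stop("edges may not target clamped input genes", call. = FALSE)
  }
  is_act <- edges$sign > 0
  b <- if ("b" %in% names(edges)) as.numeric(edges$b) else rep(NA_real_, nrow(edges))
  K <- as.numeric(edges$K)
  if (any(!is.finite(K)) || any(K <= 0)) stop("all `K` must be finite and > 0", call. = FALSE)
  if (any(is_act & (!is.finite(b) | b <= 0))) {
    stop("activating edges need finite `b` > 0", call. = FALSE)
  }
  ord <- order(tgt, reg)
  act <- data.frame(regulator = reg, target = tgt, b = b, K = K)[ord, ][is_act[ord], ]
  inh <- data.frame(regulator = reg, target = tgt, K = K)[ord, ][!is_act[ord], ]
  rownames(act) <- rownames(inh) <- NULL
  structure(
    list(gene_names = gene_names, n_genes = length(gene_names),
         act = act, inh = inh, hill_n = hill_n, lambda = lambda,
         clamped = sort(clamped_i)),
    class = "hill_model"
  )
}

resolve_gene <- function(x, gene_names, what) {
  if (length(x) == 0) return(integer())
  if (is.numeric(x)) {
    i <- as.integer(x)
    if (any(i < 1 | i > length(gene_names))) {
      stop(what, " index out of range", call. = FALSE)
    }
    return(i)
  }
  i <- match(as.character(x), gene_names)
  if (anyNA(i)) {
    stop("unknown ", what, ": ", paste(unique(x[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  i
}

#' @export
print.hill_model <- function(x, ...) {
  cat("<hill_model> ", x$n_genes, " genes, ",
      nrow(x$act), " activating + ", nrow(x$inh), " inhibitory edges, n = ",
      x$hill_n, ", lambda = ", x$lambda, "\n", sep = "")
  if (length(x$clamped)) {
    cat("  clamped inputs: ", paste(x$gene_names[x$clamped], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Signed adjacency of a Hill model
#'
#' @param model A `hill_model`.
#' @return Integer matrix (regulator x target) with +1 activation, -1
#'   inhibition, 0 absent; gene names on both dimnames.
#' @export
topology <- function(model) {
  stopifnot(inherits(model, "hill_model"))
  m <- matrix(0L, model$n_genes, model$n_genes,
              dimnames = list(model$gene_names, model$gene_names))
  if (nrow(model$act)) m[cbind(model$act$regulator, model$act$target)] <- 1L
  if (nrow(model$inh)) m[cbind(model$inh$regulator, model$inh$target)] <- -1L
  m
}

#' Edge table of a Hill model
#'
#' @param model A `hill_model`.
#' @return Tibble with columns `regulator`, `target` (names), `sign`, `b`, `K`.
#' @export
hill_edges <- function(model) {
  stopifnot(inherits(model, "hill_model"))
  g <- model$gene_names
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(regulator = g[model$act$regulator], target = g[model$act$target],
                   sign = 1, b = model$act$b, K = model$act$K),
    tibble::tibble(regulator = g[model$inh$regulator], target = g[model$inh$target],
                   sign = -1, b = NA_real_, K = model$inh$K)
  ), match(.data$target, g), match(.data$regulator, g))
}

# Precompute edge index vectors and edge->target incidence matrices used by
# the vectorised rate evaluation and the Euler engine.
hill_precomp <- function(model) {
  ng <- model$n_genes
  incidence <- function(tgt) {
    m <- matrix(0, length(tgt), ng)
    if (length(tgt)) m[cbind(seq_along(tgt), tgt)] <- 1
    m
  }
  list(
    n_genes = ng, hn = model$hill_n,
    act_reg = model$act$regulator, act_tgt = model$act$target,
    inh_reg = model$inh$regulator, inh_tgt = model$inh$target,
    b = model$act$b,
    Kn_act = model$act$K^model$hill_n,
    Kn_inh = model$inh$K^model$hill_n,
    Mact = incidence(model$act$target),
    Minh = incidence(model$inh$target)
  )
}

# Vectorised synthesis rates for a batch of states.
# S: n_traj x n_genes. Per-edge overrides (b_mat, Kn_*_mat) are n_traj x
# n_edges matrices used when parameters differ across trajectories (the
# enumeration screen); scale_* are per-edge input discount factors (link
# knockout inside the ground-truth dynamics).
hill_rates <- function(S, pc, b_mat = NULL, Kn_act_mat = NULL, Kn_inh_mat = NULL,
                       scale_act = NULL, scale_inh = NULL) {
  nt <- nrow(S)
  f <- matrix(0, nt, pc$n_genes)
  n_act <- length(pc$act_reg)
  n_inh <- length(pc$inh_reg)
  if (n_act) {
    Ga <- S[, pc$act_reg, drop = FALSE]
    if (!is.null(scale_act)) Ga <- Ga * rep(scale_act, each = nt)
    Gan <- Ga^pc$hn
    Kn <- if (is.null(Kn_act_mat)) rep(pc$Kn_act, each = nt) else Kn_act_mat
    bb <- if (is.null(b_mat)) rep(pc$b, each = nt) else b_mat
    f <- (bb * Gan / (Kn + Gan)) %*% pc$Mact
  }
  if (n_inh) {
    Gi <- S[, pc$inh_reg, drop = FALSE]
    if (!is.null(scale_inh)) Gi <- Gi * rep(scale_inh, each = nt)
    Gin <- Gi^pc$hn
    Kn <- if (is.null(Kn_inh_mat)) rep(pc$Kn_inh, each = nt) else Kn_inh_mat
    f <- f * exp(log(Kn / (Kn + Gin)) %*% pc$Minh)
  }
  f
}

#' Synthesis rates of a model at given expression states
#'
#' Generic over synthesis models: Hill-function circuits evaluate the
#' closed-form kinetics; trained neural models evaluate the network. States
#' are given in the model's native space (raw concentrations for Hill models,
#' normalised units for neural models).
#'
#' @param model A `hill_model` or `mlp_synthesis` object.
#' @param states Numeric vector (one state) or matrix (states in rows).
#' @param mask Optional regulator x target matrix of input discount factors
#'   `mu` applied per link when computing each target's rate (1 = intact).
#' @param ... Passed to methods.
#' @return Matrix of synthesis rates, one row per state, one column per gene.
#' @export
synthesis_rates <- function(model, states, mask = NULL, ...) {
  UseMethod("synthesis_rates")
}

#' @rdname synthesis_rates
#' @export
synthesis_rates.hill_model <- function(model, states, mask = NULL, ...) {
  S <- as_state_matrix(states, model$n_genes, model$gene_names)
  if (any(S < 0)) stop("expression states must be >= 0", call. = FALSE)
  pc <- hill_precomp(model)
  scale_act <- scale_inh <- NULL
  if (!is.null(mask)) {
    scale_act <- mask[cbind(model$act$regulator, model$act$target)]
    scale_inh <- mask[cbind(model$inh$regulator, model$inh$target)]
  }
  f <- hill_rates(S, pc, scale_act = scale_act, scale_inh = scale_inh)
  colnames(f) <- model$gene_names
  f
}

as_state_matrix <- function(states, n_genes, gene_names) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  states <- as.matrix(states)
  if (ncol(states) != n_genes) {
    stop("state dimension (", ncol(states), ") does not match model (",
         n_genes, " genes)", call. = FALSE)
  }
  colnames(states) <- gene_names
  states
}

#' Sample random Hill parameters for a topology
#'
#' Every maximal rate `b` (activating edges) and half-saturation `K` (all
#' edges) is drawn i.i.d. from the unit-rate exponential distribution
#' `p(x) = exp(-x)`, the sampling scheme of the enumeration screen.
#'
#' @param topology Signed adjacency matrix (regulator x target, +1/-1/0).
#' @param hill_n,lambda Hill coefficient and degradation rate of the model.
#' @param clamped Clamped input-signal genes (names or indices).
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return A `hill_model` with sampled parameters.
#' @export
sample_hill_parameters <- function(topology, hill_n = 2, lambda = 1,
                                   clamped = character(), seed = 1) {
  stopifnot(is.matrix(topology), nrow(topology) == ncol(topology))
  gene_names <- rownames(topology)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(nrow(topology)))
  idx <- which(topology != 0, arr.ind = TRUE)
  sign <- topology[idx]
  set.seed(as.integer(seed))
  n_act <- sum(sign > 0)
  b <- rep(NA_real_, nrow(idx))
  b[sign > 0] <- stats::rexp(n_act)
  K <- stats::rexp(nrow(idx))
  edges <- data.frame(regulator = idx[, 1], target = idx[, 2],
                      sign = as.numeric(sign), b = b, K = K)
  hill_model(edges, gene_names = gene_names, hill_n = hill_n, lambda = lambda,
             clamped = clamped)
}
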