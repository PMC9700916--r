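#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the training trace of a synthesis model
#'
#' @param x A trained `mlp_synthesis`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss` (empty when untrained).
#' @export
tidy.mlp_synthesis <- function(x, ...) {
  x$report %||% tibble::tibble(epoch = integer(), loss = numeric())
}

#' One-row training summary of a synthesis model
#'
#' @param x A trained `mlp_synthesis`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `hidden1`, `hidden2`, `epochs`,
#'   `initial_loss`, `final_loss`, `seed`.
#' @export
glance.mlp_synthesis <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes, hidden1 = x$hidden[1], hidden2 = x$hidden[2],
    epochs = x$epochs_trained,
    initial_loss = if (!is.null(x$report) && nrow(x$report)) x$report$loss[1]
                   else NA_real_,
    final_loss = x$final_loss, seed = x$seed
  )
}

#' Tidy an inferred network into its edge list
#'
#' @param x A `grn_network`.
#' @param called_only Keep only edges with a nonzero sign call.
#' @param ... Unused.
#' @return A plain tibble of ranked edges.
#' @export
tidy.grn_network <- function(x, called_only = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (called_only) out <- out[out$sign != 0, ]
  out
}

#' One-row summary of an inferred network
#'
#' @param x A `grn_network`.
#' @param ... Unused.
#' @return Tibble with pair/edge counts by sign and the provenance tag.
#' @export
glance.grn_network <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_called = sum(x$sign != 0),
    n_activating = sum(x$sign > 0),
    n_inhibitory = sum(x$sign < 0),
    provenance = attr(x, "provenance") %||% NA_character_
  )
}

#' Tidy a pruning path
#'
#' @param x A `pruning_path` from [prune_network()].
#' @param ... Unused.
#' @return Tibble with one row per surviving topology: `step`, `n_edges`,
#'   `sensitivity`, `adaptation_error`, and the edge removed to reach it.
#' @export
tidy.pruning_path <- function(x, ...) {
  met <- dplyr::bind_rows(x$metrics)
  tibble::tibble(
    step = seq_along(x$networks) - 1L,
    n_edges = vapply(x$networks, nrow, 1L),
    sensitivity = met$sensitivity,
    adaptation_error = met$adaptation_error,
    removed_regulator = x$removed$regulator,
    removed_target = x$removed$target
  )
}

#' Plot the functional metrics along a pruning path
#'
#' @param object A `pruning_path`.
#' @param ... Unused.
#' @return A ggplot of sensitivity and adaptation error per pruning step.
#' @export
autoplot.pruning_path <- function(object, ...) {
  d <- tidy.pruning_path(object)
  long <- tidyr::pivot_longer(
    d[, c("step", "n_edges", "sensitivity", "adaptation_error")],
    cols = c("sensitivity", "adaptation_error"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pruning step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-section of a synthesis function
#'
#' @param model A `hill_model` or trained `mlp_synthesis`.
#' @param target,varied,at,fixed_state See [cross_section()].
#' @return A ggplot of the target's synthesis rate along the varied gene.
#' @export
plot_cross_section <- function(model, target, varied, at, fixed_state) {
  d <- cross_section(model, target, varied, at, fixed_state)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = d$varied[1], y = paste0("f(", target, ")")) +
    ggplot2::theme_minimal()
}
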