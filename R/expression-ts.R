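#' Expression time series on a uniform grid
#'
#' Container for one multivariate gene-expression trajectory sampled on a
#' strictly increasing, uniform time grid. Values are non-negative
#' concentrations, one column per gene. Genes whose trajectory is externally
#' imposed (input signals) are recorded in `clamped`; the simulators never
#' apply synthesis or degradation to them.
#'
#' @param values Numeric matrix, timepoints x genes, with gene names as
#'   column names. All entries must be finite and non-negative.
#' @param times Numeric vector of sampling times, strictly increasing and
#'   uniform to a relative tolerance of 1e-9.
#' @param clamped Character vector of clamped (input-signal) gene names.
#' @return An object of class `expression_ts` with fields `values`, `times`,
#'   `dt`, `gene_names` and `clamped`.
#' @export
expression_ts <- function(values, times, clamped = character()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("G", seq_len(ncol(values)))
  }
  if (length(times) != nrow(values)) {
    stop("`times` must have one entry per row of `values`", call. = FALSE)
  }
  if (length(times) < 2) stop("need at least two timepoints", call. = FALSE)
  if (!all(is.finite(values))) stop("expression values must be finite", call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  dt <- mean(dts)
  if (any(abs(dts - dt) > 1e-9 * max(abs(times), 1))) {
    stop("`times` must be a uniform grid (relative tolerance 1e-9)", call. = FALSE)
  }
  clamped <- as.character(clamped)
  bad <- setdiff(clamped, colnames(values))
  if (length(bad)) {
    stop("clamped genes not in data: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = values, times = as.numeric(times), dt = dt,
         gene_names = colnames(values), clamped = clamped),
    class = "expression_ts"
  )
}

#' @export
print.expression_ts <- function(x, ...) {
  cat("<expression_ts> ", length(x$gene_names), " genes x ",
      length(x$times), " timepoints (dt = ", format(x$dt), ")\n", sep = "")
  if (length(x$clamped)) {
    cat("  clamped input genes: ", paste(x$clamped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expression_ts <- function(x) dim(x$values)

#' Tidy a time series into long format
#'
#' @param x An `expression_ts`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `gene`, `value`, `clamped`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.expression_ts <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$gene_names)),
    gene = rep(x$gene_names, each = length(x$times)),
    value = as.vector(x$values),
    clamped = rep(x$gene_names %in% x$clamped, each = length(x$times))
  )
}

#' Plot expression trajectories
#'
#' @param object An `expression_ts`.
#' @param ... Unused.
#' @return A ggplot object, one line per gene (clamped inputs dashed).
#' @importFrom ggplot2 autoplot
#' @export
autoplot.expression_ts <- function(object, ...) {
  dat <- as_tibble.expression_ts(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$gene,
                                    linetype = .data$clamped)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "time", y = "expression", colour = "gene") +
    ggplot2::theme_minimal()
}

# rbind the values of one ts or a list of ts into a single states matrix
pool_states <- function(ts) {
  if (inherits(ts, "expression_ts")) ts <- list(ts)
  do.call(rbind, lapply(ts, function(s) s$values))
}

as_ts_list <- function(ts) {
  if (inherits(ts, "expression_ts")) list(ts) else ts
}
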