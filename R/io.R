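#' Read multi-series expression time courses
#'
#' Reads the tab-delimited multi-series dialect used by in-silico benchmark
#' generators: a header line starting with `Time` followed by one column per
#' gene, one block of rows per series, blocks separated by blank lines (a
#' repeated header at the start of a block is allowed). Lines starting with
#' `#` are comments. Each block must have a uniform time grid, monotone
#' times and non-negative values.
#'
#' @param path File path.
#' @param clamped Clamped input-signal gene names recorded on each series.
#' @return A list of [expression_ts].
#' @export
read_timeseries <- function(path, clamped = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  is_blank <- grepl("^\\s*$", lines)
  block_id <- cumsum(c(TRUE, diff(is_blank) == -1))
  block_id[is_blank] <- NA
  blocks <- split(seq_along(lines)[!is_blank], block_id[!is_blank])
  header <- NULL
  out <- list()
  for (b in blocks) {
    rows <- lines[b]
    if (grepl("^\"?Time", rows[1], ignore.case = TRUE)) {
      h <- strsplit(rows[1], "\t", fixed = TRUE)[[1]]
      h <- gsub("^\"|\"$", "", h)
      if (is.null(header)) header <- h
      else if (!identical(header, h)) {
        stop("inconsistent headers between series blocks", call. = FALSE)
      }
      rows <- rows[-1]
    }
    if (is.null(header)) {
      stop("file must start with a header line beginning with 'Time'",
           call. = FALSE)
    }
    if (!length(rows)) next
    fields <- strsplit(rows, "\t", fixed = TRUE)
    n_col <- length(header)
    ragged <- which(vapply(fields, length, 1L) != n_col)
    if (length(ragged)) {
      stop("ragged row at line ", b[1] + ragged[1], " of ", path, call. = FALSE)
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = n_col, byrow = TRUE)
    if (anyNA(m)) {
      stop("non-numeric value near line ", b[1], " of ", path, call. = FALSE)
    }
    vals <- m[, -1, drop = FALSE]
    colnames(vals) <- header[-1]
    if (any(diff(m[, 1]) <= 0)) {
      stop("non-monotone times in block starting at line ", b[1], call. = FALSE)
    }
    if (any(vals < 0)) {
      stop("negative expression value in block starting at line ", b[1],
           call. = FALSE)
    }
    out[[length(out) + 1]] <- expression_ts(vals, m[, 1], clamped = clamped)
  }
  if (!length(out)) stop("no data blocks found in ", path, call. = FALSE)
  out
}

#' Write multi-series expression time courses
#'
#' @param ts An [expression_ts] or list of them (shared gene set).
#' @param path File path.
#' @param comment Optional character vector of comment lines (written with a
#'   `#` prefix, e.g. seed and configuration hash).
#' @export
write_timeseries <- function(ts, path, comment = NULL) {
  ts <- as_ts_list(ts)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("Time", ts[[1]]$gene_names), collapse = "\t"), con)
  for (s in seq_along(ts)) {
    if (s > 1) writeLines("", con)
    m <- cbind(ts[[s]]$times, ts[[s]]$values)
    writeLines(apply(m, 1, function(r) {
      paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = "\t")
    }), con)
  }
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Tab-delimited rows `regulator TAB target TAB {0,1}`; rows with label 1 are
#' edges, rows with label 0 are explicit non-edges (ignored beyond expanding
#' the gene universe). Duplicate pairs raise an error.
#'
#' @param path File path.
#' @param gene_names,tfs Optional full gene universe / TF subset (defaults:
#'   genes appearing in the file; all genes).
#' @param exclude_self Drop self-pairs from the candidate universe; by
#'   default inferred from the file (`FALSE` when it lists a self-edge).
#' @return A [gold_standard()].
#' @export
read_gold <- function(path, gene_names = NULL, tfs = NULL,
                      exclude_self = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("regulator", "target", "label"),
                         colClasses = c("character", "character", "integer"),
                         comment.char = "#")
  if (anyDuplicated(d[, c("regulator", "target")])) {
    stop("duplicate edges in ", path, call. = FALSE)
  }
  if (!all(d$label %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  if (is.null(gene_names)) gene_names <- unique(c(d$regulator, d$target))
  edges <- d[d$label == 1L, c("regulator", "target")]
  if (is.null(exclude_self)) {
    exclude_self <- !any(edges$regulator == edges$target)
  }
  gold_standard(edges, gene_names = gene_names, tfs = tfs,
                exclude_self = exclude_self)
}

#' Write a gold-standard edge list
#'
#' @param gold A `gold_standard`.
#' @param path File path.
#' @param comment Optional comment lines.
#' @export
write_gold <- function(gold, path, comment = NULL) {
  stopifnot(inherits(gold, "gold_standard"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(gold$edges$regulator, gold$edges$target, "1", sep = "\t"), con)
  invisible(path)
}

#' Write ranked edge predictions
#'
#' Benchmark-compatible unsigned prediction list,
#' `regulator TAB target TAB weight`, in descending weight order.
#'
#' @param pred Tibble with `regulator`, `target`, `weight` (e.g. a
#'   `grn_network`).
#' @param path File path.
#' @param comment Optional comment lines.
#' @export
write_predictions <- function(pred, path, comment = NULL) {
  pred <- tibble::as_tibble(pred)[, c("regulator", "target", "weight")]
  pred <- pred[order(-pred$weight), ]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("regulator\ttarget\tweight", con)
  if (nrow(pred)) {
    writeLines(paste(pred$regulator, pred$target,
                     format(pred$weight, digits = 15, trim = TRUE), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read ranked edge predictions
#'
#' @param path File written by [write_predictions()] (header optional).
#' @return Tibble `regulator`, `target`, `weight`, sorted descending.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^\\s*$", lines)]
  if (length(lines) && grepl("^regulator\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) {
    return(tibble::tibble(regulator = character(), target = character(),
                          weight = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(f, length, 1L) != 3L)) {
    stop("prediction rows must be 'regulator TAB target TAB weight'", call. = FALSE)
  }
  d <- tibble::tibble(regulator = vapply(f, `[[`, "", 1),
                      target = vapply(f, `[[`, "", 2),
                      weight = as.numeric(vapply(f, `[[`, "", 3)))
  if (anyDuplicated(d[, 1:2])) stop("duplicate edges in ", path, call. = FALSE)
  d[order(-d$weight), ]
}

#' Write a signed ranked network
#'
#' `regulator TAB target TAB weight TAB sign` in descending weight order.
#'
#' @param net A `grn_network` (or tibble with those columns).
#' @param path File path.
#' @param comment Optional comment lines.
#' @export
write_network <- function(net, path, comment = NULL) {
  net <- tibble::as_tibble(net)[, c("regulator", "target", "weight", "sign")]
  net <- net[order(-net$weight), ]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("regulator\ttarget\tweight\tsign", con)
  if (nrow(net)) {
    writeLines(paste(net$regulator, net$target,
                     format(net$weight, digits = 15, trim = TRUE),
                     net$sign, sep = "\t"), con)
  }
  invisible(path)
}

#' Write / read a Hill circuit as a flat text file
#'
#' One row per link, `regulator TAB target TAB sign TAB b TAB K` (b is `NA`
#' on inhibitory links), with model constants in `#`-prefixed key-value
#' header lines.
#'
#' @param model A `hill_model`.
#' @param path File path.
#' @export
write_hill_model <- function(model, path) {
  stopifnot(inherits(model, "hill_model"))
  e <- hill_edges(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# genes=", paste(model$gene_names, collapse = ",")),
    paste0("# hill_n=", model$hill_n),
    paste0("# lambda=", format(model$lambda, digits = 15)),
    paste0("# clamped=", paste(model$gene_names[model$clamped], collapse = ","))
  ), con)
  writeLines("regulator\ttarget\tsign\tb\tK", con)
  writeLines(paste(e$regulator, e$target, e$sign,
                   format(e$b, digits = 15, trim = TRUE),
                   format(e$K, digits = 15, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_hill_model
#' @export
read_hill_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^# ", lines)]
  get <- function(key) {
    v <- sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
    if (!length(v)) stop("missing header '# ", key, "=' in ", path, call. = FALSE)
    v[1]
  }
  genes <- strsplit(get("genes"), ",", fixed = TRUE)[[1]]
  clamped <- strsplit(get("clamped"), ",", fixed = TRUE)[[1]]
  clamped <- clamped[nzchar(clamped)]
  body <- lines[!grepl("^#", lines) & !grepl("^\\s*$", lines)]
  body <- body[-1]  # column header
  f <- strsplit(body, "\t", fixed = TRUE)
  edges <- data.frame(
    regulator = vapply(f, `[[`, "", 1),
    target = vapply(f, `[[`, "", 2),
    sign = as.numeric(vapply(f, `[[`, "", 3)),
    b = suppressWarnings(as.numeric(vapply(f, `[[`, "", 4))),
    K = as.numeric(vapply(f, `[[`, "", 5))
  )
  hill_model(edges, gene_names = genes,
             hill_n = as.numeric(get("hill_n")),
             lambda = as.numeric(get("lambda")),
             clamped = clamped)
}

#' Serialise a trained synthesis model to JSON
#'
#' The checkpoint stores the architecture, weights, normalisation constants,
#' degradation/time-step constants, clamped genes, any forced knockout mask,
#' and the training seed, so a reloaded model reproduces its outputs exactly.
#'
#' @param model An `mlp_synthesis`.
#' @param path File path (JSON).
#' @export
write_synthesis_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_synthesis"))
  obj <- list(
    gene_names = model$gene_names, hidden = model$hidden,
    lambda = model$lambda, dt = model$dt, clamped = model$clamped,
    seed = model$seed, epochs_trained = model$epochs_trained,
    final_loss = model$final_loss,
    norm = model$norm,
    params = lapply(model$params, unclass)
  )
  if (!is.null(model$mask)) obj$mask <- model$mask
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_synthesis_model
#' @export
read_synthesis_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- build_synthesis_model(obj$gene_names, hidden = obj$hidden,
                             seed = obj$seed, lambda = obj$lambda,
                             dt = obj$dt, clamped = as.character(obj$clamped))
  to_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  m$params <- list(
    W1 = to_mat(obj$params$W1), b1 = as.numeric(obj$params$b1),
    W2 = to_mat(obj$params$W2), b2 = as.numeric(obj$params$b2),
    W3 = to_mat(obj$params$W3), b3 = as.numeric(obj$params$b3)
  )
  if (!is.null(obj$norm)) {
    m$norm <- list(min = stats::setNames(as.numeric(obj$norm$min), obj$gene_names),
                   range = stats::setNames(as.numeric(obj$norm$range), obj$gene_names))
  }
  if (!is.null(obj$mask) && length(obj$mask)) {
    m$mask <- matrix(as.numeric(to_mat(obj$mask)), length(m$gene_names))
  }
  m$epochs_trained <- as.integer(obj$epochs_trained)
  m$final_loss <- if (length(obj$final_loss)) as.numeric(obj$final_loss)
                  else NA_real_
  m
}
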