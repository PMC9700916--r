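#' Gold-standard edge set
#'
#' Wraps a known regulatory network for benchmark scoring. The candidate
#' pair universe follows the DREAM convention: ordered (TF, gene) pairs with
#' self-edges excluded.
#'
#' @param edges Tibble/data frame with columns `regulator` and `target`
#'   listing the true edges (gene names).
#' @param gene_names All genes of the network (default: names appearing in
#'   `edges`).
#' @param tfs Allowed regulators (default: all genes).
#' @param exclude_self Drop self-pairs from the candidate universe
#'   (default TRUE).
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(edges, gene_names = NULL, tfs = NULL,
                          exclude_self = TRUE) {
  edges <- tibble::as_tibble(edges)[, c("regulator", "target")]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (is.null(gene_names)) {
    gene_names <- unique(c(edges$regulator, edges$target))
  }
  if (is.null(tfs)) tfs <- gene_names
  bad <- setdiff(c(edges$regulator, edges$target), gene_names)
  if (length(bad)) stop("edges name unknown genes: ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  if (!all(edges$regulator %in% tfs)) {
    stop("gold edges must originate from TFs", call. = FALSE)
  }
  if (anyDuplicated(edges)) stop("duplicate edges in gold standard", call. = FALSE)
  if (exclude_self && any(edges$regulator == edges$target)) {
    stop("gold standard contains self-edges but `exclude_self` is TRUE",
         call. = FALSE)
  }
  structure(
    list(gene_names = gene_names, tfs = tfs, edges = edges,
         exclude_self = exclude_self),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> ", length(x$gene_names), " genes, ", length(x$tfs),
      " TFs, ", nrow(x$edges), " edges (density ",
      network_density(length(x$gene_names), length(x$tfs), nrow(x$edges)),
      ")\n", sep = "")
  invisible(x)
}

#' Candidate ordered pairs of a gold standard
#'
#' @param gold A `gold_standard`.
#' @return Tibble of all scorable (regulator, target) pairs with a logical
#'   `truth` column.
#' @export
candidate_pairs <- function(gold) {
  stopifnot(inherits(gold, "gold_standard"))
  cand <- expand.grid(regulator = gold$tfs, target = gold$gene_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (gold$exclude_self) cand <- cand[cand$regulator != cand$target, ]
  key <- paste(cand$regulator, cand$target, sep = "\r")
  truth_key <- paste(gold$edges$regulator, gold$edges$target, sep = "\r")
  cand$truth <- key %in% truth_key
  tibble::as_tibble(cand)
}

#' Binarise a ranked prediction at top k
#'
#' Marks exactly `min(k, n)` pairs as positive calls, ranking by weight
#' (descending) with ties broken by regulator then target index in
#' `gene_names` order.
#'
#' @param pred Tibble with columns `regulator`, `target`, `weight`.
#' @param k Number of positive calls.
#' @param gene_names Gene ordering used for tie-breaks (default: order of
#'   first appearance).
#' @return `pred` sorted by rank with a logical `predicted` column.
#' @export
top_k_binarize <- function(pred, k, gene_names = NULL) {
  stopifnot(k >= 0)
  pred <- tibble::as_tibble(pred)
  if (is.null(gene_names)) {
    gene_names <- unique(c(pred$regulator, pred$target))
  }
  ord <- order(-pred$weight, match(pred$regulator, gene_names),
               match(pred$target, gene_names))
  pred <- pred[ord, ]
  pred$predicted <- seq_len(nrow(pred)) <= min(k, nrow(pred))
  pred
}

#' Confusion metrics of a binary edge prediction
#'
#' Standard 2x2 confusion-table metrics over the candidate pair universe of
#' the gold standard: true positive rate, false positive rate, Matthews
#' correlation coefficient (0 when any marginal is zero), accuracy and F1.
#' Predicted pairs outside the candidate universe (e.g. self-edge calls
#' scored against a DREAM-style gold standard) are dropped before scoring.
#'
#' @param pred Either a tibble with a logical `predicted` column (from
#'   [top_k_binarize()]) or a tibble of positively-called pairs.
#' @param gold A `gold_standard`.
#' @return One-row tibble: `tpr`, `fpr`, `mcc`, `acc`, `f1`, plus the raw
#'   cells `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(pred, gold) {
  cand <- candidate_pairs(gold)
  pred <- tibble::as_tibble(pred)
  bad <- setdiff(unique(c(pred$regulator, pred$target)), gold$gene_names)
  if (length(bad)) {
    stop("prediction names unknown genes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pos <- if ("predicted" %in% names(pred)) pred[pred$predicted, ] else pred
  key_cand <- paste(cand$regulator, cand$target, sep = "\r")
  key_pos <- unique(paste(pos$regulator, pos$target, sep = "\r"))
  called <- key_cand %in% key_pos
  tp <- sum(called & cand$truth)
  fp <- sum(called & !cand$truth)
  fn <- sum(!called & cand$truth)
  tn <- sum(!called & !cand$truth)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  acc <- (tp + tn) / (tp + fp + fn + tn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  tibble::tibble(tpr = tpr, fpr = fpr, mcc = mcc, acc = acc, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Threshold-free ranking metrics: AUROC and AUPR
#'
#' AUROC is computed tie-aware in the Mann-Whitney sense (probability that a
#' random true edge outranks a random non-edge, ties counted half), which
#' equals trapezoidal integration of the ROC curve across all thresholds.
#' AUPR is step-wise precision-recall integration with tied weights processed
#' as blocks. Candidate pairs missing from the prediction are appended with
#' weight 0.
#'
#' @param pred Tibble with columns `regulator`, `target`, `weight` (finite).
#' @param gold A `gold_standard`; must contain at least one positive.
#' @return One-row tibble: `auroc`, `aupr`.
#' @export
auroc_aupr <- function(pred, gold) {
  cand <- candidate_pairs(gold)
  pred <- tibble::as_tibble(pred)
  if (!all(is.finite(pred$weight))) stop("weights must be finite", call. = FALSE)
  bad <- setdiff(unique(c(pred$regulator, pred$target)), gold$gene_names)
  if (length(bad)) {
    stop("prediction names unknown genes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key_cand <- paste(cand$regulator, cand$target, sep = "\r")
  key_pred <- paste(pred$regulator, pred$target, sep = "\r")
  w <- numeric(nrow(cand))
  w[match(key_pred, key_cand)] <- pred$weight
  y <- cand$truth
  P <- sum(y)
  N <- sum(!y)
  if (P == 0) stop("gold standard has zero positives; AUROC/AUPR undefined",
                   call. = FALSE)
  if (N == 0) stop("gold standard has zero negatives; AUROC/AUPR undefined",
                   call. = FALSE)
  r <- rank(w)  # average ranks handle ties (half credit)
  auroc <- (sum(r[y]) - P * (P + 1) / 2) / (P * N)
  # step-wise PR: descending weight, tied blocks enter together
  ord <- order(-w)
  ws <- w[ord]
  ys <- y[ord]
  block <- cumsum(!duplicated(ws))
  tp_b <- tapply(ys, block, sum)
  n_b <- tapply(rep(1, length(ys)), block, sum)
  tp_cum <- cumsum(tp_b)
  n_cum <- cumsum(n_b)
  precision <- tp_cum / n_cum
  recall <- tp_cum / P
  aupr <- sum(precision * diff(c(0, recall)))
  tibble::tibble(auroc = auroc, aupr = aupr)
}

#' Edge density of a network
#'
#' Density of a directed network over the (TF, gene) candidate space,
#' `n_edges / (n_genes * n_tfs)`, reported to 4 decimals.
#'
#' @param n_genes,n_tfs,n_edges Positive counts (`n_edges` may be 0).
#' @return Density rounded to 4 decimal places.
#' @export
network_density <- function(n_genes, n_tfs, n_edges) {
  if (n_genes <= 0 || n_tfs <= 0) stop("counts must be positive", call. = FALSE)
  if (n_edges < 0) stop("`n_edges` must be >= 0", call. = FALSE)
  round(n_edges / (n_genes * n_tfs), 4)
}
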