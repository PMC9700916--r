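# Shared fixtures, memoised so expensive trainings run once per suite.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fb_circuit <- function() make_preset_circuit("adapt_feedback")
iffl_circuit <- function() make_preset_circuit("iffl_adaptive")

# Noiseless pulse-perturbation series from the feedback circuit.
fb_series <- function() {
  memo("fb_series", generate_timeseries(fb_circuit(), n_series = 8,
                                        n_timepoints = 41, dt = 1, seed = 7))
}

# Synthesis network trained on the feedback-circuit series.
fb_model <- function() {
  memo("fb_model", {
    nn <- build_synthesis_model(c("g1", "g2", "g3"), seed = 3, clamped = "g1")
    train_synthesis(nn, fb_series(), epochs = 1500)
  })
}

iffl_series <- function() {
  memo("iffl_series", generate_timeseries(iffl_circuit(), n_series = 8,
                                          n_timepoints = 41, dt = 1, seed = 1))
}

iffl_model <- function() {
  memo("iffl_model", {
    nn <- build_synthesis_model(c("g1", "g2", "g3"), seed = 101, clamped = "g1")
    train_synthesis(nn, iffl_series(), epochs = 2000)
  })
}

# Small random gold standard + weights for metric tests.
random_instance <- function(seed, n_genes = 10, p_edge = 0.2, tie_digits = NULL) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  cand <- expand.grid(regulator = genes, target = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand <- cand[cand$regulator != cand$target, ]
  truth <- stats::runif(nrow(cand)) < p_edge
  if (!any(truth)) truth[sample.int(length(truth), 1)] <- TRUE
  w <- stats::runif(nrow(cand))
  if (!is.null(tie_digits)) w <- round(w, tie_digits)
  gold <- gold_standard(cand[truth, c("regulator", "target")],
                        gene_names = genes)
  pred <- tibble::tibble(regulator = cand$regulator, target = cand$target,
                         weight = w)
  list(gold = gold, pred = pred, cand = cand, truth = truth)
}

# Brute-force oracles, independent of the implementation under test.
oracle_confusion <- function(pred_pos_keys, cand, truth) {
  key <- paste(cand$regulator, cand$target)
  called <- key %in% pred_pos_keys
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(key)) {
    if (called[i] && truth[i]) tp <- tp + 1
    else if (called[i] && !truth[i]) fp <- fp + 1
    else if (!called[i] && truth[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_auroc <- function(w, truth) {
  pos <- w[truth]
  neg <- w[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(w, truth) {
  P <- sum(truth)
  thr <- sort(unique(w), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- w >= t
    tp <- sum(called & truth)
    prec <- tp / sum(called)
    rec <- tp / P
    area <- area + prec * (rec - prev_recall)
    prev_recall <- rec
  }
  area
}
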