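test_that("top-k binarisation calls exactly k pairs with deterministic ties", {
  pred <- tibble::tibble(regulator = c("G1", "G2", "G3", "G1"),
                         target = c("G2", "G3", "G1", "G3"),
                         weight = c(0.5, 0.5, 0.9, 0.1))
  expect_equal(sum(top_k_binarize(pred, 0)$predicted), 0)
  expect_equal(sum(top_k_binarize(pred, 10)$predicted), 4)
  b2 <- top_k_binarize(pred, 2, gene_names = paste0("G", 1:3))
  expect_equal(sum(b2$predicted), 2)
  # tie at the cutoff broken by regulator index: G1>G2 beats G2>G3
  expect_true(b2$predicted[b2$regulator == "G1" & b2$target == "G2"])
  expect_false(b2$predicted[b2$regulator == "G2" & b2$target == "G3"])
})

test_that("confusion metrics hit the textbook endpoints", {
  inst <- random_instance(1)
  gold <- inst$gold
  pos <- inst$cand[inst$truth, ]
  perfect <- confusion_metrics(pos, gold)
  expect_equal(perfect[, c("tpr", "fpr", "mcc", "acc", "f1")],
               tibble::tibble(tpr = 1, fpr = 0, mcc = 1, acc = 1, f1 = 1))
  compl <- confusion_metrics(inst$cand[!inst$truth, ], gold)
  expect_equal(compl$tpr, 0)
  expect_equal(compl$f1, 0)
  # zero-marginal convention: empty prediction has MCC 0
  none <- confusion_metrics(inst$cand[0, ], gold)
  expect_equal(none$mcc, 0)
  expect_error(confusion_metrics(tibble::tibble(regulator = "XX", target = "G1"),
                                 gold), "XX")
})

test_that("confusion metrics agree with a cell-counting oracle on 200 instances", {
  for (sd in 1:200) {
    inst <- random_instance(sd, n_genes = 6, p_edge = runif(1, 0.1, 0.5))
    k <- sample(0:nrow(inst$cand), 1)
    bin <- top_k_binarize(inst$pred, k, gene_names = inst$gold$gene_names)
    got <- confusion_metrics(bin, inst$gold)
    pos <- bin[bin$predicted, ]
    cells <- oracle_confusion(paste(pos$regulator, pos$target),
                              inst$cand, inst$truth)
    tp <- cells["tp"]; fp <- cells["fp"]; fn <- cells["fn"]; tn <- cells["tn"]
    expect_equal(got$tp, unname(tp))
    expect_equal(got$tn, unname(tn))
    expect_equal(got$tpr, unname(if (tp + fn > 0) tp / (tp + fn) else 0),
                 tolerance = 1e-12)
    expect_equal(got$acc, unname((tp + tn) / sum(cells)), tolerance = 1e-12)
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (denom > 0) unname((tp * tn - fp * fn) / denom) else 0
    expect_equal(got$mcc, mcc, tolerance = 1e-12)
  }
})

test_that("AUROC and AUPR agree with brute-force oracles on 200 instances", {
  for (sd in 1:200) {
    # half the instances have heavy ties
    inst <- random_instance(sd + 500, n_genes = 6, p_edge = runif(1, 0.1, 0.5),
                            tie_digits = if (sd %% 2) 1 else NULL)
    got <- auroc_aupr(inst$pred, inst$gold)
    expect_equal(got$auroc, oracle_auroc(inst$pred$weight, inst$truth),
                 tolerance = 1e-9)
    expect_equal(got$aupr, oracle_aupr(inst$pred$weight, inst$truth),
                 tolerance = 1e-9)
  }
})

test_that("ranking metrics hit their analytic endpoints and null behaviour", {
  inst <- random_instance(3, n_genes = 8, p_edge = 0.25)
  # gold edges strictly above all non-edges: both areas are 1
  sep <- inst$pred
  sep$weight <- ifelse(inst$truth, 2 + runif(nrow(sep)), runif(nrow(sep)))
  expect_equal(auroc_aupr(sep, inst$gold),
               tibble::tibble(auroc = 1, aupr = 1))
  # random scores on a large instance: AUROC near 1/2
  big <- random_instance(4, n_genes = 101, p_edge = 0.03)
  expect_lt(abs(auroc_aupr(big$pred, big$gold)$auroc - 0.5), 0.05)
  # unpredicted candidates are appended with weight 0
  partial <- sep[sep$weight > 2, ]
  expect_equal(auroc_aupr(partial, inst$gold)$auroc, 1)
  # degenerate gold: no positives
  empty_gold <- inst$gold
  empty_gold$edges <- empty_gold$edges[0, ]
  expect_error(auroc_aupr(sep, empty_gold), "zero positives")
})

test_that("metric invariances and bounds hold across random rankings", {
  inst <- random_instance(9, n_genes = 8, p_edge = 0.3)
  base <- auroc_aupr(inst$pred, inst$gold)
  # AUROC invariant under strictly monotone weight transforms
  tr <- inst$pred
  tr$weight <- exp(3 * tr$weight) + 1
  expect_equal(auroc_aupr(tr, inst$gold)$auroc, base$auroc, tolerance = 1e-12)
  # all-tied ranking: AUPR equals the positive-rate baseline exactly
  flat <- inst$pred
  flat$weight <- 1
  baseline <- sum(inst$truth) / nrow(inst$pred)
  expect_equal(auroc_aupr(flat, inst$gold)$aupr, baseline, tolerance = 1e-12)
  expect_equal(auroc_aupr(flat, inst$gold)$auroc, 0.5, tolerance = 1e-12)
  # mean AUPR over random rankings clears the baseline
  auprs <- vapply(1:40, function(s) {
    set.seed(s + 2000)
    p <- inst$pred
    p$weight <- runif(nrow(p))
    auroc_aupr(p, inst$gold)$aupr
  }, numeric(1))
  expect_gt(mean(auprs), baseline)
  # adding a true positive never decreases TPR, ACC or F1
  set.seed(1)
  bin <- top_k_binarize(inst$pred, 12, gene_names = inst$gold$gene_names)
  before <- confusion_metrics(bin, inst$gold)
  missing_tp <- !bin$predicted &
    paste(bin$regulator, bin$target) %in%
      paste(inst$cand$regulator[inst$truth], inst$cand$target[inst$truth])
  bin$predicted[which(missing_tp)[1]] <- TRUE
  after <- confusion_metrics(bin, inst$gold)
  expect_gte(after$tpr, before$tpr)
  expect_gte(after$acc, before$acc)
  expect_gte(after$f1, before$f1)
})

test_that("network density matches the printed benchmark descriptors", {
  expect_identical(network_density(100, 100, 176), 0.0176)
  expect_identical(network_density(100, 100, 249), 0.0249)
  expect_identical(network_density(1484, 163, 3080), 0.0127)
  expect_identical(network_density(10, 10, 0), 0)
  expect_error(network_density(0, 10, 5), "positive")
})
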