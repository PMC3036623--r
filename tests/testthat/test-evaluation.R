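two_dom_def <- function(id, b = 100L, L = 220L)
  domain_definition(id, cbind(c(1L, b + 1L), c(b, L)))

test_that("signal coverage counts boundary points within the tolerance", {
  defs <- list(two_dom_def("A"), two_dom_def("B"))
  # saturation: co-located sites
  cov <- signal_coverage(list(A = c(100L), B = c(101L)), defs)
  expect_equal(cov$coverage, 1.0)
  # no sites at all
  cov0 <- signal_coverage(list(A = integer(0), B = integer(0)), defs)
  expect_equal(cov0$coverage, 0.0)
  # inclusive tolerance: site at 80 reaches point 100 (d = 20), misses 101
  cov5 <- signal_coverage(list(A = c(80L)), list(two_dom_def("A")))
  expect_equal(cov5$coverage, 0.5)
  # single-domain-only truth: undefined, flagged
  und <- signal_coverage(list(S = c(10L)),
                         list(domain_definition("S", cbind(1, 90))))
  expect_true(is.na(und$coverage))
  expect_false(und$defined)
})

pred_row <- function(chain, pos, s2, s1 = 1) {
  data.frame(chain_id = chain, position = pos, stage1_score = s1,
             stage2_score = s2, stringsAsFactors = FALSE)
}

test_that("site-level precision and boundary-level recall are computed correctly", {
  defs <- list(two_dom_def("A"), two_dom_def("B"), two_dom_def("C"))
  # all NEAR calls within tolerance: precision 1
  p <- site_pr(rbind(pred_row("A", 95L, 1), pred_row("B", 110L, 1)), defs, 0)
  expect_equal(p$precision, 1.0)

  # threshold above every score: no calls, precision undefined, recall 0
  p2 <- site_pr(pred_row("A", 95L, 1), defs, 5)
  expect_true(is.na(p2$precision))
  expect_equal(p2$recall, 0)
  expect_equal(p2$n_predicted, 0L)

  # duplicate sites near one boundary count once in recall: chains A and B
  # recalled (two sites each), C missed -> 4 of 6 eligible points
  preds <- rbind(pred_row("A", 98L, 1), pred_row("A", 103L, 1),
                 pred_row("B", 95L, 1), pred_row("B", 99L, 1),
                 pred_row("C", 180L, 1))
  p3 <- site_pr(preds, defs, 0)
  expect_equal(p3$recall, 4 / 6)
  expect_equal(p3$n_eligible, 6L)

  # boundaries too close to a terminus are excluded from the recall pool
  near_term <- domain_definition("T", cbind(c(1L, 31L), c(30L, 300L)))
  p4 <- site_pr(pred_row("T", 30L, 1), list(near_term), 0)
  expect_equal(p4$n_eligible, 0L)
  expect_true(is.na(p4$recall))
  expect_equal(p4$precision, 1.0)  # the call is still correct
})

test_that("site-level metrics agree with a brute-force confusion computation", {
  set.seed(40)
  defs <- lapply(1:5, function(i) two_dom_def(paste0("c", i),
                                              b = sample(80:130, 1), L = 260L))
  preds <- do.call(rbind, lapply(defs, function(d) {
    pos <- sample(10:250, 8)
    pred_row(d$chain_id, pos, rnorm(8), s1 = rnorm(8, 0.5))
  }))
  for (th in c(-0.5, 0, 0.5)) {
    got <- site_pr(preds, defs, th)
    # independent recomputation
    near <- preds[preds$stage1_score > 0 & preds$stage2_score > th, ]
    corr <- 0L
    for (i in seq_len(nrow(near))) {
      bp <- boundary_points(defs[[match(near$chain_id[i],
                                        vapply(defs, `[[`, character(1), "chain_id"))]])
      if (min(abs(near$position[i] - bp)) <= 20) corr <- corr + 1L
    }
    expect_equal(got$n_correct, corr)
    rec <- 0L; elig <- 0L
    for (d in defs) {
      for (b in boundary_points(d)) {
        if (b - 1 <= 40 || max(d$ranges$end) - b <= 40) next
        elig <- elig + 1L
        pos <- near$position[near$chain_id == d$chain_id]
        if (length(pos) && min(abs(pos - b)) <= 20) rec <- rec + 1L
      }
    }
    expect_equal(got$n_recalled, rec)
    expect_equal(got$n_eligible, elig)
  }
})

test_that("recall is monotone non-increasing along the threshold sweep", {
  set.seed(41)
  defs <- lapply(1:6, function(i) two_dom_def(paste0("c", i)))
  preds <- do.call(rbind, lapply(defs, function(d)
    pred_row(d$chain_id, sample(10:210, 6), rnorm(6), s1 = rnorm(6, 0.3))))
  curve <- pr_curve(preds, defs)
  rec <- curve$recall[!is.na(curve$recall)]
  expect_true(all(diff(rec) <= 1e-12))
})

test_that("the break-even point is located by interpolation at the crossing", {
  # constant curves
  const <- data.frame(threshold = seq(-1, 1, 0.5), precision = 0.6, recall = 0.6)
  expect_equal(break_even(const), 0.6)
  # strictly positive gap: no crossing
  gap <- data.frame(threshold = seq(-1, 1, 0.5), precision = 0.9, recall = 0.2)
  expect_true(is.na(break_even(gap)))
  # piecewise-linear curves crossing between grid points: hand computation
  th <- c(0.10, 0.15)
  hand <- data.frame(threshold = th, precision = c(0.40, 0.55),
                     recall = c(0.60, 0.45))
  expect_equal(break_even(hand), 0.40 + (0.20 / 0.30) * 0.15)  # 0.5
  # linear curves: coarse-grid interpolation matches a fine-grid brute force
  p_fun <- function(t) 0.3 + t
  r_fun <- function(t) 0.9 - 2 * t
  coarse <- data.frame(threshold = seq(0, 0.3, 0.05),
                       precision = p_fun(seq(0, 0.3, 0.05)),
                       recall = r_fun(seq(0, 0.3, 0.05)))
  fine <- data.frame(threshold = seq(0, 0.3, 0.0005),
                     precision = p_fun(seq(0, 0.3, 0.0005)),
                     recall = r_fun(seq(0, 0.3, 0.0005)))
  expect_equal(break_even(coarse), break_even(fine), tolerance = 1e-3)
  expect_equal(break_even(coarse), 0.5, tolerance = 1e-9)
})

test_that("break-even on constructed score sets matches a fine-grid sweep", {
  # 10 chains, one transition each; true sites score 0.5 (6 chains) or 0.0
  # (4 chains); off-boundary sites score 0.5 (4) or 0.0 (6)
  defs <- lapply(1:10, function(i) two_dom_def(paste0("c", i)))
  true_scores <- c(rep(0.5, 6), rep(0.0, 4))
  false_scores <- c(rep(0.5, 4), rep(0.0, 6))
  preds <- do.call(rbind, lapply(1:10, function(i) rbind(
    pred_row(paste0("c", i), 100L, true_scores[i]),
    pred_row(paste0("c", i), 160L, false_scores[i]))))
  coarse <- pr_curve(preds, defs)
  fine <- pr_curve(preds, defs, thresholds = seq(-1.5, 1.5, 0.0005))
  be_c <- break_even(coarse)
  be_f <- break_even(fine)
  expect_equal(be_c, 0.6, tolerance = 1e-9)
  expect_equal(be_c, be_f, tolerance = 1e-3)
})

test_that("protein-level metrics match confusion-matrix arithmetic", {
  mk <- function(n, call) data.frame(chain_id = character(n), call = call,
                                     stringsAsFactors = FALSE)
  # perfect calls
  truth <- data.frame(chain_id = c("a", "b"), call = c("SINGLE_DOMAIN", "MULTI_DOMAIN"))
  pm <- protein_metrics(truth, truth)
  expect_equal(unlist(pm[c("accuracy", "single_precision", "single_recall",
                           "multi_precision", "multi_recall")]),
               setNames(rep(1, 5), c("accuracy", "single_precision",
                                     "single_recall", "multi_precision",
                                     "multi_recall")))
  # all-single calls on a half/half truth
  ids <- paste0("c", 1:20)
  truth2 <- data.frame(chain_id = ids,
                       call = rep(c("SINGLE_DOMAIN", "MULTI_DOMAIN"), each = 10))
  calls2 <- data.frame(chain_id = ids, call = "SINGLE_DOMAIN")
  pm2 <- protein_metrics(calls2, truth2)
  expect_equal(pm2$accuracy, 0.5)
  expect_equal(pm2$multi_recall, 0)
  expect_true(is.na(pm2$multi_precision))
  # printed confusion toy: TP=68, FP=32, FN=28, TN=72
  ids3 <- paste0("p", 1:200)
  truth3 <- data.frame(chain_id = ids3,
                       call = c(rep("MULTI_DOMAIN", 68), rep("SINGLE_DOMAIN", 32),
                                rep("MULTI_DOMAIN", 28), rep("SINGLE_DOMAIN", 72)))
  calls3 <- data.frame(chain_id = ids3,
                       call = c(rep("MULTI_DOMAIN", 100), rep("SINGLE_DOMAIN", 100)))
  pm3 <- protein_metrics(calls3, truth3)
  expect_equal(pm3$multi_precision, 0.68)
  expect_equal(pm3$multi_recall, 68 / 96, tolerance = 1e-9)
  # unknown chain in calls
  expect_error(protein_metrics(data.frame(chain_id = "zz", call = "SINGLE_DOMAIN"),
                               truth), "missing from truth")
})

test_that("cross-validation splits at protein level with balanced folds", {
  ds <- simulate_dataset(sim_preset("easy", n_chains = 12, seed = 3))
  rep4 <- crossval(ds$chains, k = 4, seed = 9)
  expect_equal(sort(as.integer(table(rep4$folds))), rep(3L, 4))
  # deterministic fold assignment under a fixed seed
  rep4b <- crossval(ds$chains, k = 4, seed = 9)
  expect_identical(rep4$folds, rep4b$folds)
  expect_equal(rep4$protein_metrics$accuracy, rep4b$protein_metrics$accuracy)
  # LOOCV: each fold holds out exactly one chain
  repl <- crossval(ds$chains, k = 12, seed = 9)
  expect_equal(as.integer(table(repl$folds)), rep(1L, 12))
  expect_error(crossval(ds$chains, k = 13, seed = 1), "exceeds")
  expect_error(crossval(ds$chains, k = 1, seed = 1), "at least 2")
  # pooled report is complete
  expect_true(is.finite(rep4$stage1_accuracy))
  expect_true(all(!is.na(rep4$pr_curve$threshold)))
  expect_output(print(rep4), "cross-validation")
})
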