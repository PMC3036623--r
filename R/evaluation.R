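#' Signal coverage of domain boundaries
#'
#' Fraction of boundary points (both flanks of every inter-domain
#' transition, chain termini excluded) that have at least one signal site
#' within `tol` residues (inclusive). Only multi-domain definitions
#' contribute; with no boundary points at all the value is flagged
#' undefined (`NA`).
#'
#' @param sites_by_chain Named list: chain id -> data frame of sites (or
#'   integer vector of positions).
#' @param defs List of [domain_definition] (the truth).
#' @param tol Distance tolerance, residues (default 20).
#' @return List with `coverage` (fraction or `NA`), `n_boundaries`,
#'   `n_covered` and `defined`.
#' @export
signal_coverage <- function(sites_by_chain, defs, tol = 20L) {
  n_b <- 0L; n_c <- 0L
  for (def in defs) {
    bp <- boundary_points(def)
    if (length(bp) == 0L) next
    s <- sites_by_chain[[def$chain_id]]
    pos <- if (is.data.frame(s)) s$position else as.integer(s)
    for (b in bp) {
      n_b <- n_b + 1L
      if (length(pos) && min(abs(pos - b)) <= tol) n_c <- n_c + 1L
    }
  }
  list(coverage = if (n_b > 0L) n_c / n_b else NA_real_,
       n_boundaries = n_b, n_covered = n_c, defined = n_b > 0L)
}

# boundary points eligible for recall: farther than terminal_margin from
# both sequence termini (taken as the outermost defined residues)
eligible_boundaries <- function(def, terminal_margin) {
  bp <- boundary_points(def)
  if (length(bp) == 0L) return(integer(0))
  tmin <- min(def$ranges$start); tmax <- max(def$ranges$end)
  bp[(bp - tmin) > terminal_margin & (tmax - bp) > terminal_margin]
}

#' Site-level precision and recall at one decision threshold
#'
#' A site is called near-boundary when it passed stage 1 and its stage-2
#' score exceeds `threshold`. Precision is the fraction of near-boundary
#' calls lying within `tol` residues of a true boundary point. Recall is
#' boundary-level: the fraction of true boundary points, more than
#' `terminal_margin` residues from both sequence termini, that have at least
#' one near-boundary call within `tol` — several calls near one boundary
#' count once.
#'
#' @param predictions Site predictions with `chain_id`, `position`,
#'   `stage1_score`, `stage2_score` (as from [predict_sites] with an index).
#' @param defs List of [domain_definition] (truth for the evaluated chains).
#' @param threshold Stage-2 decision threshold.
#' @param tol Correctness tolerance, residues (default 20).
#' @param terminal_margin Terminal exclusion margin for recall, residues
#'   (default 40).
#' @return One-row data frame: `threshold`, `precision` (`NA` when no call
#'   is made), `recall` (`NA` when no boundary is eligible), `n_predicted`,
#'   `n_correct`, `n_eligible`, `n_recalled`.
#' @export
site_pr <- function(predictions, defs, threshold, tol = 20L,
                    terminal_margin = 40L) {
  defs_by_id <- setNames(defs, vapply(defs, `[[`, character(1), "chain_id"))
  near <- predictions[!is.na(predictions$stage2_score) &
                        predictions$stage1_score > 0 &
                        predictions$stage2_score > threshold, , drop = FALSE]
  n_pred <- nrow(near); n_corr <- 0L
  if (n_pred > 0L) {
    for (i in seq_len(n_pred)) {
      def <- defs_by_id[[near$chain_id[i]]]
      if (is.null(def)) next
      bp <- boundary_points(def)
      if (length(bp) && min(abs(near$position[i] - bp)) <= tol)
        n_corr <- n_corr + 1L
    }
  }
  n_elig <- 0L; n_rec <- 0L
  for (def in defs) {
    eb <- eligible_boundaries(def, terminal_margin)
    if (length(eb) == 0L) next
    pos <- near$position[near$chain_id == def$chain_id]
    for (b in eb) {
      n_elig <- n_elig + 1L
      if (length(pos) && min(abs(pos - b)) <= tol) n_rec <- n_rec + 1L
    }
  }
  data.frame(threshold = threshold,
             precision = if (n_pred > 0L) n_corr / n_pred else NA_real_,
             recall = if (n_elig > 0L) n_rec / n_elig else NA_real_,
             n_predicted = n_pred, n_correct = n_corr,
             n_eligible = n_elig, n_recalled = n_rec)
}

#' Precision/recall sweep over decision thresholds
#'
#' @inheritParams site_pr
#' @param thresholds Numeric vector of thresholds (default -1.5 to 1.5 in
#'   steps of 0.05).
#' @return Data frame of [site_pr] rows, one per threshold.
#' @export
pr_curve <- function(predictions, defs,
                     thresholds = seq(-1.5, 1.5, by = 0.05),
                     tol = 20L, terminal_margin = 40L) {
  stopifnot(length(thresholds) >= 1L)
  do.call(rbind, lapply(sort(thresholds), function(t)
    site_pr(predictions, defs, t, tol, terminal_margin)))
}

#' Break-even point of a precision/recall sweep
#'
#' The precision (= recall) value where the two curves cross, located at the
#' sign change of precision - recall and refined by linear interpolation
#' between the adjacent thresholds. `NA` when the curves never cross on the
#' grid (rows with undefined precision or recall are ignored).
#'
#' @param curve Data frame from [pr_curve].
#' @return Break-even value, or `NA_real_`.
#' @export
break_even <- function(curve) {
  ok <- !is.na(curve$precision) & !is.na(curve$recall)
  cv <- curve[ok, , drop = FALSE]
  if (nrow(cv) == 0L) return(NA_real_)
  d <- cv$precision - cv$recall
  for (i in seq_len(nrow(cv))) {
    if (d[i] == 0) return(cv$precision[i])
    if (i < nrow(cv) && d[i] * d[i + 1L] < 0) {
      f <- d[i] / (d[i] - d[i + 1L])
      return(cv$precision[i] + f * (cv$precision[i + 1L] - cv$precision[i]))
    }
  }
  NA_real_
}

#' Protein-level classification metrics
#'
#' Overall accuracy plus per-class precision and recall for the
#' single-domain and multi-domain calls. Undefined ratios (empty
#' denominators) are reported as `NA`, never as 0 or 1.
#'
#' @param calls Data frame with `chain_id` and `call`
#'   (`SINGLE_DOMAIN`/`MULTI_DOMAIN`).
#' @param truth Data frame with `chain_id` and `call` (the truth).
#' @return List of `accuracy`, `single_precision`, `single_recall`,
#'   `multi_precision`, `multi_recall` and the confusion counts.
#' @export
protein_metrics <- function(calls, truth) {
  m <- match(calls$chain_id, truth$chain_id)
  if (anyNA(m))
    stop("chain(s) missing from truth: ",
         paste(calls$chain_id[is.na(m)], collapse = ", "))
  pred <- calls$call
  act <- truth$call[m]
  rate <- function(num, den) if (den > 0L) num / den else NA_real_
  tp_m <- sum(pred == "MULTI_DOMAIN" & act == "MULTI_DOMAIN")
  tp_s <- sum(pred == "SINGLE_DOMAIN" & act == "SINGLE_DOMAIN")
  list(accuracy = rate(tp_m + tp_s, length(pred)),
       single_precision = rate(tp_s, sum(pred == "SINGLE_DOMAIN")),
       single_recall = rate(tp_s, sum(act == "SINGLE_DOMAIN")),
       multi_precision = rate(tp_m, sum(pred == "MULTI_DOMAIN")),
       multi_recall = rate(tp_m, sum(act == "MULTI_DOMAIN")),
       n = length(pred), tp_multi = tp_m, tp_single = tp_s)
}

#' Protein-level cross-validation of the full pipeline
#'
#' Splits chains into `k` folds at the protein level (fold sizes differ by
#' at most one; `k = n` gives leave-one-out), trains the two-stage model on
#' each training split and scores the held-out chains. Pooled over folds it
#' reports site-level stage accuracies, signal coverage, the
#' precision/recall sweep with its break-even point, and protein-level
#' single/multi metrics.
#'
#' Stage-2 accuracy is measured on the true multi-domain sites of the
#' held-out folds by scoring them with the fold's stage-2 classifier
#' directly (the gating used for prediction would otherwise hide stage-2
#' errors behind stage-1 ones).
#'
#' @param chains List of chains, each with `query`, `msa`, `ann` and `truth`
#'   (a [domain_definition]) — e.g. [simulate_dataset] output.
#' @param k Number of folds (default 10); must satisfy 2 <= k <= n.
#' @param seed Integer seed for the fold shuffle.
#' @param params [signal_params].
#' @param enc_params [encoding_params].
#' @param config [classifier_config].
#' @param thresholds Threshold grid for the precision/recall sweep.
#' @return An object of class `eval_report`.
#' @export
crossval <- function(chains, k = 10L, seed = 1L,
                     params = signal_params(),
                     enc_params = encoding_params(),
                     config = classifier_config(),
                     thresholds = seq(-1.5, 1.5, by = 0.05)) {
  n <- length(chains)
  if (k > n) stop("k = ", k, " exceeds the number of chains (", n, ")")
  if (k < 2L) stop("k must be at least 2")

  prep <- lapply(chains, function(ch) {
    ext <- extract_signals(ch$msa, params)
    labels <- label_sites(ext$sites, ch$truth, params)
    enc <- if (nrow(ext$sites) > 0L)
      encode_chain_sites(ch$msa, ext$sites, ch$ann, enc_params)
    else NULL
    list(id = ch$query$id, sites = ext$sites, labels = labels, x = enc,
         truth_multi = is_multi_domain(ch$truth), def = ch$truth)
  })

  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k), n))

  preds <- list(); calls <- list()
  s1_ok <- 0L; s1_n <- 0L; s2_ok <- 0L; s2_n <- 0L
  for (f in seq_len(k)) {
    tr <- prep[fold_of != f]
    te <- prep[fold_of == f]
    x_tr <- do.call(rbind, lapply(tr, `[[`, "x"))
    lab_tr <- unlist(lapply(tr, `[[`, "labels"))
    model <- train_two_stage(x_tr, lab_tr, config)
    for (p in te) {
      if (is.null(p$x)) {
        calls[[length(calls) + 1L]] <-
          data.frame(chain_id = p$id, call = "SINGLE_DOMAIN",
                     stringsAsFactors = FALSE)
        next
      }
      idx <- data.frame(chain_id = p$id, position = p$sites$position,
                        stringsAsFactors = FALSE)
      pr <- predict_sites(model, p$x, index = idx)
      # un-gated stage-2 scores for the PR sweep and stage-2 accuracy
      pr$stage2_all <- decision_scores(model$stage2, p$x)
      pr$label <- p$labels
      preds[[length(preds) + 1L]] <- pr
      s1_ok <- s1_ok + sum((pr$stage1_score > 0) == (p$labels != "FALSE_BOUNDARY"))
      s1_n <- s1_n + nrow(pr)
      mm <- p$labels %in% c("NEAR", "AWAY")
      s2_ok <- s2_ok + sum((pr$stage2_all[mm] > 0) == (p$labels[mm] == "NEAR"))
      s2_n <- s2_n + sum(mm)
      calls[[length(calls) + 1L]] <-
        data.frame(chain_id = p$id, call = call_protein(pr, p$id)$call,
                   stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, preds)
  calls <- do.call(rbind, calls)
  truth <- data.frame(
    chain_id = vapply(prep, `[[`, character(1), "id"),
    call = ifelse(vapply(prep, `[[`, logical(1), "truth_multi"),
                  "MULTI_DOMAIN", "SINGLE_DOMAIN"),
    stringsAsFactors = FALSE)

  multi_defs <- lapply(Filter(function(p) p$truth_multi, prep), `[[`, "def")
  multi_ids <- vapply(multi_defs, `[[`, character(1), "chain_id")
  sites_by_chain <- setNames(lapply(prep, `[[`, "sites"),
                             vapply(prep, `[[`, character(1), "id"))
  cov <- signal_coverage(sites_by_chain, multi_defs, params$near_tol)
  mp <- predictions[predictions$chain_id %in% multi_ids, , drop = FALSE]
  curve <- pr_curve(mp, multi_defs, thresholds)

  structure(list(
    coverage = cov,
    pr_curve = curve,
    break_even = break_even(curve),
    protein_metrics = protein_metrics(calls, truth),
    stage1_accuracy = if (s1_n > 0L) s1_ok / s1_n else NA_real_,
    stage2_accuracy = if (s2_n > 0L) s2_ok / s2_n else NA_real_,
    n_sites = s1_n, n_multi_sites = s2_n,
    predictions = predictions, calls = calls, truth = truth,
    folds = fold_of, k = k, seed = seed
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fm <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("boundary-signal cross-validation (", x$k, " folds, ",
      length(x$folds), " chains)\n", sep = "")
  cat("  signal coverage:      ", fm(x$coverage$coverage),
      " (", x$coverage$n_covered, "/", x$coverage$n_boundaries, " boundaries)\n",
      sep = "")
  cat("  stage-1 site accuracy:", fm(x$stage1_accuracy),
      " (", x$n_sites, " sites)\n", sep = "")
  cat("  stage-2 site accuracy:", fm(x$stage2_accuracy),
      " (", x$n_multi_sites, " multi-domain sites)\n", sep = "")
  cat("  protein accuracy:     ", fm(x$protein_metrics$accuracy), "\n", sep = "")
  cat("  PR break-even:        ", fm(x$break_even), "\n", sep = "")
  invisible(x)
}
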