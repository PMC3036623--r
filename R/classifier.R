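#' Classifier configuration
#'
#' Both classification stages use a support vector machine with a radial
#' basis kernel. `gamma` is the RBF width parameter; `cost` the
#' soft-margin regularization constant; `decision_threshold` the cutoff
#' applied to the stage-2 margin score when calling a site near-boundary
#' (raising it trades recall for precision).
#'
#' @param gamma RBF kernel parameter (> 0, default 0.015).
#' @param cost Regularization constant (> 0, default 1).
#' @param decision_threshold Stage-2 decision threshold (default 0).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(gamma = 0.015, cost = 1, decision_threshold = 0) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.numeric(cost) || cost <= 0) stop("cost must be > 0")
  structure(list(gamma = gamma, cost = cost,
                 decision_threshold = decision_threshold),
            class = "classifier_config")
}

#' Train one classification stage
#'
#' Fits a C-classification SVM with an RBF kernel on raw (unscaled)
#' features. Scores returned later are signed margin distances with positive
#' values favouring the positive class. Training is deterministic for fixed
#' inputs and configuration.
#'
#' @param x Feature matrix, one row per site.
#' @param y Logical (or 0/1) vector: `TRUE` for the stage's positive class.
#' @param config [classifier_config].
#' @return An object of class `svm_stage`.
#' @export
train_stage <- function(x, y, config = classifier_config()) {
  y <- as.logical(y)
  if (!any(y)) stop("cannot train: no examples of the positive class")
  if (all(y)) stop("cannot train: no examples of the negative class")
  yy <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(x, yy, type = "C-classification", kernel = "radial",
                    gamma = config$gamma, cost = config$cost, scale = FALSE)
  # libsvm's decision value is positive for whichever class it saw first;
  # record the orientation so scores always favour "pos" when positive.
  dv <- attr(predict(fit, x[1L, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- !startsWith(colnames(dv)[1L], "pos")
  structure(list(fit = fit, flip = flip, n_features = ncol(x)),
            class = "svm_stage")
}

#' Margin scores of a trained stage
#'
#' @param stage An `svm_stage` from [train_stage].
#' @param x Feature matrix.
#' @return Numeric vector of signed margin scores (positive favours the
#'   stage's positive class).
#' @export
decision_scores <- function(stage, x) {
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != stage$n_features)
    stop("feature count ", ncol(x), " != ", stage$n_features, " seen in training")
  dv <- attr(predict(stage$fit, x, decision.values = TRUE), "decision.values")
  s <- as.numeric(dv[, 1L])
  if (stage$flip) -s else s
}

#' Train the two-stage boundary-signal classifier
#'
#' Stage 1 separates signals from single-domain chains (`FALSE_BOUNDARY`)
#' from those of multi-domain chains (`NEAR`/`AWAY`). Stage 2 is trained
#' solely on the multi-domain signals and separates `NEAR` from `AWAY`.
#'
#' @param x Feature matrix, one row per site.
#' @param labels Character vector of site labels (`FALSE_BOUNDARY`, `NEAR`,
#'   `AWAY`).
#' @param config [classifier_config].
#' @param schema_hash Feature-schema hash to embed in the model; defaults to
#'   the `schema_hash` attribute of `x`, else the default-schema hash.
#' @return An object of class `two_stage_model`.
#' @export
train_two_stage <- function(x, labels, config = classifier_config(),
                            schema_hash = NULL) {
  stopifnot(nrow(x) == length(labels))
  bad <- setdiff(unique(labels), c("FALSE_BOUNDARY", "NEAR", "AWAY"))
  if (length(bad)) stop("unknown site label(s): ", paste(bad, collapse = ", "))
  if (is.null(schema_hash))
    schema_hash <- attr(x, "schema_hash") %||% feature_schema_hash()
  stage1 <- train_stage(x, labels != "FALSE_BOUNDARY", config)
  multi <- labels %in% c("NEAR", "AWAY")
  stage2 <- train_stage(x[multi, , drop = FALSE], labels[multi] == "NEAR", config)
  structure(list(stage1 = stage1, stage2 = stage2, config = config,
                 schema_hash = schema_hash, n_features = ncol(x)),
            class = "two_stage_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict signal sites with a two-stage model
#'
#' Every site receives a stage-1 margin score. Stage-2 scores are computed
#' only for stage-1-positive sites (the gating rule); a site is called
#' `FALSE_BOUNDARY` when its stage-1 score is non-positive, `NEAR` when its
#' stage-2 score exceeds the decision threshold, otherwise `AWAY`.
#'
#' @param model A [train_two_stage] model.
#' @param x Feature matrix.
#' @param index Optional data frame (`chain_id`, `position`) parallel to the
#'   rows of `x`; carried through to the output.
#' @param threshold Decision threshold; defaults to the model's configured
#'   value.
#' @return Data frame of site predictions with `stage1_score`,
#'   `stage2_score` (`NA` where gated off) and `call`.
#' @export
predict_sites <- function(model, x, index = NULL, threshold = NULL) {
  stopifnot(inherits(model, "two_stage_model"))
  if (ncol(x) != model$n_features)
    stop("feature count ", ncol(x), " != model's ", model$n_features)
  xh <- attr(x, "schema_hash")
  if (!is.null(xh) && !identical(unname(xh), unname(model$schema_hash)))
    stop("feature schema hash mismatch: model was trained on a different encoding")
  if (is.null(threshold)) threshold <- model$config$decision_threshold
  s1 <- decision_scores(model$stage1, x)
  s2 <- rep(NA_real_, length(s1))
  pos1 <- s1 > 0
  if (any(pos1))
    s2[pos1] <- decision_scores(model$stage2, x[pos1, , drop = FALSE])
  call <- ifelse(!pos1, "FALSE_BOUNDARY",
                 ifelse(s2 > threshold, "NEAR", "AWAY"))
  out <- data.frame(stage1_score = s1, stage2_score = s2, call = call,
                    stringsAsFactors = FALSE)
  if (!is.null(index)) out <- cbind(index, out)
  out
}

#' Protein-level single/multi-domain call
#'
#' A chain is called multi-domain iff at least one of its sites passes
#' stage 1 (positive stage-1 score); chains with no sites, or only
#' `FALSE_BOUNDARY` calls, are single-domain. Predicted boundaries are the
#' positions of `NEAR` calls.
#'
#' @param predictions Site predictions of one chain (possibly zero rows),
#'   as from [predict_sites].
#' @param chain_id Chain identifier.
#' @return List with `chain_id`, `call` (`SINGLE_DOMAIN`/`MULTI_DOMAIN`) and
#'   `predicted_boundaries`.
#' @export
call_protein <- function(predictions, chain_id) {
  multi <- nrow(predictions) > 0L && any(predictions$stage1_score > 0)
  bnd <- if (multi && "position" %in% names(predictions))
    predictions$position[predictions$call == "NEAR"] else integer(0)
  list(chain_id = chain_id,
       call = if (multi) "MULTI_DOMAIN" else "SINGLE_DOMAIN",
       predicted_boundaries = as.integer(bnd))
}

MODEL_FORMAT <- "boundscan_two_stage_model"
MODEL_VERSION <- 1L

#' Save / load a two-stage model
#'
#' The model is stored with a format tag, a version number and the feature
#' schema hash; loading verifies all three, so a truncated file or a model
#' from a different encoding fails loudly instead of corrupting predictions.
#'
#' @param model A `two_stage_model`.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "two_stage_model"))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable model file ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop("file ", path, " is not a boundscan model")
  if (!identical(obj$version, MODEL_VERSION))
    stop("model version ", obj$version, " unsupported (expected ",
         MODEL_VERSION, ")")
  m <- obj$model
  if (!inherits(m, "two_stage_model") || is.null(m$schema_hash))
    stop("model file ", path, " is incomplete")
  m
}
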