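#' Stratified train / validation / test split
#'
#' Partitions the samples into three disjoint, exhaustive subsets (default
#' 60/20/20) with per-class proportions within one sample of the global
#' fractions. Deterministic given the seed.
#'
#' @param m an `ExpressionMatrix`.
#' @param fractions length-3 positive fractions summing to 1
#'   (train, validation, test).
#' @param seed integer seed for the permutation within each class.
#' @return list with `train`, `validation`, `test` (`ExpressionMatrix`) and
#'   `indices` (list of integer column indices into `m`).
#' @export
stratified_split <- function(m, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be three positive numbers summing to 1")
  idx <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_preserved_rng(seed, {
    for (cl in levels(droplevels(m$labels))) {
      cls <- which(m$labels == cl)
      n <- length(cls)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      n_te <- n - n_tr - n_va
      if (min(n_tr, n_va, n_te) < 1)
        stop("class '", cl, "' too small to stratify into three partitions")
      perm <- sample(cls)
      idx$train <- c(idx$train, perm[seq_len(n_tr)])
      idx$validation <- c(idx$validation, perm[n_tr + seq_len(n_va)])
      idx$test <- c(idx$test, perm[n_tr + n_va + seq_len(n_te)])
    }
  })
  idx <- lapply(idx, sort)
  list(train = em_subset(m, samples = idx$train),
       validation = em_subset(m, samples = idx$validation),
       test = em_subset(m, samples = idx$test),
       indices = idx)
}

#' SMOTE oversampling of the minority class
#'
#' Balances the two classes by synthesizing minority samples on the segment
#' between a minority sample and one of its `k` minority-class nearest
#' neighbors (Euclidean distance in the full feature space):
#' `x_new = x + u * (x_nn - x)`, `u ~ U(0, 1)`. Original samples are kept
#' unchanged; synthetic samples are appended with ids `smote_1`, `smote_2`,
#' ... Already-balanced input is returned as is.
#'
#' @param train an `ExpressionMatrix` (the training partition).
#' @param k number of nearest neighbors (default 5, capped at minority size
#'   minus one).
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @return balanced `ExpressionMatrix`.
#' @export
smote_balance <- function(train, k = 5, seed = NULL) {
  stopifnot(inherits(train, "ExpressionMatrix"))
  y <- label01(train)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == n_neg) return(train)
  min_cl <- if (n_pos < n_neg) 1L else 0L
  n_min <- min(n_pos, n_neg)
  if (n_min < 2) stop("minority class has fewer than 2 samples")
  k <- min(k, n_min - 1)
  n_new <- abs(n_pos - n_neg)
  Xm <- t(train$values[, y == min_cl, drop = FALSE])  # minority samples x genes
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  synth <- matrix(0, nrow = n_new, ncol = ncol(Xm))
  gen <- function() {
    for (s in seq_len(n_new)) {
      i <- ((s - 1) %% n_min) + 1
      j <- nn[i, sample.int(k, 1)]
      u <- stats::runif(1)
      synth[s, ] <<- Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
    }
  }
  if (is.null(seed)) gen() else with_preserved_rng(seed, gen())
  rownames(synth) <- paste0("smote_", seq_len(n_new))
  values <- cbind(train$values, t(synth))
  lab_min <- levels(train$labels)[min_cl + 1L]
  labels <- c(as.character(train$labels), rep(lab_min, n_new))
  batch <- if (is.null(train$batch)) NULL else
    c(as.character(train$batch), rep(NA_character_, n_new))
  if (!is.null(batch) && anyNA(batch)) batch <- NULL  # synthetic samples have no batch
  expression_matrix(values, labels, batch = batch, positive = train$positive)
}

#' Default hyperparameters of the four base learners
#'
#' Fixed, logged settings for the fitness oracle's classifiers: gradient
#' boosted trees (xgboost), linear support vector machine (e1071), random
#' forest (ranger) and a CART decision tree (rpart). Sized for training
#' partitions of a few hundred samples; all overridable.
#'
#' @param xgb_nrounds,xgb_depth,xgb_eta boosting rounds, tree depth,
#'   learning rate.
#' @param svm_cost soft-margin cost of the linear SVM.
#' @param rf_trees number of random-forest trees.
#' @param dt_cp CART complexity parameter.
#' @return a named list of settings.
#' @export
base_learner_params <- function(xgb_nrounds = 6, xgb_depth = 2, xgb_eta = 0.6,
                                svm_cost = 1, rf_trees = 20, dt_cp = 0.01) {
  list(xgb_nrounds = xgb_nrounds, xgb_depth = xgb_depth, xgb_eta = xgb_eta,
       svm_cost = svm_cost, rf_trees = rf_trees, dt_cp = dt_cp)
}

.rpart_ctrl <- function(cp) {
  rpart::rpart.control(xval = 0, cp = cp, maxcompete = 0, maxsurrogate = 0,
                       usesurrogate = 0)
}

# Fit the four base learners on X (samples x features), y01 in {0,1}.
fit_base_learners <- function(X, y01, params = base_learner_params(), seed = 0) {
  yf <- factor(y01, levels = c(0, 1))
  y01 <- as.numeric(y01)
  df <- data.frame(.y = yf)
  df$X <- X
  list(
    # single-threaded hist boosting is deterministic; classic DMatrix API
    xgb = xgboost::xgb.train(
      params = xgboost::xgb.params(objective = "binary:logistic",
                                   max_depth = params$xgb_depth,
                                   learning_rate = params$xgb_eta,
                                   nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y01, nthread = 1),
      nrounds = params$xgb_nrounds, verbose = 0),
    svm = e1071::svm(X, yf, kernel = "linear", cost = params$svm_cost,
                     scale = FALSE, tolerance = 0.01),
    rf = ranger::ranger(x = X, y = yf, num.trees = params$rf_trees,
                        num.threads = 1, seed = seed),
    dt = rpart::rpart(.y ~ X, df, method = "class",
                      control = .rpart_ctrl(params$dt_cp))
  )
}

# Hard 0/1 predictions of the four base learners on Xv (samples x features).
predict_base_learners <- function(models, Xv) {
  dfv <- data.frame(row.names = seq_len(nrow(Xv)))
  dfv$X <- Xv
  cbind(
    xgb = as.integer(predict(models$xgb,
                             xgboost::xgb.DMatrix(Xv, nthread = 1)) >= 0.5),
    svm = as.integer(as.character(predict(models$svm, Xv))),
    rf = as.integer(as.character(
      predict(models$rf, Xv, num.threads = 1)$predictions)),
    dt = as.integer(as.character(predict(models$dt, dfv, type = "class")))
  )
}

#' Validation-performance weights of the base classifiers
#'
#' Each classifier's weight is the product of its validation accuracy,
#' precision, recall, F1 and F2, normalized over the four classifiers so the
#' weights sum to 1. When every product is zero the weights fall back to
#' uniform and the result is flagged.
#'
#' @param val_metrics list of four metric vectors from [compute_metrics()].
#' @return numeric weight vector (length 4, sums to 1); attribute
#'   `"uniform_fallback"` is `TRUE` when the fallback was taken.
#' @export
classifier_weights <- function(val_metrics) {
  stopifnot(length(val_metrics) == 4)
  prods <- vapply(val_metrics, function(ms)
    prod(ms[c("Ac", "Pr", "Re", "F1", "F2")]), numeric(1))
  if (sum(prods) == 0) {
    w <- rep(0.25, 4)
    attr(w, "uniform_fallback") <- TRUE
    return(w)
  }
  w <- prods / sum(prods)
  attr(w, "uniform_fallback") <- FALSE
  w
}

#' Weighted hard-voting ensemble prediction
#'
#' Each sample is assigned the class with the largest sum of classifier
#' weights among the hard votes; ties go to the positive (cancer) class by
#' default, a conservative choice for a screening objective.
#'
#' @param pred_mat samples-by-classifiers matrix of 0/1 hard predictions.
#' @param weights classifier weights from [classifier_weights()].
#' @param tie `"positive"` (default) or `"negative"` tie-breaking.
#' @return integer 0/1 vector of ensemble predictions.
#' @export
ensemble_predict <- function(pred_mat, weights, tie = c("positive", "negative")) {
  tie <- match.arg(tie)
  if (ncol(pred_mat) != length(weights))
    stop("number of prediction columns must match number of weights")
  w_pos <- as.vector(pred_mat %*% weights)
  w_neg <- sum(weights) - w_pos
  if (tie == "positive") as.integer(w_pos >= w_neg) else as.integer(w_pos > w_neg)
}

#' Fitness of a feature subset
#'
#' Combines the mean ensemble performance `Avg = (Ac+Pr+Re+F1+F2)/5` with
#' the selected-feature fraction `NF/AF` under weight `phi`. The default
#' `"penalized"` form is minimized:
#' `Fit = phi * (1 - Avg) + (1 - phi) * NF/AF`,
#' so perfect classification with few features drives Fit toward 0. The
#' `"literal"` form `phi * Avg + (1 - phi) * NF/AF` is also available.
#'
#' @param avg_eclf mean of the five ensemble metrics on the validation set.
#' @param nf number of selected features.
#' @param af total number of features.
#' @param phi weight on the performance term, in (0, 1); default 0.8.
#' @param form `"penalized"` (minimize, default) or `"literal"`.
#' @return a `FitnessValue` list: `fit`, `avg_eclf`, `nf`, `af`, `phi`,
#'   `form`, `direction`.
#' @export
fitness_value <- function(avg_eclf, nf, af, phi = 0.8,
                          form = c("penalized", "literal")) {
  form <- match.arg(form)
  stopifnot(phi > 0, phi < 1, nf >= 0, nf <= af)
  fit <- if (form == "penalized")
    phi * (1 - avg_eclf) + (1 - phi) * nf / af
  else
    phi * avg_eclf + (1 - phi) * nf / af
  structure(list(fit = fit, avg_eclf = avg_eclf, nf = nf, af = af, phi = phi,
                 form = form,
                 direction = if (form == "penalized") "minimize" else "maximize"),
            class = "FitnessValue")
}

#' Build a cached fitness evaluator over feature masks
#'
#' Prepares everything the wrapper objective needs once — SMOTE-balances the
#' training partition, lays out train/validation matrices — and returns a
#' closure mapping a 0/1 feature mask to a [fitness_value()]. Results are
#' cached by mask, since the metaheuristics revisit solutions frequently.
#' The empty mask never trains anything and returns the sentinel worst
#' fitness (1 for the minimized form). Classifier fits run under a seed
#' derived from `seed` and the mask so identical calls are identical, and
#' the global RNG stream is left untouched.
#'
#' @param split a [stratified_split()] result; only `train` and `validation`
#'   are touched.
#' @param phi performance weight, see [fitness_value()].
#' @param smote_k SMOTE neighbor count.
#' @param params base-learner settings from [base_learner_params()].
#' @param form fitness form, see [fitness_value()].
#' @param seed integer base seed.
#' @return function `(mask) -> FitnessValue`; attributes on the closure's
#'   environment expose `evals` (count of classifier trainings) and
#'   `sample_ids` (the ids the oracle ever sees).
#' @export
fitness_evaluator <- function(split, phi = 0.8, smote_k = 5,
                              params = base_learner_params(),
                              form = c("penalized", "literal"), seed = 0) {
  form <- match.arg(form)
  train_bal <- smote_balance(split$train, k = smote_k, seed = seed + 1L)
  Xtr <- t(train_bal$values); ytr <- label01(train_bal)
  Xva <- t(split$validation$values); yva <- label01(split$validation)
  af <- nrow(train_bal$values)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  sample_ids <- union(colnames(split$train$values),
                      colnames(split$validation$values))
  worst <- if (form == "penalized") 1 else 0
  f <- function(mask) {
    if (length(mask) != af) stop("mask length != number of features")
    sel <- which(mask == 1)
    nf <- length(sel)
    if (nf == 0) {
      out <- fitness_value(if (form == "penalized") 0 else 0, 0, af, phi, form)
      out$fit <- worst
      out$sentinel <- TRUE
      return(out)
    }
    key <- paste(sel, collapse = ",")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    es <- (seed + 1000003 * (nf %% 1013) + sum(sel * 13L)) %% 2147483646L + 1L
    out <- with_preserved_rng(es, {
      models <- fit_base_learners(Xtr[, sel, drop = FALSE], ytr, params, seed = es)
      preds <- predict_base_learners(models, Xva[, sel, drop = FALSE])
      vm <- lapply(seq_len(4), function(i)
        compute_metrics(confusion_counts(yva, preds[, i])))
      w <- classifier_weights(vm)
      ens <- ensemble_predict(preds, w)
      em <- compute_metrics(confusion_counts(yva, ens))
      avg <- mean(em[c("Ac", "Pr", "Re", "F1", "F2")])
      fv <- fitness_value(avg, nf, af, phi, form)
      fv$weights <- as.numeric(w)
      fv
    })
    evals <<- evals + 1L
    assign(key, out, envir = cache)
    out
  }
  attr(f, "af") <- af
  attr(f, "direction") <- if (form == "penalized") "minimize" else "maximize"
  attr(f, "stats") <- function() list(evals = evals, cached = length(ls(cache)),
                                      sample_ids = sample_ids)
  f
}

#' One-shot fitness of a feature mask
#'
#' Convenience wrapper building a throwaway [fitness_evaluator()] for a
#' single mask.
#'
#' @inheritParams fitness_evaluator
#' @param mask 0/1 feature mask of length `AF`.
#' @return a `FitnessValue`.
#' @export
evaluate_subset_fitness <- function(mask, split, phi = 0.8, smote_k = 5,
                                    params = base_learner_params(),
                                    form = "penalized", seed = 0) {
  fitness_evaluator(split, phi, smote_k, params, form, seed)(mask)
}

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_preserved_rng <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
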