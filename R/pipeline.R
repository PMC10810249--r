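#' Fit one panel classifier and predict labels and scores
#'
#' Shared dispatcher for the held-out evaluation panel and the incremental
#' search: gradient boosted trees (`xgb`), CART (`dt`), random forest
#' (`rf`), support vector machine (`svm`), k-nearest neighbors (`knn`) and
#' a single-hidden-layer neural network (`nn`). Scores are positive-class
#' probabilities (decision proportions for knn).
#'
#' @param name classifier id.
#' @param Xtr,ytr training matrix (samples x features) and 0/1 labels.
#' @param Xte test matrix.
#' @param seed seed for the stochastic learners.
#' @return list with `pred` (0/1) and `score` (numeric).
#' @export
fit_predict_clf <- function(name, Xtr, ytr, Xte, seed = 0) {
  yf <- factor(ytr, levels = c(0, 1))
  if (nrow(Xte) == 0) stop("empty test matrix")
  switch(name,
    xgb = {
      m <- xgboost::xgb.train(
        params = xgboost::xgb.params(objective = "binary:logistic",
                                     max_depth = 3, learning_rate = 0.3,
                                     nthread = 1),
        data = xgboost::xgb.DMatrix(Xtr, label = as.numeric(ytr), nthread = 1),
        nrounds = 60, verbose = 0)
      sc <- predict(m, xgboost::xgb.DMatrix(Xte, nthread = 1))
      list(pred = as.integer(sc >= 0.5), score = sc)
    },
    dt = {
      df <- data.frame(.y = yf); df$X <- Xtr
      m <- rpart::rpart(.y ~ X, df, method = "class", control = .rpart_ctrl(0.01))
      dfv <- data.frame(row.names = seq_len(nrow(Xte))); dfv$X <- Xte
      sc <- predict(m, dfv, type = "prob")[, "1"]
      list(pred = as.integer(sc >= 0.5), score = sc)
    },
    rf = {
      m <- ranger::ranger(x = Xtr, y = yf, num.trees = 300, probability = TRUE,
                          num.threads = 1, seed = seed)
      sc <- predict(m, Xte, num.threads = 1)$predictions[, "1"]
      list(pred = as.integer(sc >= 0.5), score = sc)
    },
    svm = {
      m <- e1071::svm(Xtr, yf, kernel = "radial", probability = TRUE)
      pr <- predict(m, Xte, probability = TRUE)
      sc <- attr(pr, "probabilities")[, "1"]
      list(pred = as.integer(as.character(pr)), score = sc)
    },
    knn = {
      k <- min(5, nrow(Xtr))
      pr <- with_preserved_rng(seed,
        class::knn(Xtr, Xte, yf, k = k, prob = TRUE))
      p_win <- attr(pr, "prob")
      sc <- ifelse(pr == "1", p_win, 1 - p_win)
      list(pred = as.integer(as.character(pr)), score = sc)
    },
    nn = {
      ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, stats::sd); scl[scl == 0] <- 1
      Zt <- scale(Xtr, ctr, scl); Zv <- scale(Xte, ctr, scl)
      m <- with_preserved_rng(seed,
        nnet::nnet(Zt, as.numeric(as.character(yf)), size = 5, decay = 0.1,
                   maxit = 200, trace = FALSE,
                   MaxNWts = (ncol(Zt) + 2) * 5 + 10))
      sc <- as.vector(predict(m, Zv))
      list(pred = as.integer(sc >= 0.5), score = sc)
    },
    stop("unknown classifier: ", name)
  )
}

#' Held-out evaluation of a feature subset with a classifier panel
#'
#' Trains each panel classifier on the union of the (SMOTE-balanced)
#' training and the validation partitions, restricted to the selected
#' genes, and scores the untouched test partition. Reports F1, PR-AUC,
#' ROC-AUC, MCC and balanced accuracy per classifier plus their arithmetic
#' mean.
#'
#' @param mask 0/1 feature mask (must select at least one gene).
#' @param split a [stratified_split()] result.
#' @param panel character vector of classifier ids
#'   (default the six-member panel).
#' @param smote_k SMOTE neighbor count for balancing the training part.
#' @param seed integer seed.
#' @param extra optional named list of additional predictors for
#'   cross-checks; each is a function `(Xtr, ytr, Xte) -> list(pred, score)`.
#' @return an `EvaluationReport` data frame (one row per classifier plus a
#'   `"mean"` row) with columns `F1`, `PR_AUC`, `ROC_AUC`, `MCC`, `BAc`.
#' @export
evaluate_feature_set <- function(mask, split,
                                 panel = c("xgb", "dt", "rf", "svm", "knn", "nn"),
                                 smote_k = 5, seed = 0, extra = NULL) {
  sel <- which(mask == 1)
  if (length(sel) == 0) stop("empty feature mask")
  if (length(panel) == 0) stop("empty classifier panel")
  tr <- smote_balance(split$train, k = smote_k, seed = seed + 1L)
  Xtr <- rbind(t(tr$values[sel, , drop = FALSE]),
               t(split$validation$values[sel, , drop = FALSE]))
  ytr <- c(label01(tr), label01(split$validation))
  Xte <- t(split$test$values[sel, , drop = FALSE])
  yte <- label01(split$test)
  one <- function(nm, fp) {
    ms <- compute_metrics(confusion_counts(yte, fp$pred))
    c(F1 = unname(ms["F1"]), PR_AUC = pr_auc(fp$score, yte),
      ROC_AUC = roc_auc(fp$score, yte), MCC = unname(ms["MCC"]),
      BAc = unname(ms["BAc"]))
  }
  rows <- lapply(panel, function(nm)
    one(nm, with_preserved_rng(seed, fit_predict_clf(nm, Xtr, ytr, Xte, seed))))
  names(rows) <- panel
  if (!is.null(extra)) {
    for (nm in names(extra)) rows[[nm]] <- one(nm, extra[[nm]](Xtr, ytr, Xte))
  }
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, mean = colMeans(tab))
  structure(as.data.frame(tab), class = c("EvaluationReport", "data.frame"))
}

#' Weighted-voting ensemble performance on the held-out test partition
#'
#' Rebuilds the four-learner fitness ensemble for a mask — SMOTE-balanced
#' training fit, validation-derived weights — and measures the weighted
#' hard vote on the untouched test partition.
#'
#' @inheritParams evaluate_feature_set
#' @param params base-learner settings.
#' @param phi kept for the audit trail in the result.
#' @return metric vector from [compute_metrics()] with attribute
#'   `"weights"`.
#' @export
ensemble_test_metrics <- function(mask, split, params = base_learner_params(),
                                  smote_k = 5, seed = 0, phi = 0.8) {
  sel <- which(mask == 1)
  if (length(sel) == 0) stop("empty feature mask")
  tr <- smote_balance(split$train, k = smote_k, seed = seed + 1L)
  Xtr <- t(tr$values[sel, , drop = FALSE]); ytr <- label01(tr)
  Xva <- t(split$validation$values[sel, , drop = FALSE])
  yva <- label01(split$validation)
  Xte <- t(split$test$values[sel, , drop = FALSE]); yte <- label01(split$test)
  with_preserved_rng(seed, {
    models <- fit_base_learners(Xtr, ytr, params, seed = seed)
    vp <- predict_base_learners(models, Xva)
    w <- classifier_weights(lapply(seq_len(4), function(i)
      compute_metrics(confusion_counts(yva, vp[, i]))))
    tp <- predict_base_learners(models, Xte)
    ens <- ensemble_predict(tp, w)
    out <- compute_metrics(confusion_counts(yte, ens))
    attr(out, "weights") <- as.numeric(w)
    out
  })
}

#' Run the hybrid BGWO + simulated annealing selector
#'
#' The binary grey wolf optimizer explores feature masks scored by the
#' SMOTE-balanced weighted-voting ensemble objective; at the end of every
#' iteration the alpha wolf is refined by simulated annealing, and the
#' refined mask replaces alpha when not worse. The best-so-far trace is
#' therefore non-increasing across hand-offs.
#'
#' @param split a [stratified_split()] result.
#' @param gwo_cfg a [gwo_config()] (its seed drives the whole run).
#' @param sa_cfg an [sa_config()]; set to `NULL` to disable the annealing
#'   refinement (the BGWO-only ablation).
#' @param phi performance weight of the fitness, see [fitness_value()].
#' @param params base-learner settings.
#' @param form fitness form, see [fitness_value()].
#' @param evaluate also run the held-out panel evaluation (default TRUE).
#' @return a `SelectionRun` with additional elements `fitness`
#'   (`FitnessValue` of the best mask), `ensemble_test` (test metrics of the
#'   weighted ensemble), `evaluation` (panel `EvaluationReport` or `NULL`)
#'   and `genes` (selected gene ids).
#' @export
bgwo_sa_ens <- function(split, gwo_cfg = gwo_config(), sa_cfg = sa_config(),
                        phi = 0.8, params = base_learner_params(),
                        form = "penalized", evaluate = TRUE) {
  af <- n_features(split$train)
  if (af < 10) stop("need at least 10 features")
  fit_fn <- fitness_evaluator(split, phi = phi, params = params, form = form,
                              seed = gwo_cfg$seed)
  refine <- if (is.null(sa_cfg)) NULL else
    function(mask, f) sa_refine(mask, f, sa_cfg)
  run <- bgwo_run(fit_fn, af, gwo_cfg, refine_alpha = refine)
  run$algorithm <- if (is.null(sa_cfg)) "bgwo_ens" else "bgwo_sa_ens"
  run$fitness <- fit_fn(run$best_mask)
  run$genes <- rownames(split$train$values)[run$best_mask == 1]
  run$oracle <- attr(fit_fn, "stats")()
  run$ensemble_test <- ensemble_test_metrics(run$best_mask, split,
                                             params = params,
                                             seed = gwo_cfg$seed, phi = phi)
  run$evaluation <- if (evaluate)
    evaluate_feature_set(run$best_mask, split, seed = gwo_cfg$seed) else NULL
  run
}

#' Multi-restart wrapper selection
#'
#' Repeats a selector over several seeds (the study protocol uses ten
#' restarts) and reports the run with the best fitness.
#'
#' @param split a [stratified_split()] result.
#' @param seeds integer seeds, one per restart.
#' @param selector function `(split, seed) -> SelectionRun`; default the
#'   hybrid [bgwo_sa_ens()] with default configuration.
#' @param ... passed to the default selector.
#' @return list with `runs` (all `SelectionRun`s), `best` (lowest fitness)
#'   and `table` (Fset-style data frame: seed, NF, fitness, test F1).
#' @export
select_restarts <- function(split, seeds = 1:10, selector = NULL, ...) {
  if (is.null(selector))
    selector <- function(split, seed, ...)
      bgwo_sa_ens(split, gwo_cfg = gwo_config(seed = seed), ...)
  runs <- lapply(seeds, function(s) selector(split, s, ...))
  fits <- vapply(runs, function(r) r$best_fitness, numeric(1))
  tab <- data.frame(
    fset = paste0("Fset", seq_along(seeds)), seed = seeds,
    NF = vapply(runs, function(r) sum(r$best_mask), numeric(1)),
    FV = fits,
    F1 = vapply(runs, function(r) unname(r$ensemble_test["F1"]), numeric(1)))
  list(runs = runs, best = runs[[which.min(fits)]], table = tab)
}

#' Genetic-algorithm baseline selector
#'
#' Generational GA over feature masks minimizing the same ensemble fitness:
#' tournament selection (size 3), uniform crossover (bit-wise probability
#' 0.5), per-bit mutation at rate `1/AF`, with single-individual elitism.
#'
#' @param split a [stratified_split()] result.
#' @param pop_size population size (>= 4).
#' @param generations number of generations.
#' @param mut_rate per-bit mutation probability; default `1/AF`.
#' @param tournament tournament size.
#' @param init_density Bernoulli density of the initial masks.
#' @param phi,params,form objective settings, as in [bgwo_sa_ens()].
#' @param seed integer run seed.
#' @return a `SelectionRun` (algorithm `"ga_ens"`).
#' @export
ga_ens <- function(split, pop_size = 20, generations = 30, mut_rate = NULL,
                   tournament = 3, init_density = 0.5, phi = 0.8,
                   params = base_learner_params(), form = "penalized",
                   seed = 1) {
  if (pop_size < 4) stop("population must be >= 4")
  af <- n_features(split$train)
  if (is.null(mut_rate)) mut_rate <- 1 / af
  fit_fn <- fitness_evaluator(split, phi = phi, params = params, form = form,
                              seed = seed)
  n_eval <- 0L
  evalf <- function(m) { n_eval <<- n_eval + 1L; fit_fn(m)$fit }
  out <- with_preserved_rng(seed, {
    pop <- lapply(seq_len(pop_size), function(i)
      as.integer(stats::runif(af) < init_density))
    fits <- vapply(pop, evalf, numeric(1))
    best_i <- which.min(fits)
    best <- pop[[best_i]]; best_fit <- fits[best_i]
    trace <- best_fit
    for (gen in seq_len(generations)) {
      pick <- function() {
        cand <- sample.int(pop_size, tournament)
        cand[which.min(fits[cand])]
      }
      children <- vector("list", pop_size)
      children[[1]] <- best  # elitism
      for (i in 2:pop_size) {
        p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
        take1 <- stats::runif(af) < 0.5
        child <- ifelse(take1, p1, p2)
        flip <- stats::runif(af) < mut_rate
        child[flip] <- 1L - child[flip]
        children[[i]] <- as.integer(child)
      }
      pop <- children
      fits <- vapply(pop, evalf, numeric(1))
      if (min(fits) < best_fit) {
        best_fit <- min(fits); best <- pop[[which.min(fits)]]
      }
      trace <- c(trace, best_fit)
    }
    list(best_mask = best, best_fitness = best_fit, trace = trace)
  })
  structure(c(out, list(algorithm = "ga_ens", seed = seed,
                        config = list(pop_size = pop_size,
                                      generations = generations,
                                      mut_rate = mut_rate,
                                      tournament = tournament),
                        n_evaluations = n_eval,
                        fitness = fit_fn(out$best_mask),
                        genes = rownames(split$train$values)[out$best_mask == 1])),
            class = "SelectionRun")
}

#' Monte Carlo feature scoring
#'
#' Repeatedly draws a uniform random feature subset from the training
#' partition, measures the subset's cross-validated random-forest F1, and
#' credits each member feature with the subset F1 weighted by the forest's
#' impurity importance within the subset. A feature's score is the
#' importance-weighted mean F1 over the subsets containing it. Features
#' never drawn score `NA` and rank last (flagged via the `"undrawn"`
#' attribute).
#'
#' @param train an `ExpressionMatrix` (training data only).
#' @param n_iter number of random subsets (default 100).
#' @param subset_size features per subset (default 5000, capped at AF).
#' @param k_folds cross-validation folds (default 10).
#' @param num_trees forest size per fold.
#' @param seed integer seed.
#' @return data frame `gene`, `score`, `times_drawn`, ordered by
#'   decreasing score.
#' @export
mcfs_scores <- function(train, n_iter = 100, subset_size = 5000, k_folds = 10,
                        num_trees = 100, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  af <- n_features(train)
  subset_size <- min(subset_size, af)
  X <- t(train$values); y <- label01(train)
  num <- rep(0, af); den <- rep(0, af); drawn <- rep(0L, af)
  with_preserved_rng(seed, {
    for (it in seq_len(n_iter)) {
      sel <- sample.int(af, subset_size)
      Xs <- X[, sel, drop = FALSE]
      f1 <- cv_f1_rf(Xs, y, k_folds, num_trees, seed + it)
      m <- ranger::ranger(x = Xs, y = factor(y, levels = c(0, 1)),
                          num.trees = num_trees, importance = "impurity",
                          num.threads = 1, seed = seed + it)
      imp <- pmax(m$variable.importance, 0)
      if (sum(imp) > 0) imp <- imp / sum(imp) else imp <- rep(1 / length(sel), length(sel))
      num[sel] <- num[sel] + f1 * imp
      den[sel] <- den[sel] + imp
      drawn[sel] <- drawn[sel] + 1L
    }
  })
  score <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(gene = rownames(train$values), score = score,
                    times_drawn = drawn)
  out <- out[order(-ifelse(is.na(out$score), -Inf, out$score)), ]
  rownames(out) <- NULL
  attr(out, "undrawn") <- sum(drawn == 0)
  out
}

# k-fold cross-validated F1 of a random forest on X/y
cv_f1_rf <- function(X, y, k_folds, num_trees, seed) {
  n <- nrow(X)
  k_folds <- min(k_folds, n)
  folds <- with_preserved_rng(seed, sample(rep_len(seq_len(k_folds), n)))
  preds <- integer(n)
  for (f in seq_len(k_folds)) {
    te <- folds == f
    if (length(unique(y[!te])) < 2) { preds[te] <- 0L; next }
    m <- ranger::ranger(x = X[!te, , drop = FALSE],
                        y = factor(y[!te], levels = c(0, 1)),
                        num.trees = num_trees, num.threads = 1, seed = seed + f)
    preds[te] <- as.integer(as.character(
      predict(m, X[te, , drop = FALSE], num.threads = 1)$predictions))
  }
  unname(compute_metrics(confusion_counts(y, preds))["F1"])
}

#' Incremental feature selection over a ranking
#'
#' Evaluates growing prefixes of a ranked feature list (sizes `step`,
#' `2*step`, ...) by cross-validated mean F1 over a classifier panel on the
#' training partition, and returns the prefix with the highest mean F1
#' (ties to the smaller prefix).
#'
#' @param ranking character vector of gene ids, best first.
#' @param train an `ExpressionMatrix` containing those genes.
#' @param step prefix increment (default 5).
#' @param panel classifier ids evaluated at each prefix
#'   (default `dt`, `knn`, `rf`, `svm`, `nn`).
#' @param k_folds cross-validation folds (default 10).
#' @param max_features optional cap on the largest prefix.
#' @param seed integer seed.
#' @return list with `best_genes`, `best_size`, `best_f1` and `table`
#'   (prefix size versus per-classifier and mean F1).
#' @export
ifs_search <- function(ranking, train, step = 5,
                       panel = c("dt", "knn", "rf", "svm", "nn"),
                       k_folds = 10, max_features = NULL, seed = 1) {
  if (length(ranking) == 0) stop("empty ranking")
  if (length(panel) == 0) stop("empty classifier panel")
  limit <- min(length(ranking), max_features %||% length(ranking))
  sizes <- unique(c(seq(min(step, limit), limit, by = step),
                    if (limit %% step != 0 || limit < step) limit))
  X <- t(train$values); y <- label01(train)
  n <- nrow(X)
  k_folds <- min(k_folds, n)
  folds <- with_preserved_rng(seed, sample(rep_len(seq_len(k_folds), n)))
  rows <- lapply(sizes, function(sz) {
    sel <- match(ranking[seq_len(sz)], rownames(train$values))
    if (anyNA(sel)) stop("ranking contains unknown genes")
    f1s <- vapply(panel, function(nm) {
      preds <- integer(n)
      for (f in seq_len(k_folds)) {
        te <- folds == f
        if (length(unique(y[!te])) < 2) { preds[te] <- 0L; next }
        fp <- fit_predict_clf(nm, X[!te, sel, drop = FALSE], y[!te],
                              X[te, sel, drop = FALSE], seed = seed + f)
        preds[te] <- fp$pred
      }
      unname(compute_metrics(confusion_counts(y, preds))["F1"])
    }, numeric(1))
    c(size = sz, f1s, mean_F1 = mean(f1s))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  best_row <- which.max(tab$mean_F1)  # which.max takes the first maximum: ties -> smaller prefix
  list(best_genes = ranking[seq_len(tab$size[best_row])],
       best_size = tab$size[best_row],
       best_f1 = tab$mean_F1[best_row],
       table = tab)
}

#' LASSO feature selection baseline
#'
#' Cross-validated L1-regularized logistic regression (glmnet); genes with
#' non-zero coefficients at `lambda.1se` are selected.
#'
#' @param train an `ExpressionMatrix`.
#' @param seed integer seed for the fold assignment.
#' @return character vector of selected gene ids.
#' @export
lasso_select <- function(train, seed = 1) {
  X <- t(train$values); y <- label01(train)
  cv <- with_preserved_rng(seed,
    glmnet::cv.glmnet(X, y, family = "binomial", nfolds = 5))
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
  names(co)[co != 0]
}

#' Intersection of DEG and selected gene sets ("superior genes")
#'
#' @param deg_sets list of >= 1 character vectors (DEGs per dataset).
#' @param selected_sets list of >= 1 character vectors (selected genes per
#'   dataset).
#' @return a `SuperiorGeneReport` list: `intersection` (sorted gene ids),
#'   `set_sizes`, `n_sets`. An empty intersection is a valid result.
#' @export
superior_genes <- function(deg_sets, selected_sets) {
  if (!is.list(deg_sets)) deg_sets <- list(deg_sets)
  if (!is.list(selected_sets)) selected_sets <- list(selected_sets)
  if (length(deg_sets) < 1 || length(selected_sets) < 1)
    stop("need at least one DEG set and one selected set; all non-empty")
  sets <- c(deg_sets, selected_sets)
  if (any(lengths(sets) == 0))
    stop("all input gene sets must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  inter <- sort(Reduce(intersect, sets))
  structure(list(intersection = inter,
                 set_sizes = lengths(sets),
                 n_sets = length(sets)),
            class = "SuperiorGeneReport")
}

#' Hypergeometric enrichment of a selected set in a planted truth set
#'
#' Upper-tail probability of drawing at least the observed overlap when
#' selecting `|selected|` genes uniformly from the universe.
#'
#' @param selected character vector of selected gene ids.
#' @param truth character vector of planted informative gene ids.
#' @param universe character vector (or size) of the gene universe.
#' @return list with `overlap`, `p_value`.
#' @export
planted_enrichment <- function(selected, truth, universe) {
  N <- if (is.numeric(universe)) universe else length(unique(universe))
  K <- length(unique(truth))
  n <- length(unique(selected))
  k <- length(intersect(selected, truth))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, p_value = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
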