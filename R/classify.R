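#' Residualize features against covariates and site
#'
#' Fits the covariate-only mixed model (`y ~ 1 + age + sex + iq + (1|site)`)
#' to every feature and returns `y` minus the fixed-effect prediction and the
#' site random-intercept prediction (its empirical BLUP), leaving the part of
#' each feature unexplained by age, sex, IQ and site.
#'
#' @param features subjects x features numeric matrix.
#' @param meta covariate data.frame.
#' @return list of class `residual_features`: `matrix` (same shape as
#'   `features`), `fits` invisibly omitted for size.
#' @export
residualize <- function(features, meta) {
  features <- as.matrix(features)
  tab <- prepare_feature_table(cbind(meta, y = 0))
  out <- matrix(0, nrow(features), ncol(features))
  for (k in seq_len(ncol(features))) {
    tab$y <- features[, k]
    if (stats::sd(tab$y) == 0) { out[, k] <- 0; next }
    f <- fit_lme(tab, 1, "ML")
    x <- lme_design(tab, 1)
    r <- tab$y - drop(x %*% f$beta)
    tau <- f$sigma_site2 / f$sigma2
    for (s in levels(tab$site)) {
      idx <- tab$site == s
      ns <- sum(idx)
      r[idx] <- r[idx] - (ns * tau / (1 + ns * tau)) * mean(r[idx])
    }
    out[, k] <- r
  }
  structure(list(matrix = out), class = "residual_features")
}

#' PCA reduction retaining a variance fraction
#'
#' Singular value decomposition of the column-centered residual matrix; the
#' smallest number of leading components whose cumulative explained variance
#' reaches `var_frac` is kept.
#'
#' @param resid a [residualize()] result or plain matrix.
#' @param var_frac variance fraction to retain (default 0.98).
#' @return list of class `pca_scores`: `scores` (subjects x k), `loadings`
#'   (features x k), `center`, `var_explained` (per component), `k`.
#' @export
pca_reduce <- function(resid, var_frac = 0.98) {
  x <- if (inherits(resid, "residual_features")) resid$matrix else as.matrix(resid)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = min(dim(xc)), nv = 0)
  ve <- sv$d^2 / sum(sv$d^2)
  ve <- ve[sv$d > max(sv$d) * 1e-12]
  k <- which(cumsum(ve) >= var_frac - 1e-12)[1]
  if (is.na(k)) k <- length(ve)
  # loadings via V = X' U / d
  v <- crossprod(xc, sv$u[, seq_len(k), drop = FALSE])
  v <- sweep(v, 2, sv$d[seq_len(k)], "/")
  structure(list(scores = sv$u[, seq_len(k), drop = FALSE] %*%
                   diag(sv$d[seq_len(k)], k),
                 loadings = v, center = ctr, var_explained = ve, k = k),
            class = "pca_scores")
}

#' S1 score: harmonic mean of sensitivity and specificity
#'
#' Used as the tuning and reporting metric because it penalizes trivial
#' single-class predictions in unbalanced samples.
#'
#' @param sens,spec rates in [0, 1].
#' @return harmonic mean, 0 when both rates are 0.
#' @export
s1_score <- function(sens, spec) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  ifelse(sens + spec > 0, 2 * sens * spec / (sens + spec), 0)
}

#' Default hyperparameter grids for the three classifiers
#'
#' Standard log-spaced ranges: linear SVC cost 10^-3..10^2; elastic net
#' inverse regularization 10^-3..10^2 crossed with l1 ratios 0.1/0.5/0.9;
#' RBF SVC cost 10^-1..10^2 with kernel width set by the median heuristic
#' scaled by 0.5/1/2.
#'
#' @return named list of data.frame grids.
#' @export
default_grids <- function() {
  list(linsvc = data.frame(C = 10^seq(-3, 2)),
       enet = expand.grid(C = 10^seq(-3, 2), l1 = c(0.1, 0.5, 0.9)),
       boruta_rbf = expand.grid(C = 10^seq(-1, 2), gamma_mult = c(0.5, 1, 2)))
}

# internal: median-heuristic RBF bandwidth gamma = 1 / (2 * median dist^2)
median_gamma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  d2 <- stats::dist(x[idx, , drop = FALSE])^2
  m <- stats::median(d2)
  if (m <= 0) m <- mean(d2) + 1e-12
  1 / (2 * m)
}

#' Boruta-style feature selection with shadow features
#'
#' Random-forest importance of every feature is compared, over repeated
#' iterations, with the maximal importance of column-shuffled "shadow"
#' copies; features whose hit count is binomially significantly above chance
#' are confirmed. A compact re-implementation of the Boruta algorithm.
#'
#' @param x subjects x features matrix.
#' @param y 0/1 labels.
#' @param n_iter iterations (default 50).
#' @param n_trees trees per forest (default 100).
#' @param alpha confirmation level (default 0.05).
#' @param seed integer seed.
#' @return integer vector of selected feature indices (never empty: falls
#'   back to the overall importance ranking when nothing is confirmed).
#' @export
boruta_select <- function(x, y, n_iter = 50, n_trees = 100, alpha = 0.05,
                          seed = 1) {
  set.seed(seed)
  p <- ncol(x)
  hits <- numeric(p)
  imp_acc <- numeric(p)
  df_y <- factor(y)
  for (it in seq_len(n_iter)) {
    shadow <- apply(x, 2, sample)
    dat <- data.frame(cbind(x, shadow))
    names(dat) <- c(paste0("f", seq_len(p)), paste0("s", seq_len(p)))
    dat$.y <- df_y
    rf <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                         num.trees = n_trees, importance = "impurity",
                         num.threads = 1, verbose = FALSE,
                         seed = seed + it)
    imp <- rf$variable.importance
    real <- imp[seq_len(p)]
    sh_max <- max(imp[p + seq_len(p)])
    hits <- hits + (real > sh_max)
    imp_acc <- imp_acc + real
  }
  thr <- stats::qbinom(1 - alpha, n_iter, 0.5)
  sel <- which(hits > thr)
  if (!length(sel)) sel <- order(-imp_acc)[seq_len(min(5, p))]
  sel
}

# internal: fit one classifier, return a prediction closure over new scores
train_classifier <- function(x, y, model_id, hyper) {
  yf <- factor(y, levels = c(0, 1))
  if (model_id == "linsvc") {
    fit <- e1071::svm(x, yf, kernel = "linear", cost = hyper$C, scale = FALSE)
    function(newx) as.integer(as.character(stats::predict(fit, newx)))
  } else if (model_id == "enet") {
    lam <- 1 / (hyper$C * length(y))
    fit <- glmnet::glmnet(x, yf, family = "binomial", alpha = hyper$l1,
                          lambda = lam, standardize = FALSE)
    function(newx) as.integer(stats::predict(fit, newx, type = "class"))
  } else if (model_id == "boruta_rbf") {
    # draw the selection seed from the live stream so repeated splits do not
    # share RNG state after the constant reseed inside boruta_select
    sel <- boruta_select(x, y, seed = sample.int(1e8, 1))
    g <- median_gamma(x[, sel, drop = FALSE]) * hyper$gamma_mult
    fit <- e1071::svm(x[, sel, drop = FALSE], yf, kernel = "radial",
                      cost = hyper$C, gamma = g, scale = FALSE)
    function(newx) as.integer(as.character(
      stats::predict(fit, newx[, sel, drop = FALSE])))
  } else stop("unknown model_id")
}

# internal: stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# internal: binary classification metrics; sensitivity = recall of class 1
class_metrics <- function(truth, pred) {
  sens <- if (any(truth == 1)) mean(pred[truth == 1] == 1) else NA_real_
  spec <- if (any(truth == 0)) mean(pred[truth == 0] == 0) else NA_real_
  c(acc = mean(pred == truth), sens = sens, spec = spec,
    s1 = s1_score(sens, spec))
}

#' Repeated-split evaluation of a classifier
#'
#' Stratified random splits with a held-out test fraction; within each
#' training part, hyperparameters are tuned by grid search with stratified
#' inner cross-validation maximizing the S1 score, the winning model is refit
#' on the whole training part, and test metrics are recorded. Aggregated
#' rates are unweighted means across splits.
#'
#' @param scores subjects x components matrix (e.g. [pca_reduce()] scores).
#' @param labels 0/1 (or ASD/NT) group labels.
#' @param model_id one of "linsvc", "enet", "boruta_rbf".
#' @param n_splits number of random splits (default 15).
#' @param test_frac held-out fraction (default 0.2).
#' @param grid hyperparameter data.frame (default from [default_grids()]).
#' @param inner_folds inner CV folds (default 10; tuning is skipped for
#'   single-row grids).
#' @param seed integer seed.
#' @return list of class `classifier_report`: `per_split` data.frame,
#'   `aggregated` named vector (acc/sens/spec/s1), `model_id`.
#' @export
evaluate_models <- function(scores, labels, model_id = "linsvc",
                            n_splits = 15, test_frac = 0.2, grid = NULL,
                            inner_folds = 10, seed = 1) {
  scores <- as.matrix(scores)
  y <- if (is.numeric(labels)) as.integer(labels)
       else as.integer(labels == "ASD")
  stopifnot(length(y) == nrow(scores), all(y %in% 0:1))
  if (is.null(grid)) grid <- default_grids()[[model_id]]
  set.seed(seed)
  per_split <- matrix(NA_real_, n_splits, 4,
                      dimnames = list(NULL, c("acc", "sens", "spec", "s1")))
  for (sp in seq_len(n_splits)) {
    test <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(test_frac * length(idx))))
    }))
    train <- setdiff(seq_along(y), test)
    if (length(unique(y[test])) < 2 || length(unique(y[train])) < 2)
      stop("stratification violated: a class is absent from a split")
    hy <- grid[1, , drop = FALSE]
    if (nrow(grid) > 1) {
      fold <- stratified_folds(y[train], inner_folds)
      cv_s1 <- vapply(seq_len(nrow(grid)), function(gi) {
        s1s <- vapply(seq_len(inner_folds), function(fd) {
          tr <- train[fold != fd]; va <- train[fold == fd]
          if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2)
            return(NA_real_)
          pred <- train_classifier(scores[tr, , drop = FALSE], y[tr],
                                   model_id, grid[gi, , drop = FALSE])(
            scores[va, , drop = FALSE])
          class_metrics(y[va], pred)[["s1"]]
        }, numeric(1))
        mean(s1s, na.rm = TRUE)
      }, numeric(1))
      hy <- grid[which.max(cv_s1), , drop = FALSE]
    }
    pred <- train_classifier(scores[train, , drop = FALSE], y[train],
                             model_id, hy)(scores[test, , drop = FALSE])
    per_split[sp, ] <- class_metrics(y[test], pred)
  }
  structure(list(per_split = as.data.frame(per_split),
                 aggregated = colMeans(per_split), model_id = model_id),
            class = "classifier_report")
}

#' Label-permutation significance of classification performance
#'
#' Re-runs the repeated-split evaluation on datasets with randomized group
#' labels and reports the proportion of null aggregated S1 scores at least as
#' large as the observed one.
#'
#' @param scores,labels,model_id,n_splits,test_frac,grid,inner_folds as in
#'   [evaluate_models()].
#' @param n_perm number of label randomizations (default 1000).
#' @param seed integer seed.
#' @return list: `p`, `observed_s1`, `null_s1` (vector), `report` (the
#'   observed [evaluate_models()] result).
#' @export
permutation_significance <- function(scores, labels, model_id = "linsvc",
                                     n_perm = 1000, n_splits = 15,
                                     test_frac = 0.2, grid = NULL,
                                     inner_folds = 10, seed = 1) {
  y <- if (is.numeric(labels)) as.integer(labels)
       else as.integer(labels == "ASD")
  rep_obs <- evaluate_models(scores, y, model_id, n_splits, test_frac, grid,
                             inner_folds, seed = substream_seed(seed, 0L))
  obs <- rep_obs$aggregated[["s1"]]
  null_s1 <- vapply(seq_len(n_perm), function(b) {
    set.seed(substream_seed(seed, b))
    yb <- sample(y)
    evaluate_models(scores, yb, model_id, n_splits, test_frac, grid,
                    inner_folds,
                    seed = substream_seed(seed, b))$aggregated[["s1"]]
  }, numeric(1))
  list(p = mean(null_s1 >= obs), observed_s1 = obs, null_s1 = null_s1,
       report = rep_obs)
}

#' Residualize, reduce and evaluate in one call
#'
#' The default "replicate" mode residualizes and applies PCA on the full
#' sample before the repeated splits (matching the original analysis
#' pipeline); "strict" mode refits the covariate models and the PCA inside
#' every split on training data only and projects the held-out subjects
#' through them, avoiding any leakage of test data into the preprocessing.
#'
#' @param features subjects x features matrix.
#' @param meta covariate data.frame (group, age, sex, iq, site).
#' @param model_id classifier id.
#' @param mode "replicate" (default) or "strict".
#' @param var_frac PCA variance fraction (default 0.98).
#' @param ... passed to [evaluate_models()].
#' @return a `classifier_report` with a `mode` element.
#' @export
classify_features <- function(features, meta, model_id = "linsvc",
                              mode = c("replicate", "strict"),
                              var_frac = 0.98, ...) {
  mode <- match.arg(mode)
  y <- as.integer(meta$group == "ASD")
  if (mode == "replicate") {
    pc <- pca_reduce(residualize(features, meta), var_frac)
    rep_ <- evaluate_models(pc$scores, y, model_id, ...)
    rep_$mode <- mode
    return(rep_)
  }
  # strict: residualization + PCA refit per split
  args <- list(...)
  n_splits <- args$n_splits %||% 15
  test_frac <- args$test_frac %||% 0.2
  grid <- args$grid %||% default_grids()[[model_id]]
  inner_folds <- args$inner_folds %||% 10
  seed <- args$seed %||% 1
  set.seed(seed)
  tab0 <- prepare_feature_table(cbind(meta, y = 0))
  per_split <- matrix(NA_real_, n_splits, 4,
                      dimnames = list(NULL, c("acc", "sens", "spec", "s1")))
  for (sp in seq_len(n_splits)) {
    test <- unlist(lapply(0:1, function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(test_frac * length(idx))))
    }))
    train <- setdiff(seq_along(y), test)
    res_tr <- matrix(0, length(train), ncol(features))
    res_te <- matrix(0, length(test), ncol(features))
    tab_tr <- prepare_feature_table(cbind(meta[train, ], y = 0))
    x_tr <- lme_design(tab_tr, 1)
    # test design on the training standardization
    age_te <- (meta$age[test] - mean(meta$age[train])) / stats::sd(meta$age[train])
    iq_te <- (meta$iq[test] - mean(meta$iq[train])) / stats::sd(meta$iq[train])
    x_te <- cbind(1, age_te, as.numeric(meta$sex[test] != "M"), iq_te)
    for (k in seq_len(ncol(features))) {
      tab_tr$y <- features[train, k]
      if (stats::sd(tab_tr$y) == 0) next
      f <- fit_lme(tab_tr, 1, "ML")
      r_tr <- tab_tr$y - drop(x_tr %*% f$beta)
      tau <- f$sigma_site2 / f$sigma2
      blup <- stats::setNames(numeric(nlevels(tab_tr$site)), levels(tab_tr$site))
      for (s in levels(tab_tr$site)) {
        idx <- tab_tr$site == s
        blup[s] <- (sum(idx) * tau / (1 + sum(idx) * tau)) * mean(r_tr[idx])
        r_tr[idx] <- r_tr[idx] - blup[s]
      }
      res_tr[, k] <- r_tr
      b_te <- ifelse(as.character(meta$site[test]) %in% names(blup),
                     blup[as.character(meta$site[test])], 0)
      res_te[, k] <- features[test, k] - drop(x_te %*% f$beta) - b_te
    }
    pc <- pca_reduce(res_tr, var_frac)
    sc_tr <- pc$scores
    sc_te <- sweep(res_te, 2, pc$center) %*% pc$loadings
    hy <- grid[1, , drop = FALSE]
    if (nrow(grid) > 1) {
      fold <- stratified_folds(y[train], inner_folds)
      cv_s1 <- vapply(seq_len(nrow(grid)), function(gi) {
        s1s <- vapply(seq_len(inner_folds), function(fd) {
          tr <- which(fold != fd); va <- which(fold == fd)
          if (length(unique(y[train][va])) < 2) return(NA_real_)
          pred <- train_classifier(sc_tr[tr, , drop = FALSE], y[train][tr],
                                   model_id, grid[gi, , drop = FALSE])(
            sc_tr[va, , drop = FALSE])
          class_metrics(y[train][va], pred)[["s1"]]
        }, numeric(1))
        mean(s1s, na.rm = TRUE)
      }, numeric(1))
      hy <- grid[which.max(cv_s1), , drop = FALSE]
    }
    pred <- train_classifier(sc_tr, y[train], model_id, hy)(sc_te)
    per_split[sp, ] <- class_metrics(y[test], pred)
  }
  structure(list(per_split = as.data.frame(per_split),
                 aggregated = colMeans(per_split), model_id = model_id,
                 mode = mode),
            class = "classifier_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
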