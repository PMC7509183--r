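algorithm_order <- c("DTR", "SVR", "AdaboostR", "RFR")

#' Split specification
#'
#' Per-patient train/validation/test partition, default 6:2:2.  Chronological
#' mode keeps row order (beats are a time series; random splitting would leak
#' neighbouring-beat correlation into the test set); random mode applies a
#' seeded shuffle before the same cut.
#'
#' @param train,val,test positive ratios summing to 1.
#' @param mode `"chronological"` or `"random"`.
#' @param seed shuffle seed for random mode.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train = 0.6, val = 0.2, test = 0.2,
                       mode = c("chronological", "random"), seed = 0L) {
  mode <- match.arg(mode)
  if (train <= 0 || val <= 0 || test <= 0)
    stop_pulsebp("split ratios must be positive")
  if (abs(train + val + test - 1) > 1e-9)
    stop_pulsebp("split ratios must sum to 1")
  structure(list(train = train, val = val, test = test, mode = mode,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Partition one patient's beats
#'
#' @param rows per-beat feature data frame.
#' @param spec a [split_spec()].
#' @return list of data frames `train`, `val`, `test` (exact disjoint
#'   partition of the input rows).
#' @export
split_patient <- function(rows, spec = split_spec()) {
  n <- nrow(rows)
  if (n < 10) stop_pulsebp("need at least 10 beats to split")
  ord <- seq_len(n)
  if (spec$mode == "random")
    ord <- with_seed(spec$seed, sample.int(n))
  n_tr <- floor(spec$train * n)
  n_val <- floor(spec$val * n)
  list(train = rows[ord[seq_len(n_tr)], , drop = FALSE],
       val = rows[ord[n_tr + seq_len(n_val)], , drop = FALSE],
       test = rows[ord[(n_tr + n_val + 1):n], , drop = FALSE])
}

# --- AdaBoost.R2 (Drucker 1997, linear loss), depth-3 regression-tree base
# learners and weighted-median prediction.
fit_adaboost_r2 <- function(x, y, n_estimators = 50L, max_depth = 3L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  dat <- data.frame(x, .y = y, check.names = FALSE)
  models <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tr <- rpart::rpart(.y ~ ., data = dat[idx, , drop = FALSE],
                       control = rpart::rpart.control(
                         maxdepth = max_depth, cp = 0, minsplit = 2,
                         minbucket = 1, xval = 0))
    pred <- unname(stats::predict(tr, dat))
    err <- abs(pred - y)
    D <- max(err)
    if (D <= .Machine$double.eps) {
      models[[length(models) + 1]] <- tr
      alphas <- c(alphas, log(1 / 1e-10))
      break
    }
    loss <- err / D
    ebar <- sum(w * loss)
    if (ebar >= 0.5) {
      if (!length(models)) { models <- list(tr); alphas <- 1 }
      break
    }
    beta <- ebar / (1 - ebar)
    models[[length(models) + 1]] <- tr
    alphas <- c(alphas, log(1 / max(beta, 1e-12)))
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  list(models = models, alphas = alphas)
}

predict_adaboost_r2 <- function(fit, newdata) {
  preds <- vapply(fit$models, function(m) unname(stats::predict(m, newdata)),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  a <- fit$alphas
  apply(preds, 1, function(p) {
    o <- order(p)
    cw <- cumsum(a[o])
    p[o][which(cw >= 0.5 * sum(a))[1]]
  })
}

#' Train one per-patient regression model
#'
#' Fits one of the four regressors to a patient's training beats:
#' \describe{
#'   \item{DTR}{regression tree grown to full depth (interpolates the
#'     training data).}
#'   \item{SVR}{RBF-kernel support vector regression; the penalty `C` in
#'     \{0.1, 1, 10, 100\} and kernel width `gamma` in
#'     \{0.001, 0.01, 0.1, 1\} are chosen by exhaustive grid search
#'     minimising validation RMSE; features are standardised with training
#'     statistics only.}
#'   \item{AdaboostR}{AdaBoost.R2 with 50 depth-3 tree base learners,
#'     linear loss and weighted-median prediction.}
#'   \item{RFR}{random forest with 50 trees; the per-feature impurity
#'     importances are retained as the weight scores `omega`.}
#' }
#' Separate models are trained per target (SBP or DBP).
#'
#' @param algorithm one of `"DTR"`, `"SVR"`, `"AdaboostR"`, `"RFR"`.
#' @param train,val training and validation feature data frames.
#' @param target `"sbp"` or `"dbp"`.
#' @param seed RNG seed for the stochastic fits.
#' @param features feature column names (default the canonical 15).
#' @param patient_id identifier stored on the model.
#' @return a `bp_model` object with fields `algorithm`, `target`, `fit`,
#'   `features`, `val_rmse`, `hyperparameters` and (RFR only) `importance`.
#' @export
train_model <- function(algorithm = algorithm_order, train, val,
                        target = c("sbp", "dbp"), seed = 0L,
                        features = feature_names(), patient_id = "anon") {
  algorithm <- match.arg(algorithm)
  target <- match.arg(target)
  ycol <- paste0("ref_", target)
  y <- train[[ycol]]
  if (is.null(y) || stats::sd(y) == 0)
    stop_pulsebp("degenerate target: zero variance in ", ycol)
  x <- train[, features, drop = FALSE]
  xv <- val[, features, drop = FALSE]
  yv <- val[[ycol]]
  fit <- with_seed(seed, switch(
    algorithm,
    DTR = rpart::rpart(stats::reformulate(features, ycol),
                       data = train,
                       control = rpart::rpart.control(
                         cp = 0, minsplit = 2, minbucket = 1,
                         maxdepth = 30, xval = 0)),
    SVR = {
      grid <- expand.grid(C = c(0.1, 1, 10, 100),
                          gamma = c(0.001, 0.01, 0.1, 1))
      best <- NULL; best_rmse <- Inf; best_par <- list()
      for (g in seq_len(nrow(grid))) {
        m <- e1071::svm(x, y, kernel = "radial", cost = grid$C[g],
                        gamma = grid$gamma[g], scale = TRUE)
        rmse <- sqrt(mean((stats::predict(m, xv) - yv)^2))
        if (rmse < best_rmse) {
          best <- m; best_rmse <- rmse
          best_par <- list(C = grid$C[g], gamma = grid$gamma[g])
        }
      }
      list(model = best, hyper = best_par)
    },
    AdaboostR = fit_adaboost_r2(x, y),
    RFR = randomForest::randomForest(x, y, ntree = 50)))
  hyper <- list()
  if (algorithm == "SVR") {
    hyper <- fit$hyper
    fit <- fit$model
  }
  model <- structure(list(algorithm = algorithm, target = target,
                          patient_id = patient_id, fit = fit,
                          features = features, hyperparameters = hyper),
                     class = "bp_model")
  if (algorithm == "RFR") {
    omega <- fit$importance[, "IncNodePurity"]
    names(omega) <- rownames(fit$importance)
    model$importance <- omega
  }
  model$val_rmse <- sqrt(mean((stats::predict(model, val) - yv)^2))
  model
}

#' Predict blood pressure for new beats
#'
#' @param object a `bp_model`.
#' @param newdata feature data frame.
#' @param ... unused.
#' @return numeric vector of estimates in mmHg.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  x <- newdata[, object$features, drop = FALSE]
  switch(object$algorithm,
         DTR = unname(stats::predict(object$fit, newdata)),
         SVR = unname(stats::predict(object$fit, x)),
         AdaboostR = predict_adaboost_r2(object$fit, x),
         RFR = unname(stats::predict(object$fit, x)))
}

#' Select the best algorithm from a validation-RMSE matrix
#'
#' Picks the algorithm with the lowest mean validation RMSE across patients;
#' exact ties break by the fixed order DTR, SVR, AdaboostR, RFR.
#'
#' @param val_rmse numeric matrix, patients x algorithms, with algorithm
#'   column names.
#' @return the selected algorithm name.
#' @export
select_best_algorithm <- function(val_rmse) {
  val_rmse <- as.matrix(val_rmse)
  if (nrow(val_rmse) < 1) stop_pulsebp("need at least one patient")
  if (any(is.na(val_rmse))) stop_pulsebp("NaN entries in RMSE matrix")
  algs <- intersect(algorithm_order, colnames(val_rmse))
  if (!length(algs)) stop_pulsebp("no recognised algorithm columns")
  means <- colMeans(val_rmse[, algs, drop = FALSE])
  algs[which.min(means)]  # which.min takes the first minimum: fixed order
}

#' Paired comparison of two algorithms
#'
#' Two-sided paired Student's t-test on the per-patient validation RMSEs of
#' two algorithms.
#'
#' @param val_rmse patients x algorithms RMSE matrix.
#' @param alg_a,alg_b algorithm column names.
#' @return the p-value.
#' @export
compare_algorithms <- function(val_rmse, alg_a, alg_b) {
  val_rmse <- as.matrix(val_rmse)
  if (nrow(val_rmse) < 2) stop_pulsebp("need at least two patients")
  d <- val_rmse[, alg_a] - val_rmse[, alg_b]
  if (stats::sd(d) == 0) stop_pulsebp("degenerate paired test")
  stats::t.test(val_rmse[, alg_a], val_rmse[, alg_b], paired = TRUE)$p.value
}

#' Aggregate random-forest feature importances across patients
#'
#' Each patient's raw importance weights `omega_ij` are normalised to
#' relative importances `FI_ij = omega_ij / sum_j omega_ij` (summing to 1
#' per patient), and the group importance of each feature is the mean of
#' `FI_ij` over patients.  The output table is sorted by descending group
#' importance.
#'
#' @param models list of RFR `bp_model`s for the same target and feature set.
#' @return list with `FI` (patients x features matrix), `group` (named
#'   vector, descending) and `table` (data frame `feature`, `importance`).
#' @export
group_importance <- function(models) {
  if (!length(models)) stop_pulsebp("no models supplied")
  if (any(vapply(models, function(m) m$algorithm, character(1)) != "RFR"))
    stop_pulsebp("group importance requires RFR models")
  targets <- unique(vapply(models, function(m) m$target, character(1)))
  if (length(targets) != 1)
    stop_pulsebp("models must share a single target")
  omega <- do.call(rbind, lapply(models, function(m)
    m$importance[models[[1]]$features]))
  tot <- rowSums(omega)
  if (any(tot == 0)) stop_pulsebp("patient with all-zero importance weights")
  fi <- omega / tot
  group <- colMeans(fi)
  ord <- order(group, decreasing = TRUE)
  list(FI = fi, group = group[ord],
       table = data.frame(feature = names(group)[ord],
                          importance = unname(group[ord]),
                          stringsAsFactors = FALSE))
}
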