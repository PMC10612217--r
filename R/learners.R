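#' Tuning settings for the six base learners
#'
#' Defaults follow the study design this workflow implements: a
#' 100-point auto-scaled lambda grid with 10-fold misclassification CV
#' for the lasso; a linear-kernel SVM with cost tuned over 1..20 by
#' 10-fold CV; a random forest choosing the tree count in 1..700 at the
#' minimum out-of-bag error; CART with complexity parameter 0.001;
#' gradient boosting with 200 trees, learning rate 0.001, 90% row
#' subsampling, Bernoulli (logistic) loss and six submodels; and a
#' neural network with three hidden layers and a sum-of-squared-error
#' objective.
#'
#' @param lasso_nlambda length of the lasso lambda grid.
#' @param svm_cost candidate SVM cost values.
#' @param rf_max_trees largest candidate tree count for the forest.
#' @param dt_cp CART complexity parameter.
#' @param gbm_trees,gbm_learning_rate,gbm_sample_rate,gbm_folds,gbm_max_depth
#'   boosting settings (trees, shrinkage, row subsample rate, number of
#'   submodel folds, tree depth).
#' @param nn_hidden hidden-layer sizes (three layers by default).
#' @param nn_maxit BFGS iteration cap for the network.
#' @param nn_decay L2 penalty on network weights (numerical
#'   regularisation; the objective remains SSE-dominated).
#' @param nn_importance per-gene weight extraction for the network:
#'   `"garson"` (products of absolute inter-layer weight matrices,
#'   normalised to sum 1) or `"first_layer"` (sum of absolute
#'   first-layer weights).
#' @param cv_folds folds for cross-validated accuracy.
#' @return list of class `iml_control`.
#' @export
iml_control <- function(lasso_nlambda = 100L, svm_cost = 1:20,
                        rf_max_trees = 700L, dt_cp = 0.001,
                        gbm_trees = 200L, gbm_learning_rate = 0.001,
                        gbm_sample_rate = 0.9, gbm_folds = 6L,
                        gbm_max_depth = 5L,
                        nn_hidden = c(16L, 8L, 4L), nn_maxit = 500L,
                        nn_decay = 1e-4,
                        nn_importance = c("garson", "first_layer"),
                        cv_folds = 10L) {
  stopifnot(lasso_nlambda >= 2, length(svm_cost) >= 1, rf_max_trees >= 1,
            dt_cp > 0, gbm_trees >= 1, gbm_learning_rate > 0,
            gbm_sample_rate > 0, gbm_sample_rate <= 1, gbm_folds >= 2,
            length(nn_hidden) >= 1, nn_maxit >= 1, cv_folds >= 2)
  structure(list(lasso_nlambda = lasso_nlambda, svm_cost = svm_cost,
                 rf_max_trees = rf_max_trees, dt_cp = dt_cp,
                 gbm_trees = gbm_trees, gbm_learning_rate = gbm_learning_rate,
                 gbm_sample_rate = gbm_sample_rate, gbm_folds = gbm_folds,
                 gbm_max_depth = gbm_max_depth, nn_hidden = nn_hidden,
                 nn_maxit = nn_maxit, nn_decay = nn_decay,
                 nn_importance = match.arg(nn_importance),
                 cv_folds = cv_folds),
            class = "iml_control")
}

## stratified fold ids, seeded
.make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.as_class_factor <- function(y) {
  y <- factor(y, levels = c("control", "case"))
  if (any(is.na(y))) stop("class labels must be 'control' or 'case'")
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  y
}

.new_learner <- function(name, object, genes, tuned, raw_weights,
                         refit, predict_prob, extra = list()) {
  structure(c(list(name = name, object = object, genes = genes,
                   tuned = tuned,
                   raw_weights = stats::setNames(raw_weights, genes),
                   refit = refit, predict_prob = predict_prob), extra),
            class = "iml_learner")
}

#' @export
print.iml_learner <- function(x, ...) {
  cat("Base learner '", x$name, "' on ", length(x$genes), " genes\n", sep = "")
  if (length(x$tuned))
    cat("  tuned:", paste(names(x$tuned), unlist(x$tuned), sep = "=",
                          collapse = ", "), "\n")
  top <- sort(abs(x$raw_weights), decreasing = TRUE)
  cat("  top |weight| genes:", paste(names(head(top, 3)), collapse = ", "), "\n")
  invisible(x)
}

## ---- lasso ----------------------------------------------------------------
.fit_lasso <- function(X, y, seed, control) {
  ## keep >= 3 observations per CV fold on small inputs
  k <- max(3L, min(control$cv_folds, floor(length(y) / 3)))
  foldid <- .make_folds(y, k, seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", type.measure = "class",
                          foldid = foldid, nlambda = control$lasso_nlambda)
  w <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
  lam <- cv$lambda.min
  .new_learner("lasso", cv, colnames(X), list(lambda = signif(lam, 4)), w,
    refit = function(X, y, seed) {
      glmnet::glmnet(X, y, family = "binomial", lambda = lam)
    },
    predict_prob = function(object, X) {
      as.numeric(predict(object, newx = X, s = lam, type = "response"))
    },
    extra = list(cv_error = min(cv$cvm)))
}

## ---- linear SVM -----------------------------------------------------------
.fit_svm <- function(X, y, seed, control) {
  set.seed(seed)
  tn <- e1071::tune.svm(x = X, y = y, kernel = "linear",
                        cost = control$svm_cost,
                        tunecontrol = e1071::tune.control(
                          cross = min(control$cv_folds, floor(length(y) / 2))))
  fit <- tn$best.model
  w <- drop(t(fit$coefs) %*% fit$SV)           # primal weights, scaled space
  w <- w[colnames(X)]
  w[is.na(w)] <- 0
  cost <- tn$best.parameters$cost
  ## e1071 orders decision values by the first label it encounters; use the
  ## stored sign so that larger decision values always mean 'case'
  dv_sign <- function(object) {
    if (identical(object$levels[1], "case")) 1 else -1
  }
  svm_prob <- function(object, X) {
    dv <- drop(attr(predict(object, X, decision.values = TRUE),
                    "decision.values"))
    1 / (1 + exp(-dv_sign(object) * dv))
  }
  .new_learner("svm", fit, colnames(X), list(cost = cost), w,
    refit = function(X, y, seed) {
      e1071::svm(x = X, y = y, kernel = "linear", cost = cost)
    },
    predict_prob = svm_prob,
    extra = list(cv_error = tn$best.performance))
}

## ---- random forest --------------------------------------------------------
.fit_rf <- function(X, y, seed, control) {
  set.seed(seed)
  probe <- randomForest::randomForest(X, y, ntree = control$rf_max_trees)
  ntree <- unname(which.min(probe$err.rate[, "OOB"]))
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = ntree)
  w <- fit$importance[, "MeanDecreaseGini"]
  .new_learner("rf", fit, colnames(X), list(ntree = ntree), w[colnames(X)],
    refit = function(X, y, seed) {
      set.seed(seed)
      randomForest::randomForest(X, y, ntree = ntree)
    },
    predict_prob = function(object, X) {
      predict(object, X, type = "prob")[, "case"]
    },
    extra = list(oob_error = min(probe$err.rate[, "OOB"])))
}

## ---- CART decision tree ---------------------------------------------------
.fit_dt <- function(X, y, seed, control) {
  san <- make.names(colnames(X), unique = TRUE)
  df <- data.frame(X)
  names(df) <- san
  df$.y <- y
  set.seed(seed)                      # cross-validation inside rpart
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      cp = control$dt_cp)
  w <- stats::setNames(numeric(ncol(X)), san)
  vi <- fit$variable.importance
  if (!is.null(vi)) w[names(vi)] <- vi
  names(w) <- colnames(X)
  .new_learner("dt", fit, colnames(X), list(cp = control$dt_cp), w,
    refit = function(X, y, seed) {
      df <- data.frame(X); names(df) <- san; df$.y <- y
      set.seed(seed)
      rpart::rpart(.y ~ ., data = df, method = "class", cp = control$dt_cp)
    },
    predict_prob = function(object, X) {
      df <- data.frame(X); names(df) <- san
      predict(object, df, type = "prob")[, "case"]
    },
    extra = list(sanitized_names = san))
}

## ---- gradient boosting ----------------------------------------------------
.xgb_params <- function(control, seed) {
  list(objective = "binary:logistic", eta = control$gbm_learning_rate,
       subsample = control$gbm_sample_rate, max_depth = control$gbm_max_depth,
       nthread = 1L, seed = seed)
}

.xgb_gain <- function(bst, genes) {
  w <- stats::setNames(numeric(length(genes)), genes)
  imp <- tryCatch(xgboost::xgb.importance(model = bst), error = function(e) NULL)
  if (!is.null(imp) && nrow(imp)) w[imp$Feature] <- imp$Gain * 100
  w
}

.fit_gbm <- function(X, y, seed, control) {
  ynum <- as.numeric(y == "case")
  dall <- xgboost::xgb.DMatrix(X, label = ynum)
  full <- xgboost::xgb.train(params = .xgb_params(control, seed), data = dall,
                             nrounds = control$gbm_trees, verbose = 0)
  ## per-fold submodels: each trained without one stratified fold,
  ## relative influence (gain, %) averaged over the submodels
  folds <- .make_folds(y, control$gbm_folds, seed)
  wmat <- vapply(seq_len(control$gbm_folds), function(f) {
    keep <- folds != f
    dtr <- xgboost::xgb.DMatrix(X[keep, , drop = FALSE], label = ynum[keep])
    bst <- xgboost::xgb.train(params = .xgb_params(control, seed + f),
                              data = dtr, nrounds = control$gbm_trees,
                              verbose = 0)
    .xgb_gain(bst, colnames(X))
  }, numeric(ncol(X)))
  w <- rowMeans(wmat)
  .new_learner("gbm", full, colnames(X),
               list(ntree = control$gbm_trees, eta = control$gbm_learning_rate,
                    subsample = control$gbm_sample_rate), w,
    refit = function(X, y, seed) {
      d <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "case"))
      xgboost::xgb.train(params = .xgb_params(control, seed), data = d,
                         nrounds = control$gbm_trees, verbose = 0)
    },
    predict_prob = function(object, X) {
      predict(object, xgboost::xgb.DMatrix(X))
    })
}

## ---- three-hidden-layer neural network ------------------------------------
## Fully connected sigmoid network trained by BFGS on a sum-of-squared-error
## objective (plus a small L2 term for conditioning).  Written in-package:
## the architecture (three hidden layers) is part of the workflow contract
## and the per-gene importance must be extracted from the weight matrices.
.nn_shapes <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L),
         function(i) c(sizes[i], sizes[i + 1L]))
}

.nn_unpack <- function(theta, shapes) {
  out <- vector("list", length(shapes))
  pos <- 0L
  for (i in seq_along(shapes)) {
    nw <- prod(shapes[[i]])
    out[[i]] <- list(W = matrix(theta[pos + seq_len(nw)], shapes[[i]][1]),
                     b = theta[pos + nw + seq_len(shapes[[i]][2])])
    pos <- pos + nw + shapes[[i]][2]
  }
  out
}

.nn_forward <- function(layers, X) {
  a <- X
  acts <- list()
  for (i in seq_along(layers)) {
    z <- sweep(a %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    a <- 1 / (1 + exp(-z))
    acts[[i]] <- a
  }
  acts
}

.fit_nn <- function(X, y, seed, control) {
  p <- ncol(X)
  xm <- colMeans(X)
  xs <- apply(X, 2, sd)
  xs[xs == 0] <- 1
  Xs <- scale(X, xm, xs)
  tgt <- as.numeric(y == "case")
  shapes <- .nn_shapes(p, control$nn_hidden)
  n_par <- sum(vapply(shapes, function(s) prod(s) + s[2], numeric(1)))
  set.seed(seed)
  theta0 <- runif(n_par, -0.5, 0.5)
  decay <- control$nn_decay

  loss <- function(theta) {
    layers <- .nn_unpack(theta, shapes)
    out <- .nn_forward(layers, Xs)[[length(shapes)]]
    0.5 * sum((out - tgt)^2) + 0.5 * decay * sum(theta^2)
  }
  grad <- function(theta) {
    layers <- .nn_unpack(theta, shapes)
    acts <- .nn_forward(layers, Xs)
    L <- length(shapes)
    out <- acts[[L]]
    delta <- (out - tgt) * out * (1 - out)
    g <- numeric(length(theta))
    pos_end <- length(theta)
    for (i in L:1) {
      a_prev <- if (i == 1L) Xs else acts[[i - 1L]]
      gW <- crossprod(a_prev, delta)
      gb <- colSums(delta)
      nw <- prod(shapes[[i]]); nb <- shapes[[i]][2]
      g[(pos_end - nw - nb + 1L):pos_end] <- c(as.numeric(gW), gb)
      pos_end <- pos_end - nw - nb
      if (i > 1L)
        delta <- (delta %*% t(layers[[i]]$W)) * acts[[i - 1L]] *
          (1 - acts[[i - 1L]])
    }
    g + decay * theta
  }
  opt <- stats::optim(theta0, loss, grad, method = "BFGS",
                      control = list(maxit = control$nn_maxit, reltol = 1e-10))
  layers <- .nn_unpack(opt$par, shapes)

  w <- if (control$nn_importance == "garson") {
    imp <- abs(layers[[1]]$W)
    for (i in 2:length(layers)) imp <- imp %*% abs(layers[[i]]$W)
    imp <- drop(imp)
    if (sum(imp) > 0) imp / sum(imp) else imp
  } else {
    rowSums(abs(layers[[1]]$W))
  }

  model <- list(layers = layers, xm = xm, xs = xs, shapes = shapes,
                value = opt$value)
  .new_learner("nn", model, colnames(X),
               list(hidden = paste(control$nn_hidden, collapse = "-")), w,
    refit = function(X, y, seed) {
      .fit_nn(X, y, seed, control)$object
    },
    predict_prob = function(object, X) {
      Xs <- scale(X, object$xm, object$xs)
      drop(.nn_forward(object$layers, Xs)[[length(object$layers)]])
    })
}

.learner_registry <- list(lasso = .fit_lasso, svm = .fit_svm, rf = .fit_rf,
                          dt = .fit_dt, gbm = .fit_gbm, nn = .fit_nn)

#' Tune and fit one base learner
#'
#' Fits one of the six base classifiers on an expression matrix
#' restricted to a candidate gene set, applying its tuning rule (see
#' [iml_control()]), and extracts a per-gene raw weight vector: lasso
#' coefficients, the SVM primal vector, random-forest impurity-decrease
#' importance, CART variable importance (zero for unused genes), mean
#' gradient-boosting relative influence across submodels, or
#' Garson-style network importance.
#'
#' @param model one of `"lasso"`, `"svm"`, `"rf"`, `"dt"`, `"gbm"`,
#'   `"nn"`.
#' @param matrix genes x samples expression matrix (e.g. restricted to
#'   the selected DEGs).
#' @param labels sample annotation with `class`, or a factor of class
#'   labels aligned with the columns.
#' @param seed integer seed driving every stochastic component.
#' @param control an [iml_control()].
#' @return an `iml_learner` object: model spec, tuned values, named
#'   `raw_weights`, and prediction hooks used by [evaluate_accuracy()]
#'   and [cv_accuracy()].
#' @export
tune_and_fit <- function(model, matrix, labels, seed = 1L,
                         control = iml_control()) {
  model <- match.arg(model, names(.learner_registry))
  y <- if (is.data.frame(labels)) {
    labels <- .validate_labels(matrix, labels)
    .as_class_factor(labels$class)
  } else .as_class_factor(labels)
  X <- t(matrix)
  if (is.null(colnames(X))) stop("matrix must carry gene ids as rownames")
  fit <- .learner_registry[[model]](X, y, seed, control)
  fit$seed <- seed
  fit$train_accuracy <- evaluate_accuracy(fit, matrix, y)
  fit
}

#' Classification accuracy of a fitted base learner
#'
#' Fraction of correctly predicted labels at the model's default
#' decision rule (probability 0.5 for probabilistic models).
#'
#' @param fit an `iml_learner` from [tune_and_fit()].
#' @param matrix genes x samples matrix over the same gene set the
#'   model was fitted on.
#' @param labels class labels (factor or annotation data.frame).
#' @return accuracy in \[0, 1\].
#' @export
evaluate_accuracy <- function(fit, matrix, labels) {
  y <- if (is.data.frame(labels)) {
    labels <- .validate_labels(matrix, labels)
    .as_class_factor(labels$class)
  } else .as_class_factor(labels)
  if (!setequal(rownames(matrix), fit$genes))
    stop("gene set of the matrix does not match the fitted model")
  X <- t(matrix[fit$genes, , drop = FALSE])
  prob <- fit$predict_prob(fit$object, X)
  pred <- ifelse(prob > 0.5, "case", "control")
  mean(pred == as.character(y))
}

#' Cross-validated accuracy of a base learner
#'
#' Stratified k-fold cross-validation: the learner is refitted on each
#' training fold with the hyperparameters tuned on the full data and
#' scored on the held-out fold.
#'
#' @inheritParams evaluate_accuracy
#' @param folds number of folds.
#' @param seed fold-assignment and refit seed.
#' @return mean held-out accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(fit, matrix, labels, folds = 10L, seed = 1L) {
  y <- if (is.data.frame(labels)) {
    labels <- .validate_labels(matrix, labels)
    .as_class_factor(labels$class)
  } else .as_class_factor(labels)
  X <- t(matrix[fit$genes, , drop = FALSE])
  k <- min(folds, min(table(y)))
  id <- .make_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr <- id != f
    obj <- fit$refit(X[tr, , drop = FALSE], y[tr], seed + f)
    prob <- fit$predict_prob(obj, X[!tr, , drop = FALSE])
    mean(ifelse(prob > 0.5, "case", "control") == as.character(y[!tr]))
  }, numeric(1))
  mean(acc)
}
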