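#' Imbalance-aware model training and selection
#'
#' Repeated (or group) 5-fold cross-validation with minority subsampling on
#' training folds only, a lambda grid for penalized logistic regression, a
#' 32-point grid for boosted trees, one-standard-error model selection, and
#' a bootstrap-weighted stacked ensemble.
#'
#' @name feature_ml
NULL

#' Stratified 75/25 train/test split
#'
#' @param y Label vector (`"functional"` / `"nonfunctional"`).
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_holdout <- function(y, train_frac = 0.75, seed = 1L) {
  restore <- .local_seed(seed)
  on.exit(restore())
  train <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_tr <- round(train_frac * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Cross-validation fold plan
#'
#' `repeated_kfold`: n repeats of stratified k-fold splits (every row is in
#' validation exactly once per repeat). `group_kfold`: groups (e.g. the 13
#' TAD sets) are partitioned into k folds of near-equal group counts,
#' repeated n times, so no group ever spans train and validation.
#'
#' @param y Label vector.
#' @param mode `"repeated_kfold"` or `"group_kfold"`.
#' @param groups Group ids (required for group mode).
#' @param k Folds (default 5).
#' @param repeats Repeats (default 10; k x repeats = 50 splits).
#' @param seed Integer seed.
#' @return List of splits, each with `train` and `validation` index vectors.
#' @export
make_folds <- function(y, mode = c("repeated_kfold", "group_kfold"),
                       groups = NULL, k = 5L, repeats = 10L, seed = 1L) {
  mode <- match.arg(mode)
  restore <- .local_seed(seed)
  on.exit(restore())
  n <- length(y)
  splits <- list()
  if (mode == "repeated_kfold") {
    for (r in seq_len(repeats)) {
      fold_of <- integer(n)
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
      for (f in seq_len(k)) {
        splits[[length(splits) + 1L]] <- list(
          train = which(fold_of != f), validation = which(fold_of == f)
        )
      }
    }
  } else {
    if (is.null(groups)) stop("group mode requires group ids", call. = FALSE)
    gids <- unique(groups)
    if (length(gids) < k) stop("fewer groups than folds", call. = FALSE)
    for (r in seq_len(repeats)) {
      shuffled <- sample(gids)
      fold_of_g <- rep_len(seq_len(k), length(gids))[order(order(shuffled))]
      names(fold_of_g) <- shuffled
      for (f in seq_len(k)) {
        val_groups <- names(fold_of_g)[fold_of_g == f]
        splits[[length(splits) + 1L]] <- list(
          train = which(!groups %in% val_groups),
          validation = which(groups %in% val_groups)
        )
      }
    }
  }
  splits
}

#' Downsample the majority class on training rows
#'
#' @param y Labels of the training rows.
#' @param origin Optional origin stratum (library of origin); when given,
#'   classes are equalized within each stratum.
#' @param seed Integer seed.
#' @return Integer vector of retained training-row positions.
#' @export
subsample_minority <- function(y, origin = NULL, seed = 1L) {
  restore <- .local_seed(seed)
  on.exit(restore())
  strata <- if (is.null(origin)) rep("all", length(y)) else origin
  keep <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    tab <- table(y[idx])
    if (length(tab) < 2L) stop("a class is empty in stratum ", s, call. = FALSE)
    n_min <- min(tab)
    for (cls in names(tab)) {
      cls_idx <- idx[y[idx] == cls]
      keep <- c(keep, if (length(cls_idx) > n_min) sample(cls_idx, n_min) else cls_idx)
    }
  }
  sort(keep)
}

#' Hyper-parameter grids
#'
#' Penalized: 50 evenly spaced lambda values on [1e-5, 0.1] (log spacing
#' optional), for L1 (lasso) and L2 (ridge). Boosted: the 32-point product
#' of eta {0.1, 0.3} x max_depth {2, 4} x subsample {0.5, 0.75} x
#' nrounds {30, 100} x min_child_weight {0.5, 1}, with colsample 0.8 and
#' gamma 0 fixed.
#'
#' @param spacing `"linear"` or `"log"` lambda spacing.
#' @return List with `lambda` (50 values, decreasing) and `boosted`
#'   (32-row data.frame).
#' @export
hyper_grid <- function(spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  lambda <- switch(spacing,
    linear = seq(1e-5, 0.1, length.out = 50),
    log = exp(seq(log(1e-5), log(0.1), length.out = 50))
  )
  boosted <- expand.grid(
    eta = c(0.1, 0.3), max_depth = c(2L, 4L), subsample = c(0.5, 0.75),
    nrounds = c(30L, 100L), min_child_weight = c(0.5, 1),
    colsample_bytree = 0.8, gamma = 0
  )
  list(lambda = sort(lambda, decreasing = TRUE), boosted = boosted)
}

.y01 <- function(y) as.numeric(y == "functional")

#' Train a single classifier
#'
#' @param x Preprocessed numeric matrix.
#' @param y Labels.
#' @param kind `"logit_single"`, `"logit_multi"`, `"penalized_L1"`,
#'   `"penalized_L2"`, or `"boosted"`.
#' @param lambda Lambda path for penalized kinds (model fitted on the full
#'   path; predictions taken at a chosen lambda).
#' @param params One row of the boosted grid for `kind = "boosted"`.
#' @param seed Seed forwarded to the boosted learner's internal row/column
#'   sampling (ignored by deterministic kinds).
#' @return A `screen_model` with `predict_prob(newx, s)` giving
#'   P(functional).
#' @export
train_model <- function(x, y, kind = c("logit_multi", "logit_single",
                                       "penalized_L1", "penalized_L2",
                                       "boosted"),
                        lambda = hyper_grid()$lambda, params = NULL,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (any(!is.finite(x))) stop("non-finite features", call. = FALSE)
  y01 <- .y01(y)
  obj <- switch(kind,
    logit_single = ,
    logit_multi = {
      df <- data.frame(y = y01, x)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      list(fit = fit,
           predict_prob = function(newx, s = NULL) {
             unname(predict(fit, newdata = data.frame(newx), type = "response"))
           },
           coefs = coef(fit)[-1])
    },
    penalized_L1 = ,
    penalized_L2 = {
      alpha <- if (kind == "penalized_L1") 1 else 0
      fit <- glmnet::glmnet(x, y01, family = "binomial", alpha = alpha,
                            lambda = lambda, standardize = FALSE)
      list(fit = fit,
           predict_prob = function(newx, s = min(lambda)) {
             as.numeric(predict(fit, newx = newx, s = s, type = "response",
                                exact = FALSE))
           },
           coefs_at = function(s) {
             cf <- as.matrix(predict(fit, s = s, type = "coefficients"))
             setNames(cf[-1, 1], rownames(cf)[-1])
           })
    },
    boosted = {
      if (is.null(params)) params <- hyper_grid()$boosted[1, ]
      dtrain <- xgboost::xgb.DMatrix(x, label = y01)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth, subsample = params$subsample,
                      min_child_weight = params$min_child_weight,
                      colsample_bytree = params$colsample_bytree,
                      gamma = params$gamma, nthread = 1,
                      seed = as.integer(seed)),
        data = dtrain, nrounds = params$nrounds, verbose = 0
      )
      list(fit = fit,
           predict_prob = function(newx, s = NULL) {
             predict(fit, xgboost::xgb.DMatrix(newx))
           },
           feature_names = colnames(x))
    }
  )
  structure(c(obj, list(kind = kind)), class = "screen_model")
}

#' Precision-recall and ROC AUC for probability scores
#'
#' The PR curve is swept over descending unique scores with step-wise
#' (achievable-precision) interpolation: AUC = sum over steps of
#' (recall gain) x precision at that step. ROC AUC uses the rank
#' (Mann-Whitney) formulation, which handles ties exactly. The PR baseline
#' of a random classifier is the positive-class prevalence.
#'
#' @param probs Scores in [0, 1].
#' @param labels `"functional"` / `"nonfunctional"`.
#' @return List with `pr_auc`, `roc_auc`, `baseline` (prevalence).
#' @export
evaluate_scores <- function(probs, labels) {
  y <- .y01(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined metric: single-class labels", call. = FALSE)
  }
  ord <- order(probs, decreasing = TRUE)
  ys <- y[ord]; ps <- probs[ord]
  # collapse tied scores into single thresholds
  grp <- cumsum(!duplicated(ps))
  tp_g <- tapply(ys, grp, sum)
  n_g <- tapply(ys, grp, length)
  tp <- cumsum(tp_g); np <- cumsum(n_g)
  recall <- tp / n_pos
  precision <- tp / np
  pr_auc <- sum(diff(c(0, recall)) * precision)
  r <- rank(probs)
  roc_auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(pr_auc = unname(pr_auc), roc_auc = unname(roc_auc),
       baseline = n_pos / (n_pos + n_neg))
}

#' One-standard-error model selection
#'
#' Among grid points whose mean cross-validated score is within one
#' standard error of the best mean, the first under the supplied
#' simplest-to-most-complex ordering is chosen (boosted: fewest rounds,
#' then shallowest depth; penalized: strongest penalty first).
#'
#' @param results `data.frame` with columns `mean` and `se`, ordered from
#'   simplest to most complex.
#' @return Row index of the chosen grid point.
#' @export
select_one_se <- function(results) {
  if (!nrow(results)) stop("empty grid results", call. = FALSE)
  best <- which.max(results$mean)
  cutoff <- results$mean[best] - results$se[best]
  which(results$mean >= cutoff)[1]
}

.se <- function(x) sd(x) / sqrt(length(x))

#' Cross-validate one model family over its hyper-parameter grid
#'
#' For every split: minority-subsample the training rows (optionally per
#' origin), fit the center/scale transformer on those rows, train at every
#' grid point, score the untouched validation rows by PR-AUC. Grid results
#' are aggregated over splits and the one-SE rule picks the final
#' configuration, which is then refitted on the full (subsampled,
#' rescaled) training data.
#'
#' @param x Feature matrix (training partition).
#' @param y Labels.
#' @param splits From [make_folds()].
#' @param kind `"penalized_L1"`, `"penalized_L2"` or `"boosted"`.
#' @param grid From [hyper_grid()].
#' @param origin Optional origin stratum for subsampling.
#' @param seed Integer seed.
#' @return List with `model` (refitted), `transformer`, `chosen` (grid
#'   point), `cv` (per-grid-point mean/se), `oof` (out-of-fold
#'   probabilities, averaged over repeats, at the chosen configuration).
#' @export
cv_train <- function(x, y, splits, kind, grid = hyper_grid(), origin = NULL,
                     seed = 1L) {
  penalized <- kind %in% c("penalized_L1", "penalized_L2")
  grid_points <- if (penalized) grid$lambda else seq_len(nrow(grid$boosted))
  scores <- matrix(NA_real_, nrow = length(grid_points), ncol = length(splits))
  oof_sum <- rep(0, length(y)); oof_n <- rep(0L, length(y))
  oof_prob <- vector("list", length(splits))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    sub <- subsample_minority(y[sp$train], origin = origin[sp$train],
                              seed = seed + si)
    tr_idx <- sp$train[sub]
    tf <- center_scale(x[tr_idx, , drop = FALSE])
    xtr <- apply_center_scale(tf, x[tr_idx, , drop = FALSE])
    xva <- apply_center_scale(tf, x[sp$validation, , drop = FALSE])
    yva <- y[sp$validation]
    if (penalized) {
      m <- train_model(xtr, y[tr_idx], kind, lambda = grid$lambda)
      for (gi in seq_along(grid_points)) {
        pr <- m$predict_prob(xva, s = grid_points[gi])
        scores[gi, si] <- evaluate_scores(pr, yva)$pr_auc
      }
      oof_prob[[si]] <- m
    } else {
      for (gi in seq_along(grid_points)) {
        m <- train_model(xtr, y[tr_idx], "boosted",
                         params = grid$boosted[grid_points[gi], ],
                         seed = seed + si)
        pr <- m$predict_prob(xva)
        scores[gi, si] <- evaluate_scores(pr, yva)$pr_auc
        if (is.null(oof_prob[[si]])) oof_prob[[si]] <- list()
        oof_prob[[si]][[gi]] <- pr
      }
    }
  }
  cv <- data.frame(grid = seq_along(grid_points),
                   mean = rowMeans(scores), se = apply(scores, 1, .se))
  order_idx <- if (penalized) {
    order(-grid_points) # strongest penalty = simplest first
  } else {
    b <- grid$boosted
    order(b$nrounds, b$max_depth, b$eta, b$min_child_weight, b$subsample)
  }
  chosen_rel <- select_one_se(cv[order_idx, , drop = FALSE])
  chosen_gi <- order_idx[chosen_rel]
  # out-of-fold probabilities at the chosen configuration
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    pr <- if (penalized) {
      tfm <- oof_prob[[si]]
      sub <- subsample_minority(y[sp$train], origin = origin[sp$train],
                                seed = seed + si)
      tf <- center_scale(x[sp$train[sub], , drop = FALSE])
      tfm$predict_prob(apply_center_scale(tf, x[sp$validation, , drop = FALSE]),
                       s = grid_points[chosen_gi])
    } else {
      oof_prob[[si]][[chosen_gi]]
    }
    oof_sum[sp$validation] <- oof_sum[sp$validation] + pr
    oof_n[sp$validation] <- oof_n[sp$validation] + 1L
  }
  # refit on the full training data at the chosen configuration
  sub <- subsample_minority(y, origin = origin, seed = seed)
  tf <- center_scale(x[sub, , drop = FALSE])
  xtr <- apply_center_scale(tf, x[sub, , drop = FALSE])
  model <- if (penalized) {
    train_model(xtr, y[sub], kind, lambda = grid$lambda)
  } else {
    train_model(xtr, y[sub], "boosted", params = grid$boosted[chosen_gi, ],
                seed = seed)
  }
  list(model = model, transformer = tf,
       chosen = if (penalized) grid_points[chosen_gi] else grid$boosted[chosen_gi, ],
       cv = cv, oof = ifelse(oof_n > 0, oof_sum / pmax(oof_n, 1L), NA_real_))
}

#' Stack base models with bootstrap-weighted logistic meta-learning
#'
#' The meta-learner is a logistic regression on the base models'
#' out-of-fold probabilities, with base-model weights constrained
#' non-negative (a lightly ridge-regularized fit): base probabilities are
#' strongly collinear, and unconstrained logistic weights can turn negative
#' on a good model and invert its ranking. Weights are averaged over
#' `n_bootstrap` resamples; each resample splits rows into in-bag training
#' (minority subsampled) and out-of-bag validation, on which the
#' per-bootstrap PR-AUC is recorded. A single base model degenerates to a
#' pass-through (with a warning).
#'
#' @param oof Matrix of out-of-fold probabilities (rows x base models).
#' @param y Labels aligned to `oof` rows.
#' @param n_bootstrap Bootstrap resamples (default 50).
#' @param seed Integer seed.
#' @return A `stacked_model` with `weights` and
#'   `predict_prob(base_prob_matrix)`.
#' @export
stack_models <- function(oof, y, n_bootstrap = 50L, seed = 1L) {
  oof <- as.matrix(oof)
  if (ncol(oof) == 1L) {
    warning("single base model: stack is a pass-through")
    return(structure(list(weights = c(`(Intercept)` = 0, base = 1),
                          pass_through = TRUE,
                          predict_prob = function(p) as.numeric(p[, 1])),
                     class = "stacked_model"))
  }
  restore <- .local_seed(seed)
  on.exit(restore())
  n <- nrow(oof)
  coefs <- matrix(NA_real_, n_bootstrap, ncol(oof) + 1L)
  boot_pr <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    inbag <- unique(sample(n, n, replace = TRUE))
    oob <- setdiff(seq_len(n), inbag)
    sub <- tryCatch(subsample_minority(y[inbag], seed = seed + b),
                    error = function(e) seq_along(inbag))
    tr <- inbag[sub]
    fit <- suppressWarnings(glmnet::glmnet(
      oof[tr, , drop = FALSE], .y01(y[tr]), family = "binomial", alpha = 0,
      lambda = 1e-3, lower.limits = 0, standardize = FALSE
    ))
    coefs[b, ] <- as.numeric(coef(fit, s = 1e-3))
    if (length(oob) && length(unique(y[oob])) == 2L) {
      p <- as.numeric(predict(fit, newx = oof[oob, , drop = FALSE],
                              s = 1e-3, type = "response"))
      boot_pr[b] <- evaluate_scores(p, y[oob])$pr_auc
    }
  }
  w <- colMeans(coefs, na.rm = TRUE)
  names(w) <- c("(Intercept)", colnames(oof))
  structure(list(
    weights = w, boot_pr_auc = boot_pr, pass_through = FALSE,
    predict_prob = function(p) {
      as.numeric(plogis(w[1] + as.matrix(p) %*% w[-1]))
    }
  ), class = "stacked_model")
}

#' Relative feature-importance table across model families
#'
#' Penalized models: importance is |standardized coefficient| (at the
#' chosen lambda) rescaled to percentages summing to 100 per method;
#' direction is the coefficient sign. Boosted trees: gain-based importance
#' rescaled to percentages; direction is the sign of the class-conditional
#' mean difference (functional minus nonfunctional, on the training
#' features). Stacked: base importances combined with the normalized
#' absolute stack weights.
#'
#' @param fits Named list of [cv_train()] results; names among
#'   `lasso`, `ridge`, `boosted`.
#' @param stack Optional [stack_models()] result (base order = `fits`
#'   order).
#' @param x,y Feature matrix and labels used for the tree direction.
#' @return `data.frame` feature x method of percentages, plus a
#'   `direction_<method>` column per method; sorted by stacked (or first
#'   method) importance.
#' @export
importance_table <- function(fits, stack = NULL, x = NULL, y = NULL) {
  feats <- colnames(fits[[1]]$transformer$mean)
  imp <- list(); dir <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (f$model$kind %in% c("penalized_L1", "penalized_L2")) {
      cf <- f$model$coefs_at(f$chosen)
      raw <- abs(cf)
      d <- sign(cf)
    } else {
      it <- xgboost::xgb.importance(model = f$model$fit)
      raw <- setNames(rep(0, length(f$model$feature_names)),
                      f$model$feature_names)
      raw[it$Feature] <- it$Gain
      d <- setNames(rep(0, length(raw)), names(raw))
      if (!is.null(x) && !is.null(y)) {
        mu_pos <- colMeans(x[y == "functional", names(raw), drop = FALSE])
        mu_neg <- colMeans(x[y == "nonfunctional", names(raw), drop = FALSE])
        d <- sign(mu_pos - mu_neg)
      }
    }
    pct <- if (sum(raw) > 0) 100 * raw / sum(raw) else raw
    imp[[nm]] <- pct
    dir[[nm]] <- d
  }
  features <- names(imp[[1]])
  out <- data.frame(feature = features, stringsAsFactors = FALSE)
  for (nm in names(imp)) {
    out[[nm]] <- unname(imp[[nm]][features])
    out[[paste0("direction_", nm)]] <-
      c("down", "none", "up")[sign(dir[[nm]][features]) + 2]
  }
  if (!is.null(stack) && !stack$pass_through) {
    w <- abs(stack$weights[-1])
    w <- w / sum(w)
    signed <- Reduce(`+`, lapply(seq_along(imp), function(i) {
      w[i] * imp[[i]][features] * ifelse(dir[[i]][features] < 0, -1, 1)
    }))
    raw <- abs(signed)
    out$stacked <- if (sum(raw) > 0) unname(100 * raw / sum(raw)) else unname(raw)
    out$direction_stacked <- c("down", "none", "up")[sign(signed) + 2]
    out <- out[order(-out$stacked), ]
  } else {
    out <- out[order(-out[[names(imp)[1]]]), ]
  }
  rownames(out) <- NULL
  out
}
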