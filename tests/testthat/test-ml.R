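make_xy <- function(n = 200, p = 6, seed = 111, prevalence = 0.3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  score <- x[, 1] - x[, 2]
  y <- ifelse(score + rnorm(n, 0, 0.5) >
                quantile(score, 1 - prevalence), "functional", "nonfunctional")
  list(x = x, y = y)
}

test_that("correlation pruning matches the brute-force component oracle", {
  set.seed(112)
  base <- rnorm(100)
  x <- cbind(
    a = base, b = base + rnorm(100, 0, 0.1), c = base + rnorm(100, 0, 0.1),
    d = rnorm(100), e = rnorm(100)
  )
  got <- corr_prune(x, 0.75)
  expect_setequal(sort(got$kept), oracle_corr_prune_kept(x, 0.75))
  # duplicated column: exactly one survivor of the pair
  xd <- cbind(u = base, v = base, w = rnorm(100))
  expect_equal(sort(corr_prune(xd, 0.75)$kept), c("u", "w"))
  # orthogonal features are all kept
  xo <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("p", "q", "r")))
  expect_setequal(corr_prune(xo, 0.75)$kept, c("p", "q", "r"))
  # forced-keep features survive even inside a correlated cluster
  expect_true("b" %in% corr_prune(x, 0.75, forced_keep = "b")$kept)
})

test_that("linear-combination pruning restores full column rank", {
  set.seed(113)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("c", 1:4)))
  x <- cbind(x, c5 = x[, 1] + x[, 2])
  before_rank <- qr(x)$rank
  out <- lincomb_prune(x)
  expect_equal(ncol(out$x), qr(out$x)$rank)
  expect_equal(qr(out$x)$rank, before_rank)
  expect_length(out$removed, 1L)
  # full-rank input is unchanged
  full <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))
  expect_identical(lincomb_prune(full)$x, full)
})

test_that("near-zero-variance pruning applies the 95/5 frequency ratio", {
  x <- cbind(
    rare = c(rep(0, 96), rep(1, 4)),    # ratio 24 > 19 -> removed
    even = rep(c(0, 1), 50),            # 50:50 -> kept
    constant = rep(7, 100),             # removed
    border = c(rep(0, 95), rep(1, 5))   # ratio 19, not > 19 -> kept
  )
  out <- nzv_prune(x)
  expect_setequal(out$removed, c("rare", "constant"))
  expect_setequal(colnames(out$x), c("even", "border"))
})

test_that("center/scale is fitted on training rows only", {
  d <- make_xy()
  tf <- center_scale(d$x[1:150, ])
  xt <- apply_center_scale(tf, d$x[1:150, ])
  expect_true(all(abs(colMeans(xt)) < 1e-12))
  expect_true(all(abs(apply(xt, 2, sd) - 1) < 1e-12))
  # validation rows reuse training parameters (transformer unchanged)
  before <- tf
  xv <- apply_center_scale(tf, d$x[151:200, ] + 100)
  expect_identical(tf, before)
  expect_false(all(abs(colMeans(xv)) < 1))
  # zero-variance column: centered, no division blow-up
  xz <- cbind(z = rep(3, 50), w = rnorm(50))
  tz <- center_scale(xz)
  expect_true(all(is.finite(apply_center_scale(tz, xz))))
})

test_that("stratified holdout preserves sizes and prevalence", {
  y <- c(rep("functional", 40), rep("nonfunctional", 360))
  sp <- split_holdout(y, seed = 5)
  expect_equal(length(sp$train), 300L)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
  expect_equal(sum(y[sp$train] == "functional"), 30L)
  expect_identical(sp, split_holdout(y, seed = 5))
})

test_that("fold plans cover rows exactly and never split groups", {
  y <- rep(c("functional", "nonfunctional"), c(30, 170))
  folds <- make_folds(y, "repeated_kfold", k = 5, repeats = 10, seed = 7)
  expect_length(folds, 50L)
  for (r in 1:10) {
    val <- unlist(lapply(folds[(5 * (r - 1) + 1):(5 * r)], `[[`, "validation"))
    expect_equal(sort(val), seq_along(y)) # each row validated once per repeat
  }
  for (f in folds) expect_length(intersect(f$train, f$validation), 0L)
  # group mode with 13 groups: fold sizes {3,3,3,2,2}, no group on both sides
  groups <- rep(paste0("tad", 1:13), each = 10)
  yg <- rep(c("functional", "nonfunctional"), length.out = length(groups))
  gf <- make_folds(yg, "group_kfold", groups = groups, k = 5, repeats = 2,
                   seed = 8)
  expect_length(gf, 10L)
  for (f in gf) {
    expect_length(intersect(unique(groups[f$train]),
                            unique(groups[f$validation])), 0L)
  }
  sizes <- sort(sapply(gf[1:5], function(f) length(unique(groups[f$validation]))))
  expect_equal(sizes, c(2L, 2L, 3L, 3L, 3L))
  expect_error(make_folds(yg[1:30], "group_kfold", groups = groups[1:30],
                          k = 13), "fewer groups")
})

test_that("minority subsampling equalizes classes (per origin when asked)", {
  y <- rep(c("functional", "nonfunctional"), c(20, 300))
  keep <- subsample_minority(y, seed = 9)
  expect_equal(as.integer(table(y[keep])), c(20L, 20L))
  origin <- rep(c("random", "design"), length.out = 320)
  keep2 <- subsample_minority(y, origin = origin, seed = 9)
  tab <- table(y[keep2], origin[keep2])
  expect_equal(unname(tab["functional", ]), unname(tab["nonfunctional", ]))
  expect_identical(subsample_minority(y, seed = 9), keep)
  expect_error(subsample_minority(rep("functional", 5)), "class is empty")
})

test_that("hyper grids enumerate 50 lambdas and 32 boosted combinations", {
  g <- hyper_grid()
  expect_length(g$lambda, 50L)
  expect_equal(range(g$lambda), c(1e-5, 0.1))
  expect_true(all(abs(diff(sort(g$lambda)) - diff(sort(g$lambda))[1]) < 1e-12))
  expect_equal(nrow(g$boosted), 32L)
  expect_equal(length(unique(g$boosted$colsample_bytree)), 1L)
})

test_that("penalized models shrink to zero at extreme penalty", {
  d <- make_xy()
  m <- train_model(d$x, d$y, "penalized_L1", lambda = c(100, 1, 1e-4))
  cf <- m$coefs_at(100)
  expect_true(all(abs(cf) < 1e-10))
  cf2 <- m$coefs_at(1e-4)
  expect_gt(max(abs(cf2)), 0)
  probs <- m$predict_prob(d$x, s = 1e-4)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("score evaluation matches known geometry and external AUC", {
  y <- c(rep("functional", 10), rep("nonfunctional", 90))
  perfect <- c(seq(0.9, 0.99, length.out = 10), seq(0.0, 0.5, length.out = 90))
  ev <- evaluate_scores(perfect, y)
  expect_equal(ev$pr_auc, 1.0)
  expect_equal(ev$roc_auc, 1.0)
  expect_equal(ev$baseline, 0.1)
  # random scores at low prevalence: PR-AUC near prevalence, ROC near 0.5
  set.seed(115)
  yr <- ifelse(runif(20000) < 0.01, "functional", "nonfunctional")
  pr <- runif(20000)
  evr <- evaluate_scores(pr, yr)
  expect_lt(abs(evr$pr_auc - 0.01), 0.01)
  expect_lt(abs(evr$roc_auc - 0.5), 0.05)
  expect_error(evaluate_scores(runif(5), rep("functional", 5)), "single-class")
  # ROC agrees with an independent implementation
  skip_if_not_installed("pROC")
  set.seed(116)
  ys <- ifelse(runif(300) < 0.3, "functional", "nonfunctional")
  ps <- runif(300) + 0.3 * (ys == "functional")
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(ys, ps, levels = c("nonfunctional", "functional"),
                        direction = "<"))))
  expect_equal(evaluate_scores(ps, ys)$roc_auc, ref, tolerance = 1e-10)
})

test_that("one-SE selection picks the simplest model within one SE", {
  res <- data.frame(mean = c(0.79, 0.80), se = c(0.01, 0.02))
  expect_equal(select_one_se(res), 1L) # .79 >= .80 - .02
  res2 <- data.frame(mean = c(0.70, 0.80), se = c(0.01, 0.02))
  expect_equal(select_one_se(res2), 2L)
  expect_equal(select_one_se(data.frame(mean = 0.5, se = 0.1)), 1L)
  expect_error(select_one_se(data.frame(mean = numeric(0), se = numeric(0))),
               "empty")
})

test_that("cross-validated training recovers the informative features", {
  d <- make_xy(n = 300, seed = 117)
  splits <- make_folds(d$y, "repeated_kfold", repeats = 2, seed = 118)
  fit <- cv_train(d$x, d$y, splits, "penalized_L1", seed = 119)
  cf <- fit$model$coefs_at(fit$chosen)
  expect_gt(abs(cf["f1"]), max(abs(cf[c("f3", "f4", "f5", "f6")])))
  expect_lt(cf["f2"], 0)
  expect_equal(length(fit$oof), length(d$y))
  expect_true(all(is.finite(fit$oof)))
  # deterministic under the same seed
  fit2 <- cv_train(d$x, d$y, splits, "penalized_L1", seed = 119)
  expect_equal(coef(fit$model$fit), coef(fit2$model$fit), tolerance = 1e-10)
})

test_that("stacking weights base models and degenerates gracefully", {
  d <- make_xy(n = 250, seed = 120)
  good <- plogis(d$x[, 1] - d$x[, 2] + rnorm(250, 0, 0.3))
  noise <- runif(250)
  stack <- stack_models(cbind(good = good, noise = noise), d$y, seed = 121)
  expect_gt(stack$weights["good"], stack$weights["noise"])
  p <- stack$predict_prob(cbind(good, noise))
  expect_gt(evaluate_scores(p, d$y)$roc_auc,
            evaluate_scores(noise, d$y)$roc_auc)
  expect_identical(stack$weights,
                   stack_models(cbind(good = good, noise = noise), d$y,
                                seed = 121)$weights)
  expect_warning(s1 <- stack_models(cbind(only = good), d$y), "pass-through")
  expect_equal(s1$predict_prob(cbind(good)), good)
})

test_that("importance tables are percentage-normalized with directions", {
  d <- make_xy(n = 300, seed = 122)
  splits <- make_folds(d$y, "repeated_kfold", repeats = 2, seed = 123)
  fits <- list(
    lasso = cv_train(d$x, d$y, splits, "penalized_L1", seed = 124),
    ridge = cv_train(d$x, d$y, splits, "penalized_L2", seed = 125)
  )
  oof <- cbind(lasso = fits$lasso$oof, ridge = fits$ridge$oof)
  stack <- stack_models(oof, d$y, seed = 126)
  tab <- importance_table(fits, stack, x = d$x, y = d$y)
  expect_equal(sum(tab$lasso), 100, tolerance = 1e-8)
  expect_equal(sum(tab$ridge), 100, tolerance = 1e-8)
  expect_equal(sum(tab$stacked), 100, tolerance = 1e-8)
  expect_equal(tab$direction_lasso[tab$feature == "f1"], "up")
  expect_equal(tab$direction_lasso[tab$feature == "f2"], "down")
  expect_true(all(tab$feature[1:2] %in% c("f1", "f2")))
})
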