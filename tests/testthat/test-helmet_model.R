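test_that("the transition-weighted loss matches its closed forms", {
  # two observations with probability 1/2 on the true class, one
  # transition and one not, w = 1/2: L = ln 2 + 0.5 ln 2 = 1.5 ln 2
  p <- matrix(c(0.5, 0.5, 0, 0,
                0.5, 0.5, 0, 0), 2, byrow = TRUE)
  y <- c(0L, 0L)
  wx <- weighted_xent(p, y, filtered = c(TRUE, FALSE), w = 0.5)
  expect_equal(wx$loss, 1.5 * log(2), tolerance = 1e-12)

  # w = 1 reduces to plain categorical cross-entropy
  set.seed(41)
  P <- runif_simplex(50)
  yy <- sample(0:3, 50, replace = TRUE)
  fl <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  plain <- -sum(log(P[cbind(1:50, yy + 1)]))
  expect_equal(weighted_xent(P, yy, fl, 1)$loss, plain, tolerance = 1e-9)

  # perfect prediction has zero loss, and zero probabilities are clipped
  eye <- diag(4)[yy + 1, ]
  expect_equal(weighted_xent(eye, yy, fl, 0.5)$loss, 0)
  expect_true(is.finite(weighted_xent(eye, (yy + 1) %% 4, fl, 0.5)$loss))

  expect_error(weighted_xent(P, yy, fl, 0), "w must")
  expect_error(weighted_xent(P, yy, fl, 1.5), "w must")
})

test_that("the loss is affine in w with slope equal to the non-filtered cross-entropy", {
  set.seed(42)
  P <- runif_simplex(80)
  y <- sample(0:3, 80, replace = TRUE)
  fl <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  L <- function(w) weighted_xent(P, y, fl, w)$loss
  xent_nf <- -sum(log(pmax(P[cbind(which(!fl), y[!fl] + 1)], 1e-12)))
  # evaluate at two w values and check slope and a third point
  slope <- (L(1) - L(0.25)) / 0.75
  expect_equal(slope, xent_nf, tolerance = 1e-9)
  expect_equal(L(0.5), L(0.25) + 0.25 * xent_nf, tolerance = 1e-9)
  # all observations filtered: w is irrelevant
  expect_equal(weighted_xent(P, y, rep(TRUE, 80), 0.3)$loss,
               weighted_xent(P, y, rep(TRUE, 80), 1)$loss)
})

test_that("gradients and curvatures scale with the per-observation weight", {
  set.seed(43)
  P <- runif_simplex(20)
  y <- sample(0:3, 20, replace = TRUE)
  Y <- diag(4)[y + 1, ]
  wx <- weighted_xent(P, y, filtered = rep(FALSE, 20), w = 0.5)
  expect_equal(wx$grad, 0.5 * (P - Y), tolerance = 1e-12)
  expect_equal(wx$hess, 2 * 0.5 * P * (1 - P), tolerance = 1e-12)
  expect_equal(wx$weights, rep(0.5, 20))
})

test_that("split plans are patient-disjoint, sized, and seeded", {
  ids <- sprintf("P%03d", 1:100)
  plan <- make_splits(ids, seed = 7)
  expect_length(plan, 5)
  for (sp in plan) {
    expect_length(sp$test, 20)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), ids)
  }
  expect_identical(make_splits(ids, seed = 7), plan)
  expect_false(identical(make_splits(ids, seed = 8), plan))
  expect_error(make_splits(ids[1:3], seed = 1), "at least 5")
})

test_that("w = 1 training coincides with the builtin multiclass log-loss objective", {
  obs <- cached_obs(20, 13, 24)
  hp <- helmet_hyperparams(w = 1, nrounds = 15, eta = 0.3, subsample = 1,
                           colsample_bytree = 1, seed = 5)
  bundle <- train_helmet(obs, hp)
  mf <- helmet:::model_frame(obs, bundle$feature_names)
  X <- helmet:::impute_columns(mf$X, bundle$col_means)
  ref <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 4,
                  max_depth = hp$max_depth, eta = hp$eta,
                  subsample = 1, colsample_bytree = 1,
                  min_child_weight = hp$min_child_weight,
                  nthread = 1, seed = 5),
    data = xgboost::xgb.DMatrix(X, label = mf$y, nthread = 1),
    nrounds = 15, verbose = 0)
  p_ours <- predict_proba(bundle, obs[mf$rows, ])
  p_ref <- predict(ref, xgboost::xgb.DMatrix(X, nthread = 1))
  expect_equal(p_ours, unname(p_ref), tolerance = 1e-6)
})

test_that("training is deterministic and loss decreases over boosting rounds", {
  obs <- cached_obs(20, 13, 24)
  hp <- helmet_hyperparams(w = 0.5, nrounds = 30, eta = 0.3, seed = 9)
  b1 <- train_helmet(obs, hp)
  b2 <- train_helmet(obs, hp)
  mf <- helmet:::model_frame(obs, b1$feature_names)
  p1 <- predict_proba(b1, obs[mf$rows, ])
  p2 <- predict_proba(b2, obs[mf$rows, ])
  expect_identical(p1, p2)
  expect_equal(max(abs(rowSums(p1) - 1)), 0, tolerance = 1e-9)

  losses <- vapply(c(5, 15, 30), function(nr) {
    b <- train_helmet(obs, helmet_hyperparams(w = 0.5, nrounds = nr,
                                              eta = 0.3, seed = 9))
    p <- predict_proba(b, obs[mf$rows, ])
    weighted_xent(p, mf$y, mf$filtered, 0.5)$loss
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("lowering w raises the filtered share of the training loss", {
  obs <- cached_obs(20, 13, 24)
  mf <- helmet:::model_frame(obs, names(attr(obs, "categories")))
  share <- function(w) {
    b <- train_helmet(obs, helmet_hyperparams(w = w, nrounds = 25,
                                              eta = 0.3, seed = 4))
    p <- predict_proba(b, obs[mf$rows, ])
    pc <- pmax(p[cbind(seq_along(mf$y), mf$y + 1)], 1e-12)
    ll <- -log(pc)
    sum(ll[mf$filtered]) / (sum(ll[mf$filtered]) + w * sum(ll[!mf$filtered]))
  }
  expect_gte(share(0.3), share(1) - 0.02)
})

test_that("schema mismatch and degenerate targets raise errors", {
  obs <- cached_obs(20, 13, 24)
  hp <- helmet_hyperparams(nrounds = 5)
  one_class <- obs
  one_class$target_class[one_class$valid] <- 2L
  expect_error(train_helmet(one_class, hp), "single target class")
  b <- train_helmet(obs, hp)
  expect_error(predict_proba(b, obs[, 1:10]), "schema mismatch")
})

test_that("random-search tuning returns the dominant candidate deterministically", {
  obs <- cached_obs(20, 13, 24)
  ids <- unique(obs$patient_id)
  space <- list(
    w = function(n) c(0.5, 0.5)[seq_len(n)],
    eta = function(n) c(0.3, 0.3)[seq_len(n)],
    max_depth = function(n) c(4L, 4L)[seq_len(n)],
    nrounds = function(n) c(25L, 1L)[seq_len(n)],  # 25 rounds dominates 1
    subsample = function(n) rep(1, n),
    colsample_bytree = function(n) rep(1, n)
  )
  hp1 <- tune_w_and_params(obs, ids, budget = 2, seed = 3, space = space)
  expect_identical(hp1$nrounds, 25L)
  tr <- attr(hp1, "trace")
  expect_identical(nrow(tr), 2L)
  expect_gt(tr$score[1], tr$score[2])
  hp2 <- tune_w_and_params(obs, ids, budget = 2, seed = 3, space = space)
  attr(hp1, "trace") <- attr(hp2, "trace") <- NULL
  expect_identical(hp1, hp2)
  # budget 1 returns the single candidate
  hp3 <- tune_w_and_params(obs, ids, budget = 1, seed = 3, space = space)
  expect_identical(hp3$nrounds, 25L)
})
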