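test_that("perfectly separating probabilities score AUROC 1 and accuracy 1", {
  y <- rep(0:3, each = 10)
  p <- diag(4)[y + 1, ] * 0.97 + 0.0075
  cv <- weighted_ovr_curves(p, y)
  expect_equal(cv$auroc, 1, tolerance = 1e-9)
  expect_equal(accuracy_argmax(p, y), 1)
  expect_false(cv$undefined)
})

test_that("single-class targets yield undefined curve metrics, not numbers", {
  p <- runif_simplex(10)
  cv <- weighted_ovr_curves(p, rep(2L, 10))
  expect_true(cv$undefined)
  expect_true(is.na(cv$auroc))
  expect_true(is.na(cv$auprc))
})

test_that("threshold-swept areas agree with the brute-force cutoff oracle", {
  set.seed(51)
  for (rep in 1:3) {
    n <- 200
    y <- sample(0:3, n, replace = TRUE,
                prob = c(0.4, 0.3, 0.2, 0.1))
    # a mildly informative predictor: noisy one-hot mixtures
    p <- runif_simplex(n) + 1.5 * diag(4)[y + 1, ] * runif(n)
    p <- p / rowSums(p)
    cv <- weighted_ovr_curves(p, y)
    bf <- brute_force_ovr_areas(p, y)
    expect_equal(cv$auroc, bf$auroc, tolerance = 1e-6)
    expect_equal(cv$auprc, bf$auprc, tolerance = 1e-6)
  }
})

test_that("class-complement symmetry holds per class", {
  # for a binary one-vs-rest problem, AUROC of p and of 1 - p sum to 1;
  # check on a two-class instance where only one class weight is active
  set.seed(52)
  n <- 100
  y <- sample(c(0L, 1L), n, replace = TRUE)
  s <- runif(n)
  mk <- function(score) cbind(score, 1 - score, 0, 0)
  a <- weighted_ovr_curves(mk(s), y)$auroc
  b <- weighted_ovr_curves(mk(1 - s), y)$auroc
  expect_equal(a + b, 1, tolerance = 1e-9)
})

test_that("the weighted curve lies between the per-class extremes", {
  set.seed(53)
  n <- 120
  y <- sample(0:3, n, replace = TRUE)
  p <- runif_simplex(n)
  th <- c(0.25, 0.5, 0.75)
  cv <- weighted_ovr_curves(p, y, thresholds = th)
  for (t in th) {
    per_class <- vapply(0:3, function(c) {
      mean(p[y == c, c + 1] >= t)
    }, numeric(1))
    row <- cv$roc[abs(cv$roc$threshold - t) < 1e-12, ]
    expect_gte(row$tpr, min(per_class) - 1e-9)
    expect_lte(row$tpr, max(per_class) + 1e-9)
  }
})

test_that("argmax accuracy breaks ties toward the lower class code", {
  p <- matrix(c(0.4, 0.4, 0.1, 0.1), 1)
  expect_identical(argmax_class(p), 0L)
  expect_equal(accuracy_argmax(p, 0L), 1)
  expect_equal(accuracy_argmax(p, 1L), 0)
  expect_true(is.na(accuracy_argmax(p[0, , drop = FALSE], integer(0))))
})

test_that("worsening reformulation follows the class-ordering rules", {
  # current 1, target 2, argmax 3: a true positive
  p <- matrix(c(0, 0, 0, 1), 1)
  wm <- worsening_metrics(p, targets = 2L, current = 1L)
  expect_equal(wm$sensitivity, 1)
  expect_true(is.na(wm$specificity))

  # current class 3 can never worsen: always a true negative
  wm3 <- worsening_metrics(matrix(c(1, 0, 0, 0), 1), targets = 3L,
                           current = 3L)
  expect_true(is.na(wm3$sensitivity))
  expect_equal(wm3$specificity, 1)

  # persistence predictor: sensitivity 0, specificity 1
  set.seed(54)
  cur <- sample(0:2, 50, replace = TRUE)
  tgt <- pmin(cur + sample(0:1, 50, replace = TRUE), 3)
  p_persist <- diag(4)[cur + 1, ]
  wm_p <- worsening_metrics(p_persist, tgt, cur)
  expect_equal(wm_p$sensitivity, 0)
  expect_equal(wm_p$specificity, 1)
})

test_that("evaluate_predictions selects the filtered subset exactly", {
  set.seed(55)
  n <- 80
  tgt <- sample(0:3, n, replace = TRUE)
  cur <- sample(0:3, n, replace = TRUE)
  fl <- tgt != cur
  p <- runif_simplex(n)
  overall <- evaluate_predictions(p, tgt, cur, fl, "overall")
  filt <- evaluate_predictions(p, tgt, cur, fl, "filtered")
  expect_identical(overall$n, as.integer(n))
  expect_identical(filt$n, as.integer(sum(fl)))
  direct <- weighted_ovr_curves(p[fl, ], tgt[fl])
  expect_equal(filt$auroc, direct$auroc)
  # permutation invariance
  o <- sample(n)
  perm <- evaluate_predictions(p[o, ], tgt[o], cur[o], fl[o], "overall")
  expect_equal(perm$auroc, overall$auroc, tolerance = 1e-12)
  # empty subset: undefined throughout
  none <- evaluate_predictions(p, tgt, cur, rep(FALSE, n), "filtered")
  expect_identical(none$n, 0L)
  expect_true(is.na(none$auroc))
})

test_that("split summaries reproduce the closed-form t-interval", {
  v <- c(0.8, 0.85, 0.9, 0.95, 1.0)
  df <- data.frame(mode = "overall", split = 1:5, n = 10, auroc = v)
  s <- summarize_splits(df)
  m <- mean(v)
  half <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(s$mean[s$metric == "auroc"], m)
  expect_equal(s$ci_lo[s$metric == "auroc"], m - half)
  expect_equal(s$ci_hi[s$metric == "auroc"], m + half)

  same <- data.frame(mode = "overall", split = 1:5, n = 10, auroc = 0.9)
  s2 <- summarize_splits(same)
  expect_equal(s2$ci_lo, 0.9)
  expect_equal(s2$ci_hi, 0.9)

  # NA split values propagate with reduced n
  some_na <- data.frame(mode = "overall", split = 1:5, n = 10,
                        auroc = c(0.8, 0.9, NA, NA, NA))
  s3 <- summarize_splits(some_na)
  expect_identical(s3$n_splits, 2L)
  all_na <- data.frame(mode = "overall", split = 1:2, n = 5,
                       auroc = NA_real_)
  expect_true(is.na(summarize_splits(all_na)$mean))
})
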