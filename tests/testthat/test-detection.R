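test_that("confusion counts match enumeration", {
  # perfect separation
  cc <- confusionCounts(c(0.9, 0.8, 0.1, 0.2),
                        c(TRUE, TRUE, FALSE, FALSE), 0.5)
  expect_equal(cc[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  expect_equal(cc$se, 1); expect_equal(cc$sp, 1)
  # threshold 0 calls everything positive
  cc0 <- confusionCounts(c(0.9, 0.8, 0.1, 0.2),
                         c(TRUE, TRUE, FALSE, FALSE), 0)
  expect_equal(cc0$se, 1); expect_equal(cc0$sp, 0)
  # enumeration oracle on the mixed example
  cc2 <- confusionCounts(c(0.35, 0.8, 0.1, 0.4),
                         c(TRUE, TRUE, FALSE, FALSE), 0.35)
  expect_equal(cc2[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 1L, tn = 1L, fn = 0L))
  expect_equal(cc2$se, 1); expect_equal(cc2$sp, 0.5)
  expect_error(confusionCounts(1:3, c(TRUE, TRUE, TRUE), 1), "class")
})

test_that("ROC analysis reproduces hand-derived cases", {
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(rocAuc(rocCurve(c(5, 6, 1, 2), pos)), 1)
  # identical scores in both classes -> chance
  expect_equal(rocAuc(rocCurve(c(3, 3, 3, 3), pos)), 0.5)
  # pair-counting oracle: 3 of 4 positive>negative pairs
  roc <- rocCurve(c(0.35, 0.8, 0.1, 0.4), pos)
  expect_equal(rocAuc(roc), 0.75)
  expect_equal(youdenJ(roc), 0.5)
  expect_equal(optimalThreshold(roc), 0.35)   # tie with 0.8 broken low
  # degenerate label input
  expect_error(rocCurve(1:4, rep(TRUE, 4)), "class")
})

test_that("Youden search ties resolve toward higher sensitivity", {
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  y <- youdenOptimal(rocCurve(c(0.35, 0.8, 0.1, 0.4), pos))
  expect_equal(y$j, 0.5)
  expect_equal(y$threshold, 0.35)
  # identical distributions give J = 0
  expect_equal(youdenOptimal(rocCurve(c(1, 2, 1, 2), pos))$j, 0)
})

test_that("trapezoidal AUC equals Mann-Whitney and Youden equals grid
           search on random instances", {
  set.seed(314)
  for (rep in 1:60) {
    n <- sample(6:50, 1)
    n_pos <- sample(2:(n - 2), 1)
    positive <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    scores <- round(rnorm(n, mean = positive * runif(1, 0, 2)),
                    sample(0:2, 1))   # rounding induces ties
    roc <- rocCurve(scores, positive)
    expect_equal(rocAuc(roc), mann_whitney_auc(scores, positive),
                 tolerance = 1e-12)
    g <- grid_youden(scores, positive)
    expect_equal(youdenJ(roc), g$j, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:10) {
    n <- 40
    positive <- sample(c(TRUE, FALSE), n, replace = TRUE,
                       prob = c(0.3, 0.7))
    if (!any(positive) || all(positive)) next
    scores <- rnorm(n) + positive
    ref <- as.numeric(pROC::auc(pROC::roc(positive, scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(rocCurve(scores, positive)), ref,
                 tolerance = 1e-10)
  }
})

test_that("monotone score transforms leave AUC, J and rho unchanged", {
  set.seed(5)
  n <- 30
  positive <- sample(c(TRUE, FALSE), n, replace = TRUE)
  positive[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(n) + positive
  grades <- sample(1:5, n, replace = TRUE)
  f <- function(x) exp(2 * x) + 1
  r1 <- rocCurve(scores, positive); r2 <- rocCurve(f(scores), positive)
  expect_equal(rocAuc(r1), rocAuc(r2))
  expect_equal(youdenJ(r1), youdenJ(r2))
  expect_equal(optimalThreshold(r2), f(optimalThreshold(r1)))
  expect_equal(spearmanScoreGrade(scores, grades)$rho,
               spearmanScoreGrade(f(scores), grades)$rho)
})

test_that("0.632 blend has the right fixed point and hand value", {
  blend <- fidnavQC:::.blend632
  for (a in c(0, 0.37, 1)) expect_equal(blend(a, a), a)
  expect_equal(blend(1.0, 0.8), 0.8736)
})

test_that("bootstrap of well-separated classes is near-perfect and
           deterministic for a seed", {
  set.seed(2)
  scores <- c(runif(12, 10, 14), runif(30, 1, 6))
  positive <- scores > 9
  bs <- bootstrap632(scores, positive, b = 50, seed = 9)
  expect_equal(bs@sp632, 1)
  expect_gte(bs@se632, 0.9)
  expect_equal(bs@aucMean, 1)
  expect_equal(bs@jMean, 1)
  bs2 <- bootstrap632(scores, positive, b = 50, seed = 9)
  expect_equal(bs@se632, bs2@se632)
  expect_equal(bs@threshold,
               optimalThreshold(rocCurve(scores, positive)))
  expect_error(bootstrap632(scores, rep(TRUE, length(scores)), b = 5),
               "class")
})

test_that("Spearman correlation matches the rank-formula oracle", {
  # d^2 = (0,1,1,0) -> rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(spearmanScoreGrade(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_equal(spearmanScoreGrade(1:6, 1:6)$rho, 1)
  expect_equal(spearmanScoreGrade(1:6, 6:1)$rho, -1)
  sp <- spearmanScoreGrade(c(10, 20, 30, 25, 5, 40), c(1, 2, 3, 3, 1, 5))
  expect_lt(sp$p, 1)
  expect_warning(z <- spearmanScoreGrade(rep(1, 5), 1:5), "constant")
  expect_equal(z$rho, 0)
})

test_that("weighted kappa matches a brute-force contingency oracle", {
  # identical ratings
  expect_equal(weightedKappa(1:5, 1:5, ci_b = 0)$kappa, 1)
  # 2x2-style table [[20,5],[5,20]]: brute force from observed/expected
  a <- rep(c(1, 1, 2, 2), c(20, 5, 5, 20))
  b <- rep(c(1, 2, 1, 2), c(20, 5, 5, 20))
  o <- table(a, b) / 50
  e <- outer(rowSums(o), colSums(o))
  v <- abs(outer(1:2, 1:2, `-`))
  oracle <- 1 - sum(v * o) / sum(v * e)
  expect_equal(weightedKappa(a, b, ci_b = 0)$kappa, oracle)
  # near-independent uniform ratings -> kappa near 0
  set.seed(31)
  x <- sample(1:5, 4000, replace = TRUE)
  y <- sample(1:5, 4000, replace = TRUE)
  expect_lt(abs(weightedKappa(x, y, ci_b = 0)$kappa), 0.05)
  # quadratic weights on an off-by-adjacent pattern exceed linear
  a2 <- c(1, 2, 3, 4, 5, 1, 2, 3)
  b2 <- c(1, 2, 3, 4, 4, 1, 3, 3)
  lin <- weightedKappa(a2, b2, "linear", levels = 1:5, ci_b = 0)$kappa
  quad <- weightedKappa(a2, b2, "quadratic", levels = 1:5, ci_b = 0)$kappa
  expect_gt(quad, lin)
  # CI is seeded-deterministic and brackets the estimate
  k1 <- weightedKappa(a2, b2, ci_b = 200, seed = 4)
  k2 <- weightedKappa(a2, b2, ci_b = 200, seed = 4)
  expect_equal(k1$ci, k2$ci)
  expect_true(k1$ci[1] <= k1$kappa && k1$kappa <= k1$ci[2])
  expect_error(weightedKappa(1:4, 1:5), "equal length")
})

test_that("grade dichotomizations split at the documented boundaries", {
  g <- c(1, 2, 3, 4, 5)
  expect_equal(dichotomizeGrades(g, "12v345"),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(dichotomizeGrades(g, "123v45"),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(dichotomizeGrades(c(0, 3)), "1..5")
})
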