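test_that("intercept-only fit reproduces outcome frequencies", {
  y <- factor(rep(c("1", "2", "3"), c(46, 32, 22)))
  fit <- fit_baseline_multinomial(y)
  freq <- c(`1` = 46, `2` = 32, `3` = 22) / 100
  expect_equal(colMeans(fit$fitted)[names(freq)], freq, tolerance = 1e-6)
  # null-model accuracy equals the largest class share
  expect_equal(correctly_predicted_pct(fit), 46)
  expect_equal(fit$reference, "1")  # largest class is the reference
})

test_that("binary logit odds ratio equals the contingency cross-product", {
  # 2x2 table: a=30 b=10 / c=15 d=25
  y <- factor(rep(c("no", "yes", "no", "yes"), c(30, 10, 15, 25)))
  x <- factor(rep(c("lo", "hi"), c(40, 40)))
  fit <- fit_baseline_multinomial(y, data.frame(x = x), reference = "no")
  or <- wald_or_ci(fit)
  row <- or[or$term != "(intercept)", ]
  # cross-product ratio for yes vs no, comparing the non-reference level of x
  ref_level <- fit$predictor_refs$x
  other <- setdiff(levels(x), ref_level)
  tab <- table(x, y)
  cross <- (tab[other, "yes"] * tab[ref_level, "no"]) /
    (tab[other, "no"] * tab[ref_level, "yes"])
  expect_equal(row$or, unname(cross), tolerance = 1e-6)
})

test_that("the fit matches the reference implementation and recovers parameters", {
  skip_if_not_installed("nnet")
  set.seed(31)
  n <- 2000
  x1 <- factor(sample(1:3, n, TRUE, prob = c(0.2, 0.5, 0.3)))
  x2 <- factor(sample(1:2, n, TRUE))
  b <- list(`2` = c(0.3, 0.8, -0.4, -0.6), `3` = c(-0.2, -0.5, 0.6, 0.9))
  X <- cbind(1, x1 == "1", x1 == "3", x2 == "2")  # ref: largest levels (2, 1)
  lp2 <- drop(X %*% b$`2`); lp3 <- drop(X %*% b$`3`)
  pr <- cbind(1, exp(lp2), exp(lp3)); pr <- pr / rowSums(pr)
  y <- factor(vapply(seq_len(n), function(i)
    sample(1:3, 1, prob = pr[i, ]), integer(1)))

  fit <- fit_baseline_multinomial(y, data.frame(x1 = x1, x2 = x2),
                                  reference = "1")
  expect_true(fit$converged)

  # parameter recovery within 3 Wald SEs
  truth <- rbind(unlist(b$`2`), unlist(b$`3`))
  expect_true(all(abs(fit$coef - truth) < 3 * fit$se))

  # reference oracle on the identical design
  d <- data.frame(y = relevel(y, "1"),
                  x1.1 = as.numeric(x1 == "1"), x1.3 = as.numeric(x1 == "3"),
                  x2.2 = as.numeric(x2 == "2"))
  rf <- nnet::multinom(y ~ ., data = d, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(fit$coef), unname(coef(rf)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(summary(rf)$standard.errors),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(rf)), tolerance = 1e-6)
})

test_that("Wald intervals are log-symmetric and match the printed example", {
  # printed OR 6.27 with CI (1.58-24.88): SE back-solved from the interval
  se <- log(24.88 / 1.58) / (2 * qnorm(0.975))
  ci_lo <- exp(log(6.27) - qnorm(0.975) * se)
  ci_hi <- exp(log(6.27) + qnorm(0.975) * se)
  expect_equal(round(ci_lo, 2), 1.58, tolerance = 0.015)
  expect_equal(round(ci_hi, 2), 24.88, tolerance = 0.015)

  # CI endpoints multiply to OR^2 (identity on the log scale)
  y <- factor(rep(c("a", "b"), c(35, 45)))
  x <- factor(rep(c("p", "q", "p", "q"), c(10, 25, 30, 15)))
  fit <- fit_baseline_multinomial(y, data.frame(x = x))
  tab <- wald_or_ci(fit)
  expect_equal(tab$ci_lo * tab$ci_hi, tab$or^2, tolerance = 1e-9)

  # beta = 0 -> OR 1 with symmetric interval
  fit0 <- fit_baseline_multinomial(factor(rep(c("a", "b"), 50)))
  t0 <- wald_or_ci(fit0)
  expect_equal(t0$or, 1, tolerance = 1e-8)
})

test_that("the reciprocal rule matches the in-text reinterpretations", {
  expect_equal(reciprocal_or(0.36), 2.78)
  expect_equal(reciprocal_or(0.18), 5.56)
  expect_equal(reciprocal_or(0.27), 3.70)
  expect_equal(reciprocal_or(0.29), 3.45)
  expect_equal(reciprocal_or(1.00), 1.00)
  expect_error(reciprocal_or(0), "positive")
  # involution up to rounding
  for (v in c(0.2, 0.36, 0.5, 0.75, 2, 5)) {
    expect_equal(reciprocal_or(reciprocal_or(v)), v, tolerance = 0.02)
  }
})

test_that("stepwise selection keeps informative predictors and drops noise", {
  set.seed(32)
  n <- 1000
  x1 <- factor(sample(1:3, n, TRUE))
  x2 <- factor(sample(1:3, n, TRUE))                 # pure noise
  lp2 <- 1.4 * (x1 == "2"); lp3 <- 1.8 * (x1 == "3")
  pr <- cbind(1, exp(lp2), exp(lp3)); pr <- pr / rowSums(pr)
  y <- factor(vapply(seq_len(n), function(i)
    sample(1:3, 1, prob = pr[i, ]), integer(1)))
  sel <- stepwise_select(y, data.frame(x1 = x1, x2 = x2))
  expect_identical(sel$selected, "x1")
  expect_true(all(sel$trace$action[sel$trace$predictor == "x1"] == "add"))

  # no informative candidate -> empty selection
  sel0 <- stepwise_select(y, data.frame(x2 = x2))
  expect_length(sel0$selected, 0)

  # redundant collinear copy of x1 is not added on top of x1
  sel2 <- stepwise_select(y, data.frame(x1 = x1, x1copy = x1))
  expect_length(sel2$selected, 1)
})

test_that("accuracy beats the null baseline when outcomes are predictable", {
  set.seed(34)
  n <- 600
  x <- factor(sample(1:3, n, TRUE))
  flip <- runif(n) < 0.25
  y <- factor(ifelse(flip, sample(1:3, n, TRUE), as.integer(x)))
  fit <- fit_baseline_multinomial(y, data.frame(x = x))
  null_share <- 100 * max(table(y)) / n
  expect_gt(correctly_predicted_pct(fit), null_share)

  # deterministic labels: perfect prediction
  yd <- factor(c(rep("a", 30), rep("b", 30)))
  xd <- factor(c(rep("p", 30), rep("q", 30)))
  # exact separation is refused rather than silently blown up
  expect_error(fit_baseline_multinomial(yd, data.frame(x = xd)),
               "separation")
})

test_that("changing the reference category preserves log-OR transitivity", {
  set.seed(35)
  n <- 400
  x <- factor(sample(1:2, n, TRUE))
  y <- factor(sample(1:3, n, TRUE, prob = c(0.3, 0.4, 0.3)))
  f1 <- fit_baseline_multinomial(y, data.frame(x = x), reference = "1")
  f2 <- fit_baseline_multinomial(y, data.frame(x = x), reference = "2")
  term <- setdiff(colnames(f1$coef), "(intercept)")
  # beta(3 vs 1) = beta(3 vs 2) + beta(2 vs 1)
  expect_equal(f1$coef["3", term],
               f2$coef["3", term] + f1$coef["2", term], tolerance = 1e-6)
})

test_that("Pearson matrix uses listwise deletion and reports the score r^2", {
  set.seed(36)
  z <- rnorm(200)
  a <- z + rnorm(200); b <- z + rnorm(200)
  v <- data.frame(a = a, b = b)
  v$a[1:5] <- NA
  cm <- pearson_matrix(v, score_pair = c("a", "b"))
  expect_equal(cm$n, 195)
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$r, t(cm$r))

  # printed arithmetic: r = 0.56 -> r^2 = 0.31 at 2 dp
  expect_equal(round_half_up(0.56^2, 2), 0.31)

  # two vectors correlated at ~0.56 report r^2 0.31
  set.seed(37)
  u <- rnorm(5000); w <- 0.56 * u + sqrt(1 - 0.56^2) * rnorm(5000)
  cm2 <- pearson_matrix(data.frame(u = u, w = w), score_pair = c("u", "w"))
  expect_equal(cm2$score_r, 0.56, tolerance = 0.05)

  # independent vectors: |r| small
  cm3 <- pearson_matrix(data.frame(p = rnorm(10000), q = rnorm(10000)))
  expect_lt(abs(cm3$r[1, 2]), 0.05)

  expect_error(pearson_matrix(data.frame(a = 1:2, b = 2:3)[1:2, ][-c(1, 2), ]),
               "3 complete")
  expect_warning(pearson_matrix(data.frame(a = rep(1, 10), b = rnorm(10))),
                 "zero-variance")
})
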