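test_that("SSCP decomposition conserves the total matrix and matches the reference", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    x <- matrix(rnorm(n * 5), n, 5)
    g <- sample(1:3, n, TRUE)
    mv <- manova_one_way(x, g)
    ref <- stats::manova(x ~ factor(g))
    for (s in c("Pillai", "Wilks", "Hotelling-Lawley", "Roy")) {
      rs <- summary(ref, test = s)$stats[1, ]
      expect_equal(unname(mv$table[s, 1:4]),
                   unname(rs[2:5]), tolerance = 1e-8)
      expect_equal(unname(mv$table[s, "p_value"]), unname(rs[6]),
                   tolerance = 1e-8)
    }
  }
})

test_that("permuted labels give a near-null MANOVA and Wilks is affine invariant", {
  set.seed(15)
  x <- matrix(rnorm(90 * 5), 90, 5)
  g <- rep(1:3, each = 30)
  mv <- manova_one_way(x, g)                 # labels independent of data
  expect_gt(mv$table["Wilks", "statistic"], 0.7)
  expect_gt(mv$table["Wilks", "p_value"], 0.01)

  mv2 <- manova_one_way(x * 3.7 + 2, g)      # joint affine rescale
  expect_equal(mv$table["Wilks", "statistic"],
               mv2$table["Wilks", "statistic"], tolerance = 1e-10)

  # partial eta^2 convention: 1 - lambda^(1/s)
  s <- min(5, 2)
  expect_equal(mv$partial_eta_sq,
               1 - mv$table["Wilks", "statistic"]^(1 / s),
               ignore_attr = TRUE)
})

test_that("two-cluster Hotelling trace matches the two-sample T^2 closed form", {
  set.seed(16)
  x <- rbind(matrix(rnorm(25 * 3, 0), 25, 3),
             matrix(rnorm(20 * 3, 0.8), 20, 3))
  g <- rep(1:2, c(25, 20))
  mv <- manova_one_way(x, g)
  n1 <- 25; n2 <- 20; n <- n1 + n2
  d <- colMeans(x[g == 1, ]) - colMeans(x[g == 2, ])
  S <- (24 * cov(x[g == 1, ]) + 19 * cov(x[g == 2, ])) / (n - 2)
  t2 <- (n1 * n2 / n) * drop(t(d) %*% solve(S, d))
  expect_equal(mv$table["Hotelling-Lawley", "statistic"], t2 / (n - 2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("per-sample Tukey tests match the reference and encode letters correctly", {
  set.seed(17)
  x <- matrix(rnorm(60 * 5, rep(c(0, 1, 4), each = 20)), 60, 5)
  colnames(x) <- c("A", "B", "C", "D", "E")
  g <- rep(1:3, each = 20)
  tk <- tukey_hsd_per_sample(x, g)
  for (s in colnames(x)) {
    ref <- stats::TukeyHSD(stats::aov(x[, s] ~ factor(g)))$`factor(g)`
    mine <- tk$pairs[tk$pairs$sample == s, ]
    key <- paste(mine$cluster_b, mine$cluster_a, sep = "-")
    expect_equal(mine$p_value, unname(ref[key, "p adj"]), tolerance = 1e-9)
  }

  # identical groups: one shared letter
  x0 <- matrix(rep(rnorm(20), 3), 60, 1, dimnames = list(NULL, "A"))
  g0 <- rep(1:3, each = 20)
  tk0 <- tukey_hsd_per_sample(matrix(rnorm(60, 5, 1), 60, 1,
                                     dimnames = list(NULL, "A")), g0)
  if (!any(tk0$pairs$significant)) {
    expect_equal(unname(tk0$letters[, 1]), c("a", "a", "a"))
  }

  # strong separation of the third group only: "a a b"
  y <- c(rnorm(30, 0), rnorm(30, 0.1), rnorm(30, 50))
  tks <- tukey_hsd_per_sample(matrix(y, ncol = 1,
                                     dimnames = list(NULL, "A")),
                              rep(1:3, each = 30))
  expect_equal(unname(tks$letters[, 1]), c("a", "a", "b"))

  expect_error(tukey_hsd_per_sample(matrix(rnorm(4), 4, 1),
                                    c(1, 1, 2, 3)), "size 1")
})

test_that("compact letters reproduce any pairwise significance relation", {
  mk <- function(pairs, k = 3) {
    s <- matrix(FALSE, k, k)
    for (p in pairs) { s[p[1], p[2]] <- TRUE; s[p[2], p[1]] <- TRUE }
    s
  }
  expect_equal(compact_letters(mk(list())), c("a", "a", "a"))
  expect_equal(compact_letters(mk(list(c(1, 2), c(1, 3), c(2, 3)))),
               c("a", "b", "c"))
  expect_equal(compact_letters(mk(list(c(1, 3)))), c("a", "ab", "b"))

  # round-trip property: shared letter <=> non-significant pair
  set.seed(18)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    sig <- matrix(FALSE, k, k)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      sig[a, b] <- sig[b, a] <- runif(1) < 0.4
    }
    lets <- compact_letters(sig)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      shared <- length(intersect(strsplit(lets[a], "")[[1]],
                                 strsplit(lets[b], "")[[1]])) > 0
      expect_identical(shared, !sig[a, b])
    }
  }
})

test_that("cluster summaries reconcile with the size-weighted overall mean", {
  expect_equal(round(weighted_overall_mean(c(6.21, 8.63, 8.18),
                                           c(91, 62, 44)), 2), 7.41)
  expect_equal(round(weighted_overall_mean(c(3.99, 6.32, 8.78),
                                           c(81, 96, 21)), 2), 5.63)
  expect_equal(weighted_overall_mean(c(4, 4, 4), c(3, 9, 2)), 4)
  expect_error(weighted_overall_mean(c(1, 2), c(1, 2, 3)), "length")

  set.seed(19)
  x <- matrix(rnorm(50 * 5, 5), 50, 5,
              dimnames = list(NULL, c("A", "B", "C", "D", "E")))
  g <- sample(1:3, 50, TRUE)
  sm <- summarize_clusters(x, g)
  for (s in c("A", "C", "E")) {
    cl <- sm$stats[sm$stats$sample == s & sm$stats$cluster != "all", ]
    all_row <- sm$stats[sm$stats$sample == s & sm$stats$cluster == "all", ]
    expect_equal(weighted_overall_mean(cl$mean, cl$n), all_row$mean,
                 tolerance = 1e-12)
  }
  # two identical values: zero SD, zero-width CI
  x2 <- matrix(c(2, 2, 5, 6), 4, 1, dimnames = list(NULL, "A"))
  sm2 <- summarize_clusters(x2, c(1, 1, 2, 2))
  r <- sm2$stats[sm2$stats$cluster == "1", ]
  expect_equal(r$sd, 0)
  expect_equal(r$ci_lo, r$ci_hi)
  # singleton cluster: CI undefined
  sm3 <- summarize_clusters(x2, c(1, 1, 1, 2))
  expect_true(is.na(sm3$stats[sm3$stats$cluster == "2", "ci_lo"]))
})

test_that("cohorts from the published profiles reproduce printed patterns stochastically", {
  cfg <- generator_config(seed = 23)
  coh <- generate_cohort(cfg)
  tab <- exclude_incomplete_subjects(drop_zero_sample(coh$ratings),
                                     "astringency")
  x <- to_intensity_matrix(tab, "astringency")
  truth <- coh$truth[coh$truth$modality == "astringency", ]
  g <- truth$latent_cluster[match(rownames(x), truth$subject_id)]

  # summary means close to the generating profile means
  sm <- summarize_clusters(x, g)
  prof <- chem_cluster_profiles()$astringency
  for (k in 1:3) {
    rows <- sm$stats[sm$stats$cluster == as.character(k), ]
    se <- prof[[k]]$sds / sqrt(prof[[k]]$size)
    expect_true(all(abs(rows$mean - prof[[k]]$means) < 3 * se + 0.15))
  }

  # sample E letters: cluster 1 differs from 2 and 3; 2 vs 3 n.s.
  tk <- tukey_hsd_per_sample(x, g)
  expect_equal(unname(tk$letters[, "E"]), c("a", "b", "b"))

  # MANOVA strongly rejects with a large effect, as printed
  mv <- manova_one_way(x, g)
  expect_lt(mv$table["Wilks", "p_value"], 0.001)
  expect_gt(mv$partial_eta_sq, 0.4)
})
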