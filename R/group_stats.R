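#' One-way MANOVA across sensitivity clusters
#'
#' Tests whether the five-sample intensity profile differs across clusters.
#' Between- and within-group SSCP matrices are formed directly; Wilks'
#' lambda is `det(W) / det(W + B)` and Pillai's trace, Hotelling's trace
#' and Roy's largest root are computed from the eigenvalues of `W^-1 B`,
#' with the conventional F approximations (Rao's for Wilks; Roy's F is an
#' upper bound). The multivariate partial eta squared is reported as
#' `1 - lambda^(1/s)` with `s = min(g - 1, p)`. A Box's M test of
#' covariance homogeneity is attached as a diagnostic and triggers a
#' warning (only) when significant.
#'
#' @param matrix N x p intensity matrix
#' @param solution a `chem_cluster_solution` (or an integer label vector)
#' @return object of class `chem_manova`: per-statistic value, approximate
#'   F, degrees of freedom and p-value, plus `partial_eta_sq`, `eig`,
#'   `box_m`
#' @export
manova_one_way <- function(matrix, solution) {
  x <- as.matrix(matrix)
  g <- if (inherits(solution, "chem_cluster_solution"))
    solution$assignments else as.integer(solution)
  stopifnot(length(g) == nrow(x))
  groups <- sort(unique(g))
  k <- length(groups)
  if (k < 2) stop("need at least two clusters")
  n <- nrow(x); p <- ncol(x)
  sizes <- vapply(groups, function(gr) sum(g == gr), integer(1))
  if (any(sizes <= p))
    warning("cluster(s) with n <= p; MANOVA statistics may be unstable")

  grand <- colMeans(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (gr in groups) {
    xg <- x[g == gr, , drop = FALSE]
    mg <- colMeans(xg)
    W <- W + crossprod(sweep(xg, 2, mg))
    B <- B + nrow(xg) * tcrossprod(mg - grand)
  }
  if (abs(det(W)) < 1e-300)
    stop("within-cluster SSCP matrix is singular")

  eig <- sort(Re(eigen(solve(W, B), only.values = TRUE)$values),
              decreasing = TRUE)
  eig[eig < 0] <- 0
  q <- k - 1          # hypothesis df
  df_res <- n - k
  s <- min(p, q)

  stats_tab <- rbind(
    Pillai = manova_pillai(eig, q, df_res),
    Wilks = manova_wilks(eig, q, df_res),
    `Hotelling-Lawley` = manova_hotelling(eig, q, df_res),
    Roy = manova_roy(eig, q, df_res))
  colnames(stats_tab) <- c("statistic", "approx_F", "df1", "df2")
  pvals <- stats::pf(stats_tab[, "approx_F"], stats_tab[, "df1"],
                     stats_tab[, "df2"], lower.tail = FALSE)
  lambda <- stats_tab["Wilks", "statistic"]

  structure(list(
    modality = if (inherits(solution, "chem_cluster_solution"))
      solution$modality else NA_character_,
    table = cbind(stats_tab, p_value = pvals),
    partial_eta_sq = 1 - lambda^(1 / s),
    eig = eig, n = n, p = p, n_clusters = k,
    box_m = box_m_test(x, g)),
    class = "chem_manova")
}

# standard multivariate F approximations from the eigenvalues of W^-1 B
manova_pillai <- function(eig, q, df_res) {
  v <- sum(eig / (1 + eig))
  p <- length(eig); s <- min(p, q)
  m <- 0.5 * (abs(p - q) - 1); nn <- 0.5 * (df_res - p - 1)
  t1 <- 2 * m + s + 1; t2 <- 2 * nn + s + 1
  c(v, (t2 / t1 * v) / (s - v), s * t1, s * t2)
}
manova_wilks <- function(eig, q, df_res) {
  lambda <- prod(1 / (1 + eig))
  p <- length(eig)
  t1 <- df_res - 0.5 * (p - q + 1)
  t2 <- (p * q - 2) / 4
  t3 <- p^2 + q^2 - 5
  t3 <- if (t3 > 0) sqrt(((p * q)^2 - 4) / t3) else 1
  f <- ((lambda^(-1 / t3) - 1) * (t1 * t3 - 2 * t2)) / (p * q)
  c(lambda, f, p * q, t1 * t3 - 2 * t2)
}
manova_hotelling <- function(eig, q, df_res) {
  tt <- sum(eig)
  p <- length(eig); s <- min(p, q)
  m <- 0.5 * (abs(p - q) - 1); nn <- 0.5 * (df_res - p - 1)
  t1 <- 2 * m + s + 1; t2 <- 2 * (s * nn + 1)
  c(tt, (t2 * tt) / s / s / t1, s * t1, t2)
}
manova_roy <- function(eig, q, df_res) {
  p <- length(eig)
  r <- max(p, q)
  df2 <- df_res - r + q
  c(max(eig), (df2 * max(eig)) / r, r, df2)
}

box_m_test <- function(x, g) {
  groups <- sort(unique(g))
  p <- ncol(x)
  sizes <- vapply(groups, function(gr) sum(g == gr), integer(1))
  if (any(sizes <= p)) return(NULL)
  n <- nrow(x); k <- length(groups)
  covs <- lapply(groups, function(gr) stats::cov(x[g == gr, , drop = FALSE]))
  sp <- Reduce(`+`, Map(function(S, ni) (ni - 1) * S, covs, sizes)) / (n - k)
  logdets <- vapply(covs, function(S) determinant(S)$modulus, numeric(1))
  m_stat <- (n - k) * determinant(sp)$modulus -
    sum((sizes - 1) * logdets)
  c1 <- (sum(1 / (sizes - 1)) - 1 / (n - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi <- as.numeric(m_stat * (1 - c1))
  df <- p * (p + 1) * (k - 1) / 2
  pv <- stats::pchisq(chi, df, lower.tail = FALSE)
  if (!is.na(pv) && pv <= 0.05)
    warning("Box's M indicates heterogeneous covariances (p = ",
            format_p(pv), "); MANOVA statistics reported regardless")
  list(statistic = chi, df = df, p_value = pv)
}

#' Report-style p-value formatting with a floor at 0.001
#' @param p p-value(s)
#' @return character
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Per-concentration Tukey HSD between clusters
#'
#' For each of the five samples, runs all pairwise cluster comparisons with
#' the studentized-range (Tukey-Kramer for unequal sizes) test at the given
#' alpha, using the one-way ANOVA within-cluster mean square of that sample,
#' and summarizes each sample's pattern as a compact letter display
#' (clusters sharing a letter do not differ significantly).
#'
#' @param matrix N x 5 intensity matrix
#' @param solution `chem_cluster_solution` or label vector
#' @param alpha significance level (default 0.05)
#' @return object of class `chem_tukey`: list with `pairs` (long data.frame
#'   of sample, pair, difference, q, p, significant) and `letters`
#'   (k x 5 character matrix)
#' @export
tukey_hsd_per_sample <- function(matrix, solution, alpha = 0.05) {
  x <- as.matrix(matrix)
  g <- if (inherits(solution, "chem_cluster_solution"))
    solution$assignments else as.integer(solution)
  groups <- sort(unique(g))
  k <- length(groups)
  if (k < 2) stop("need at least two clusters")
  sizes <- vapply(groups, function(gr) sum(g == gr), integer(1))
  if (any(sizes < 2)) stop("cluster of size 1: no within-cluster variance")
  n <- nrow(x)
  df_w <- n - k
  combs <- utils::combn(k, 2)

  pairs <- list()
  letters_mat <- matrix("", k, ncol(x),
                        dimnames = list(paste0("cluster", groups),
                                        colnames(x)))
  for (s in seq_len(ncol(x))) {
    y <- x[, s]
    means <- vapply(groups, function(gr) mean(y[g == gr]), numeric(1))
    ss_w <- sum(vapply(groups, function(gr) {
      yy <- y[g == gr]; sum((yy - mean(yy))^2)
    }, numeric(1)))
    mse <- ss_w / df_w
    sig <- matrix(FALSE, k, k)
    for (cidx in seq_len(ncol(combs))) {
      i <- combs[1, cidx]; j <- combs[2, cidx]
      se <- sqrt(mse / 2 * (1 / sizes[i] + 1 / sizes[j]))
      qstat <- abs(means[i] - means[j]) / se
      pv <- stats::ptukey(qstat, k, df_w, lower.tail = FALSE)
      sig[i, j] <- sig[j, i] <- (pv <= alpha)
      pairs[[length(pairs) + 1L]] <- data.frame(
        sample = colnames(x)[s],
        cluster_a = groups[i], cluster_b = groups[j],
        difference = means[i] - means[j],
        q = qstat, p_value = pv, significant = pv <= alpha,
        stringsAsFactors = FALSE)
    }
    letters_mat[, s] <- compact_letters(sig)
  }
  structure(list(pairs = do.call(rbind, pairs), letters = letters_mat,
                 alpha = alpha),
            class = "chem_tukey")
}

#' Compact letter display from a pairwise significance relation
#'
#' Insertion-absorption algorithm: groups sharing a letter are exactly the
#' pairs that are not significantly different.
#'
#' @param sig symmetric logical matrix, `TRUE` = significantly different
#' @return character vector of letter strings, one per group
#' @export
compact_letters <- function(sig) {
  k <- nrow(sig)
  stopifnot(isTRUE(all.equal(sig, t(sig))))
  cols <- list(seq_len(k))          # letter columns = sets of groups
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      cc <- cols[[ci]]
      if (all(c(i, j) %in% cc)) {
        cols[[ci]] <- setdiff(cc, i)
        cols[[length(cols) + 1L]] <- setdiff(cc, j)
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b)) keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  out <- vapply(seq_len(k), function(gr)
    paste0(letters[which(vapply(cols, function(cc) gr %in% cc, logical(1)))],
           collapse = ""),
    character(1))
  out
}

#' Cluster summary in report layout
#'
#' Per cluster and sample: mean, sample SD (n-1) and 95% t confidence
#' interval for the mean; plus the overall (all clusters pooled) column and
#' the n (%) row. A cluster of one subject gets an undefined CI (NA).
#'
#' @param matrix N x 5 intensity matrix
#' @param solution `chem_cluster_solution` or label vector
#' @return object of class `chem_cluster_summary`: long data.frame
#'   `stats` (cluster, sample, n, mean, sd, ci_lo, ci_hi; cluster "all" =
#'   pooled) and `sizes` with percentages
#' @export
summarize_clusters <- function(matrix, solution) {
  x <- as.matrix(matrix)
  g <- if (inherits(solution, "chem_cluster_solution"))
    solution$assignments else as.integer(solution)
  groups <- sort(unique(g))
  cell <- function(y) {
    n <- length(y); m <- mean(y); s <- if (n > 1) sd(y) else NA_real_
    half <- if (n > 1) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    c(n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
  }
  rows <- list()
  for (gr in c(as.list(groups), list("all"))) {
    sel <- if (identical(gr, "all")) rep(TRUE, nrow(x)) else g == gr
    for (s in seq_len(ncol(x))) {
      st <- cell(x[sel, s])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = as.character(gr), sample = colnames(x)[s],
        n = st["n"], mean = st["mean"], sd = st["sd"],
        ci_lo = st["ci_lo"], ci_hi = st["ci_hi"],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  sizes <- vapply(groups, function(gr) sum(g == gr), integer(1))
  structure(list(
    stats = do.call(rbind, rows),
    sizes = data.frame(cluster = as.character(groups), n = sizes,
                       pct = 100 * sizes / sum(sizes),
                       stringsAsFactors = FALSE)),
    class = "chem_cluster_summary")
}

#' Size-weighted overall mean
#'
#' Pools per-cluster means into the all-subjects mean:
#' `sum(n_i * m_i) / sum(n_i)`.
#'
#' @param means per-cluster means
#' @param sizes per-cluster sizes
#' @return the weighted mean
#' @export
weighted_overall_mean <- function(means, sizes) {
  if (length(means) != length(sizes)) stop("means and sizes differ in length")
  if (any(sizes <= 0)) stop("sizes must be positive")
  sum(sizes * means) / sum(sizes)
}
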