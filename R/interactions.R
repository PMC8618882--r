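#' Dummy-code a categorical predictor against its largest level
#'
#' Mirrors the convention used for the dependent side: every sensitivity
#' factor is coded with its largest cluster as the reference.
#'
#' @param f factor (or vector coercible to factor)
#' @param name column-name prefix
#' @return list with `X` (n x (levels-1) indicator matrix) and `reference`
#' @keywords internal
dummy_code_largest_ref <- function(f, name) {
  f <- as.factor(f)
  tab <- table(f)
  ref <- names(tab)[which.max(tab)]   # ties: first level, deterministic
  keep <- setdiff(levels(f), ref)
  X <- vapply(keep, function(l) as.numeric(f == l), numeric(length(f)))
  X <- matrix(X, nrow = length(f),
              dimnames = list(NULL, paste0(name, keep)))
  list(X = X, reference = ref, levels = keep)
}

#' Baseline-category multinomial logistic regression
#'
#' Maximum-likelihood fit of the baseline-category logit by Newton-Raphson
#' on the multinomial log-likelihood: for outcome categories
#' `j != reference`, `log(P(y = j) / P(y = ref)) = x' beta_j`. Categorical
#' predictors are dummy-coded against their own largest level. Convergence
#' when the log-likelihood changes by less than 1e-8 (at most 200
#' iterations); if the Newton step diverges a small ridge (1e-6) is added
#' and flagged. Unbounded coefficient growth raises a complete-separation
#' error naming the offending term.
#'
#' @param outcome factor of outcome labels
#' @param predictors data.frame of categorical predictors (may have zero
#'   columns for the intercept-only model)
#' @param reference outcome reference category; default the largest class
#' @return object of class `chem_multinom`: `coef` ((J-1) x p matrix),
#'   `se`, `vcov`, `loglik`, `fitted` (n x J probabilities),
#'   `outcome_levels`, `reference`, `predictor_refs`, `converged`, `ridged`
#' @export
fit_baseline_multinomial <- function(outcome, predictors = NULL,
                                     reference = NULL) {
  y <- as.factor(outcome)
  if (nlevels(y) < 2) stop("outcome needs at least two categories")
  if (is.null(reference)) {
    tab <- table(y)
    reference <- names(tab)[which.max(tab)]
  }
  lev <- c(reference, setdiff(levels(y), reference))
  y <- factor(y, levels = lev)
  n <- length(y)
  J <- nlevels(y)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  predictor_refs <- list()
  if (!is.null(predictors) && ncol(as.data.frame(predictors)) > 0) {
    predictors <- as.data.frame(predictors)
    for (nm in names(predictors)) {
      tab <- table(predictors[[nm]], y)
      if (nrow(tab) > 1 && all(rowSums(tab > 0) == 1))
        stop("complete separation on predictor '", nm,
             "': every level determines the outcome")
      dc <- dummy_code_largest_ref(predictors[[nm]], paste0(nm, "."))
      predictor_refs[[nm]] <- dc$reference
      X <- cbind(X, dc$X)
    }
  }
  p <- ncol(X)
  Y <- vapply(lev[-1], function(l) as.numeric(y == l), numeric(n))

  # empty outcome x predictor-level cells: proceed, but bound the drifting
  # coefficients (quasi-separation) instead of failing
  any_empty <- FALSE
  if (p > 1) {
    for (cc in 2:p) {
      if (any(tapply(X[, cc], y, sum) == 0) && any(X[, cc] > 0)) {
        any_empty <- TRUE
        warning("empty outcome cell for term '", colnames(X)[cc],
                "'; estimates for it are unstable")
      }
    }
  }

  B <- matrix(0, p, J - 1)
  ll_old <- -Inf
  ridged <- FALSE
  converged <- FALSE
  for (it in seq_len(200L)) {
    eta <- X %*% B
    eta <- pmin(pmax(eta, -500), 500)
    expeta <- exp(eta)
    denom <- 1 + rowSums(expeta)
    P <- expeta / denom                       # n x (J-1)
    ll <- sum(Y * eta) - sum(log(denom))
    grad <- as.vector(crossprod(X, Y - P))
    info <- matrix(0, p * (J - 1), p * (J - 1))
    for (j in seq_len(J - 1)) for (k in seq_len(j)) {
      wjk <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
      blk <- crossprod(X, X * wjk)
      ri <- (j - 1) * p + seq_len(p); ci <- (k - 1) * p + seq_len(p)
      info[ri, ci] <- blk
      info[ci, ri] <- t(blk)
    }
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) {
      ridged <- TRUE
      step <- solve(info + diag(1e-6, nrow(info)), grad)
    }
    B_new <- B + matrix(step, p, J - 1)
    if (max(abs(B_new)) > 30) {
      if (any_empty) {
        B_new <- pmin(pmax(B_new, -30), 30)
        ridged <- TRUE
      } else {
        worst <- which.max(abs(B_new)) %% p
        worst <- if (worst == 0) p else worst
        stop("complete (or quasi-complete) separation detected for term '",
             colnames(X)[worst], "'")
      }
    }
    if (is.finite(ll) && abs(ll - ll_old) < 1e-8) { converged <- TRUE; break }
    ll_old <- ll
    B <- B_new
  }
  eta <- pmin(pmax(X %*% B, -500), 500)
  expeta <- exp(eta)
  denom <- 1 + rowSums(expeta)
  fitted <- cbind(1 / denom, expeta / denom)
  colnames(fitted) <- lev
  ll <- sum(Y * eta) - sum(log(denom))

  vc <- {
    P <- expeta / denom
    info <- matrix(0, p * (J - 1), p * (J - 1))
    for (j in seq_len(J - 1)) for (k in seq_len(j)) {
      wjk <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
      blk <- crossprod(X, X * wjk)
      ri <- (j - 1) * p + seq_len(p); ci <- (k - 1) * p + seq_len(p)
      info[ri, ci] <- blk
      info[ci, ri] <- t(blk)
    }
    tryCatch(solve(info), error = function(e) {
      solve(info + diag(1e-6, nrow(info)))
    })
  }
  se <- matrix(sqrt(pmax(diag(vc), 0)), p, J - 1)

  coef <- t(B)                      # (J-1) x p: one row per non-ref outcome
  se <- t(se)
  dimnames(coef) <- dimnames(se) <- list(lev[-1], colnames(X))
  structure(list(coef = coef, se = se, vcov = vc, loglik = ll,
                 fitted = fitted, outcome = y, outcome_levels = lev,
                 reference = reference, predictor_refs = predictor_refs,
                 n = n, df = p * (J - 1),
                 converged = converged, ridged = ridged),
            class = "chem_multinom")
}

#' Wald odds ratios with confidence intervals
#'
#' `OR = exp(beta)` with `CI = exp(beta +/- z * SE)` and significance stars
#' (* p <= 0.05, ** p <= 0.01, *** p <= 0.001) from the Wald z test.
#'
#' @param fit a `chem_multinom`
#' @param level confidence level (default 0.95)
#' @return data.frame: outcome (dependent factor level), term, estimate
#'   (log-odds), se, or, ci_lo, ci_hi, p_value, stars
#' @export
wald_or_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "chem_multinom"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(rownames(fit$coef), function(oc) {
    b <- fit$coef[oc, , drop = TRUE]; s <- fit$se[oc, , drop = TRUE]
    zstat <- b / s
    pv <- 2 * stats::pnorm(-abs(zstat))
    data.frame(outcome = oc, term = colnames(fit$coef), estimate = unname(b),
               se = unname(s), or = exp(unname(b)),
               ci_lo = exp(unname(b - z * s)), ci_hi = exp(unname(b + z * s)),
               p_value = unname(pv), stars = significance_stars(pv),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "")))
}

#' Reciprocal odds-ratio reinterpretation
#'
#' An OR below 1 for "dependent vs reference" is re-expressed as the factor
#' belonging `1/OR` times more likely to the reference group; the value is
#' reported rounded half-up to two decimals.
#'
#' @param or_value positive odds ratio(s)
#' @return reciprocal OR, rounded to 2 decimals
#' @export
reciprocal_or <- function(or_value) {
  if (any(or_value <= 0)) stop("odds ratios must be positive")
  round_half_up(1 / or_value, 2L)
}

#' Forward-backward stepwise predictor selection
#'
#' Forward phase: among candidates not in the model, add the one with the
#' smallest likelihood-ratio p-value, if at or below the criterion.
#' Backward phase: drop any retained predictor whose likelihood-ratio
#' p-value (vs the model without it) has risen above the criterion.
#' Repeats to a fixed point (at most 50 steps). The likelihood-ratio
#' chi-square is used for selection; Wald tests only star individual
#' coefficients.
#'
#' @param outcome factor of outcome labels
#' @param candidates data.frame of candidate categorical predictors
#' @param criterion significance criterion (default 0.05)
#' @param reference outcome reference category (default largest class)
#' @return list with `fit` (final `chem_multinom`), `selected` (character),
#'   `trace` (data.frame step, action, predictor, p_value)
#' @export
stepwise_select <- function(outcome, candidates, criterion = 0.05,
                            reference = NULL) {
  candidates <- as.data.frame(candidates)
  current <- character(0)
  trace <- list()
  fit_with <- function(terms) {
    preds <- if (length(terms)) candidates[, terms, drop = FALSE] else NULL
    fit_baseline_multinomial(outcome, preds, reference)
  }
  lr_p <- function(full, reduced) {
    stat <- 2 * (full$loglik - reduced$loglik)
    df <- full$df - reduced$df
    if (df <= 0) return(1)
    stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
  }
  current_fit <- fit_with(current)
  for (step in seq_len(50L)) {
    changed <- FALSE
    # forward
    pool <- setdiff(names(candidates), current)
    if (length(pool)) {
      ps <- vapply(pool, function(tm) {
        lr_p(fit_with(c(current, tm)), current_fit)
      }, numeric(1))
      best <- which.min(ps)
      if (ps[best] <= criterion) {
        current <- c(current, pool[best])
        current_fit <- fit_with(current)
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "add", predictor = pool[best],
          p_value = ps[best], stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    # backward
    if (length(current)) {
      ps <- vapply(current, function(tm) {
        lr_p(current_fit, fit_with(setdiff(current, tm)))
      }, numeric(1))
      worst <- which.max(ps)
      if (length(ps) && ps[worst] > criterion) {
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "remove", predictor = current[worst],
          p_value = ps[worst], stringsAsFactors = FALSE)
        current <- setdiff(current, current[worst])
        current_fit <- fit_with(current)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(fit = current_fit, selected = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), action = character(0),
                    predictor = character(0), p_value = numeric(0)))
}

#' Correctly-predicted percentage
#'
#' Assigns each subject to the modal-probability outcome category of the
#' fit and reports the percentage matching the observed label.
#'
#' @param fit a `chem_multinom`
#' @param outcome observed labels (default: the labels the model was fit to)
#' @return percentage in `[0, 100]`
#' @export
correctly_predicted_pct <- function(fit, outcome = fit$outcome) {
  stopifnot(inherits(fit, "chem_multinom"))
  pred <- fit$outcome_levels[max.col(fit$fitted, ties.method = "first")]
  100 * mean(pred == as.character(outcome))
}

#' Pearson correlation matrix of sensitivity variables
#'
#' Product-moment correlations over the supplied block of variables with
#' listwise deletion (rows with any missing value are dropped). Cluster
#' labels are treated as numeric 1-3 scores. A zero-variance variable
#' yields NA correlations with a warning.
#'
#' @param variables data.frame of numeric variables (one column per
#'   modality / score)
#' @param score_pair optional character pair naming the two composite
#'   scores whose `r` and `r^2` are reported separately
#' @return object of class `chem_cormat`: `r` (matrix), `n` (complete
#'   cases), and when `score_pair` is given, `score_r` and `score_r2`
#'   (2 dp)
#' @export
pearson_matrix <- function(variables, score_pair = NULL) {
  v <- as.data.frame(variables)
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (nrow(v) < 3) stop("need at least 3 complete observations")
  sds <- vapply(v, stats::sd, numeric(1))
  if (any(sds == 0))
    warning("zero-variance variable(s): ",
            paste(names(v)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  r <- suppressWarnings(stats::cor(as.matrix(v)))
  out <- list(r = r, n = nrow(v))
  if (!is.null(score_pair)) {
    stopifnot(all(score_pair %in% colnames(r)))
    rr <- r[score_pair[1], score_pair[2]]
    out$score_r <- rr
    out$score_r2 <- round_half_up(rr^2, 2L)
  }
  structure(out, class = "chem_cormat")
}
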