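#' Round half up
#'
#' Two-decimal rounding with the half-up rule (`4/3 -> 1.33`,
#' `5/3 -> 1.67`), pinned for cross-platform determinism where `round()`'s
#' round-half-even could differ.
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

CSS_LATTICE <- c(1.00, 1.33, 1.67, 2.00, 2.33, 2.67, 3.00)
CSS_CATEGORIES <- c("Hyposensitive", "Semi-sensitive", "Hypersensitive")

#' Attainable values of a k-modality sensitivity score
#'
#' Enumerates, by brute force over all `3^k` label combinations, the values
#' the mean of `k` cluster labels (each 1, 2 or 3) can take, rounded to two
#' decimals. For the three chemesthetic modalities this is the seven-value
#' CSS lattice 1.00, 1.33, ..., 3.00; for five taste modalities the
#' eleven-value TSS lattice 1.0, 1.2, ..., 3.0.
#'
#' @param n_modalities number of modality labels averaged (default 3)
#' @return sorted numeric vector of attainable score values
#' @export
enumerate_lattice <- function(n_modalities = 3L) {
  grids <- rep(list(1:3), n_modalities)
  combos <- as.matrix(expand.grid(grids))
  sort(unique(round_half_up(rowMeans(combos), 2L)))
}

#' Categorize a sensitivity score
#'
#' Maps a lattice score to its sensitivity category: scores of 1.00 or 1.33
#' are Hyposensitive, 1.67 through 2.33 Semi-sensitive, 2.67 or 3.00
#' Hypersensitive. For taste scores (5 modalities) the boundaries are
#' configurable; the defaults place hypo below 1.4 and hyper above 2.4.
#'
#' @param score score value(s) on the lattice
#' @param n_modalities how many labels the score averages (3 = CSS, 5 = TSS)
#' @param hypo_max largest hyposensitive score (default 1.33 for CSS,
#'   1.4 for TSS)
#' @param semi_max largest semi-sensitive score (default 2.33 for CSS,
#'   2.4 for TSS)
#' @return factor with levels Hyposensitive, Semi-sensitive, Hypersensitive
#' @export
categorize <- function(score, n_modalities = 3L,
                       hypo_max = if (n_modalities == 3L) 1.33 else 1.4,
                       semi_max = if (n_modalities == 3L) 2.33 else 2.4) {
  lattice <- enumerate_lattice(n_modalities)
  ok <- vapply(score, function(s)
    is.na(s) || any(abs(lattice - s) < 1e-6), logical(1))
  if (!all(ok))
    stop("score value(s) not on the attainable lattice: ",
         paste(utils::head(score[!ok], 5), collapse = ", "))
  cat <- ifelse(is.na(score), NA_character_,
                ifelse(score <= hypo_max + 1e-9, CSS_CATEGORIES[1],
                       ifelse(score <= semi_max + 1e-9, CSS_CATEGORIES[2],
                              CSS_CATEGORIES[3])))
  factor(cat, levels = CSS_CATEGORIES)
}

#' Compute the composite sensitivity score (CSS / TSS)
#'
#' The Chemesthesis Sensitivity Score is the average of a subject's three
#' per-modality cluster labels (astringency, pungency, cooling), rounded to
#' two decimals; the Taste Sensitivity Score is the same operator over five
#' taste labels. Subjects missing any required label are skipped with a
#' warning (they stay in per-modality outputs but get no composite score).
#'
#' @param labels data.frame with a `subject_id` column and one integer
#'   label column (values 1-3) per modality
#' @param modalities which label columns to average (default the three
#'   chemesthetic modalities)
#' @return data.frame: subject_id, score (exact mean), score_group (lattice
#'   value, 2 dp), category
#' @export
compute_css <- function(labels, modalities = CHEM_MODALITIES) {
  miss_col <- setdiff(modalities, names(labels))
  if (length(miss_col))
    stop("label column(s) missing: ", paste(miss_col, collapse = ", "))
  lab <- as.matrix(labels[, modalities, drop = FALSE])
  if (any(!is.na(lab) & !(lab %in% 1:3)))
    stop("cluster labels must be 1, 2 or 3")
  complete <- rowSums(is.na(lab)) == 0L
  if (any(!complete))
    warning(sum(!complete), " subject(s) missing a modality label; skipped")
  score <- rowMeans(lab)
  out <- data.frame(subject_id = labels$subject_id,
                    score = ifelse(complete, score, NA_real_),
                    stringsAsFactors = FALSE)
  out$score_group <- round_half_up(out$score, 2L)
  out$category <- categorize(out$score_group, length(modalities))
  out[complete, , drop = FALSE]
}

#' Distribution of sensitivity scores
#'
#' Counts subjects per lattice score value and per sensitivity category.
#'
#' @param scores output of [compute_css()]
#' @param n_modalities lattice size selector (3 = CSS, 5 = TSS)
#' @return list with `by_group` (named integer vector over the lattice)
#'   and `by_category` (named integer vector over the three categories)
#' @export
css_distribution <- function(scores, n_modalities = 3L) {
  lattice <- enumerate_lattice(n_modalities)
  grp <- vapply(scores$score_group, function(s)
    which(abs(lattice - s) < 1e-6)[1], integer(1))
  by_group <- tabulate(grp, nbins = length(lattice))
  names(by_group) <- sprintf("%.2f", lattice)
  by_category <- table(factor(scores$category, levels = CSS_CATEGORIES))
  list(by_group = by_group,
       by_category = stats::setNames(as.integer(by_category),
                                     CSS_CATEGORIES))
}

#' Per-subject modality labels from cluster solutions
#'
#' Joins the assignments of several per-modality cluster solutions into the
#' wide label table [compute_css()] expects.
#'
#' @param solutions named list of `chem_cluster_solution` objects
#' @return data.frame: subject_id plus one label column per modality (NA
#'   where a subject was not clustered for that modality)
#' @export
collect_labels <- function(solutions) {
  ids <- sort(unique(unlist(lapply(solutions, function(s)
    names(s$assignments)))))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (m in names(solutions)) {
    a <- solutions[[m]]$assignments
    out[[m]] <- unname(a[match(ids, names(a))])
  }
  out
}
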