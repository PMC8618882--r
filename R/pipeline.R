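#' Run the full sensitivity analysis pipeline
#'
#' Orchestrates generate/read -> exclusion filtering -> Ward clustering ->
#' sensitivity scores -> MANOVA / Tukey summaries -> interaction models ->
#' correlation matrix, deterministically for a fixed input and seed.
#'
#' @param input a `chem_generator_config` (cohort is generated), a
#'   `chem_cohort`, a rating-table data.frame, or a path to a long-format
#'   rating CSV
#' @param k number of clusters per modality (default 3)
#' @param alpha significance level for post hocs and stepwise selection
#' @param modalities chemesthetic modalities to analyze
#' @return object of class `chem_run`: per-modality `solutions`, `manova`,
#'   `tukey`, `summary`; `labels`, `css`, `tss` (when taste present),
#'   `or_chem`, `or_taste_by_chem`, `or_chem_by_taste`, `correlation`,
#'   `manifest`
#' @export
run_pipeline <- function(input, k = 3L, alpha = 0.05,
                         modalities = CHEM_MODALITIES) {
  if (k < 2) stop("k must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")

  cohort <- NULL
  if (inherits(input, "chem_generator_config")) {
    cohort <- generate_cohort(input)
    ratings <- cohort$ratings
  } else if (inherits(input, "chem_cohort")) {
    cohort <- input
    ratings <- cohort$ratings
  } else if (is.character(input)) {
    ratings <- read_ratings_csv(input)
  } else if (is.data.frame(input)) {
    ratings <- validate_rating_table(input)
  } else stop("unsupported input type")

  present <- unique(ratings$modality)
  chem <- intersect(modalities, present)
  taste <- intersect(TASTE_MODALITIES, present)
  if (!length(chem)) stop("no chemesthetic modality found in the input")

  counts <- list(n_subjects = length(unique(ratings$subject_id)))
  stage <- function(tab, m) {
    tab <- exclude_incomplete_subjects(tab, m)
    tab
  }

  tab <- drop_zero_sample(ratings)
  solutions <- list(); manova <- list(); tukey <- list(); summaries <- list()
  for (m in c(chem, taste)) {
    tab_m <- stage(tab, m)
    x <- to_intensity_matrix(tab_m, m)
    counts[[paste0("n_", m)]] <- nrow(x)
    sol <- cluster_modality(x, k = k, modality = m)
    solutions[[m]] <- sol
    manova[[m]] <- manova_one_way(x, sol)
    tukey[[m]] <- tukey_hsd_per_sample(x, sol, alpha = alpha)
    summaries[[m]] <- summarize_clusters(x, sol)
  }

  labels <- collect_labels(solutions)
  css <- suppressWarnings(compute_css(labels, chem))
  counts$n_css <- nrow(css)
  tss <- NULL
  if (length(taste) == 5L) {
    tss <- suppressWarnings(compute_css(labels, taste))
    counts$n_tss <- nrow(tss)
  }

  # chemesthesis-chemesthesis interactions on CSS-complete subjects
  or_chem <- NULL
  if (length(chem) >= 2) {
    lab_c <- labels[stats::complete.cases(labels[, chem]), , drop = FALSE]
    or_chem <- do.call(rbind, lapply(chem, function(m) {
      sel <- stepwise_select(factor(lab_c[[m]]),
                             lab_c[setdiff(chem, m)], criterion = alpha)
      collect_or_rows(sel, modality = m)
    }))
  }

  or_chem_by_taste <- NULL
  or_taste_by_chem <- NULL
  cormat <- NULL
  if (length(taste) == 5L) {
    both <- labels[stats::complete.cases(labels[, c(chem, taste)]), ,
                   drop = FALSE]
    counts$n_both <- nrow(both)
    # chem outcome, taste modalities entered one at a time with the chem base
    or_chem_by_taste <- do.call(rbind, lapply(chem, function(m) {
      do.call(rbind, lapply(taste, function(tm) {
        sel <- stepwise_select(factor(both[[m]]),
                               both[c(setdiff(chem, m), tm)],
                               criterion = alpha)
        rows <- collect_or_rows(sel, modality = m)
        if (!is.null(rows) && nrow(rows))
          rows <- rows[grepl(paste0("^", tm, "\\."), rows$term), ,
                       drop = FALSE]
        if (!is.null(rows) && nrow(rows)) rows$taste_block <- tm
        rows
      }))
    }))
    # taste outcome, chem modalities entered one at a time
    or_taste_by_chem <- do.call(rbind, lapply(taste, function(tm) {
      do.call(rbind, lapply(chem, function(m) {
        sel <- stepwise_select(factor(both[[tm]]),
                               both[m], criterion = alpha)
        rows <- collect_or_rows(sel, modality = tm)
        if (!is.null(rows) && nrow(rows)) rows$chem_block <- m
        rows
      }))
    }))
    score_df <- data.frame(
      both[, c(chem, taste)],
      css = rowMeans(both[, chem]),
      tss = rowMeans(both[, taste]))
    cormat <- pearson_matrix(score_df, score_pair = c("css", "tss"))
  }

  manifest <- list(
    seed = if (!is.null(cohort)) cohort$config$seed else NA_integer_,
    k = k, alpha = alpha, counts = counts,
    modalities = list(chemesthesis = chem, taste = taste))

  structure(list(ratings = ratings, cohort = cohort,
                 solutions = solutions, manova = manova, tukey = tukey,
                 summaries = summaries, labels = labels,
                 css = css, tss = tss,
                 or_chem = or_chem,
                 or_chem_by_taste = or_chem_by_taste,
                 or_taste_by_chem = or_taste_by_chem,
                 correlation = cormat,
                 manifest = manifest),
            class = "chem_run")
}

# significant non-intercept OR rows of a stepwise fit, report layout
collect_or_rows <- function(sel, modality) {
  if (!length(sel$selected)) return(NULL)
  tab <- wald_or_ci(sel$fit)
  tab <- tab[tab$term != "(intercept)" & tab$p_value <= 0.05, , drop = FALSE]
  if (!nrow(tab)) return(NULL)
  data.frame(modality = modality,
             reference = sel$fit$reference,
             dependent = tab$outcome,
             term = tab$term,
             or = tab$or, ci_lo = tab$ci_lo, ci_hi = tab$ci_hi,
             p_value = tab$p_value, stars = tab$stars,
             reciprocal = ifelse(tab$or < 1, reciprocal_or(tab$or), NA_real_),
             correct_pct = correctly_predicted_pct(sel$fit),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write report artifacts for a pipeline run
#'
#' Emits diff-able CSVs (assignments, scores, per-modality summaries with
#' Tukey letters, MANOVA statistics, OR tables, correlation matrix), a CSS
#' histogram and a correlation heat map (PNG), and a JSON run manifest.
#'
#' @param run a `chem_run`
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest (with the file inventory added)
#' @export
render_reports <- function(run, dir) {
  stopifnot(inherits(run, "chem_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }

  asg <- do.call(rbind, lapply(names(run$solutions), function(m) {
    a <- run$solutions[[m]]$assignments
    data.frame(subject_id = names(a), modality = m, csg_label = unname(a),
               stringsAsFactors = FALSE)
  }))
  put(asg, "assignments.csv")
  put(run$css, "css_scores.csv")
  if (!is.null(run$tss)) put(run$tss, "tss_scores.csv")

  for (m in names(run$summaries)) {
    s <- run$summaries[[m]]$stats
    lets <- run$tukey[[m]]$letters
    s$letter <- ""
    is_cl <- s$cluster != "all"
    s$letter[is_cl] <- lets[cbind(as.integer(s$cluster[is_cl]),
                                  match(s$sample[is_cl], colnames(lets)))]
    put(s, paste0("summary_", m, ".csv"))
  }

  man <- do.call(rbind, lapply(names(run$manova), function(m) {
    tb <- as.data.frame(run$manova[[m]]$table)
    tb$statistic_name <- rownames(tb)
    tb$modality <- m
    tb$partial_eta_sq <- run$manova[[m]]$partial_eta_sq
    tb
  }))
  put(man, "manova.csv")

  empty_or <- data.frame(modality = character(0), reference = character(0),
                         dependent = character(0), term = character(0),
                         or = numeric(0), ci_lo = numeric(0),
                         ci_hi = numeric(0), p_value = numeric(0),
                         stars = character(0), reciprocal = numeric(0),
                         correct_pct = numeric(0))
  put(if (is.null(run$or_chem)) empty_or else run$or_chem, "or_chem.csv")
  if (!is.null(run$tss)) {
    put(if (is.null(run$or_chem_by_taste)) empty_or else
      run$or_chem_by_taste, "or_chem_by_taste.csv")
    put(if (is.null(run$or_taste_by_chem)) empty_or else
      run$or_taste_by_chem, "or_taste_by_chem.csv")
  }

  if (!is.null(run$correlation)) {
    r <- as.data.frame(run$correlation$r)
    r <- cbind(variable = rownames(r), r)
    put(r, "correlation.csv")
  }

  hist_path <- file.path(dir, "css_histogram.png")
  grDevices::png(hist_path, width = 800, height = 500)
  print(css_histogram(run$css))
  grDevices::dev.off()
  files <- c(files, hist_path)

  if (!is.null(run$correlation)) {
    heat_path <- file.path(dir, "correlation_heatmap.png")
    grDevices::png(heat_path, width = 700, height = 600)
    print(correlation_heatmap(run$correlation))
    grDevices::dev.off()
    files <- c(files, heat_path)
  }

  manifest <- run$manifest
  manifest$files <- basename(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Histogram of composite sensitivity scores over the lattice
#'
#' One bar per attainable lattice value, coloured by sensitivity category.
#'
#' @param scores output of [compute_css()]
#' @param n_modalities lattice selector (3 = CSS)
#' @return a ggplot object
#' @export
css_histogram <- function(scores, n_modalities = 3L) {
  lattice <- enumerate_lattice(n_modalities)
  counts <- css_distribution(scores, n_modalities)$by_group
  df <- data.frame(group = factor(sprintf("%.2f", lattice),
                                  levels = sprintf("%.2f", lattice)),
                   n = as.integer(counts),
                   category = categorize(lattice, n_modalities))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sensitivity score", y = "subjects",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' Correlation heat map
#'
#' @param cormat a `chem_cormat`
#' @return a ggplot object
#' @export
correlation_heatmap <- function(cormat) {
  r <- cormat$r
  df <- expand.grid(x = colnames(r), y = rev(rownames(r)),
                    stringsAsFactors = FALSE)
  df$r <- r[cbind(match(df$y, rownames(r)), match(df$x, colnames(r)))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
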