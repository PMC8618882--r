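#!/usr/bin/env Rscript
# Stage 2: exclusion filtering and Ward clustering per chemesthetic
# modality, with MANOVA and per-concentration Tukey letters.
#
# Expects results/cohort/ratings.csv from stage 1. Writes cluster
# assignments, a report-style per-cluster summary for each modality, and
# the MANOVA statistics table.

suppressPackageStartupMessages(library(chemsens))

ratings <- read_ratings_csv("results/cohort/ratings.csv")
tab <- drop_zero_sample(ratings)
modalities <- c("astringency", "pungency", "cooling",
                "sour", "sweet", "umami", "bitter", "salty")
modalities <- intersect(modalities, unique(tab$modality))

out <- "results"
asg_rows <- list()
manova_rows <- list()
for (m in modalities) {
  tm <- exclude_incomplete_subjects(tab, m)
  x <- to_intensity_matrix(tm, m)
  sol <- cluster_modality(x, k = 3, modality = m)
  mv <- suppressWarnings(manova_one_way(x, sol))
  tk <- tukey_hsd_per_sample(x, sol)
  sm <- summarize_clusters(x, sol)

  cat(sprintf("%-11s N=%3d  sizes %s  Wilks=%.3f  partial_eta2=%.3f\n",
              m, nrow(x), paste(sol$sizes, collapse = "/"),
              mv$table["Wilks", "statistic"], mv$partial_eta_sq))
  cat(sprintf("  sample E letters: %s\n",
              paste(tk$letters[, "E"], collapse = " ")))

  asg_rows[[m]] <- data.frame(subject_id = names(sol$assignments),
                              modality = m,
                              csg_label = unname(sol$assignments))
  st <- sm$stats
  st$letter <- ""
  is_cl <- st$cluster != "all"
  st$letter[is_cl] <- tk$letters[cbind(as.integer(st$cluster[is_cl]),
                                       match(st$sample[is_cl],
                                             colnames(tk$letters)))]
  st$modality <- m
  utils::write.csv(st, file.path(out, paste0("summary_", m, ".csv")),
                   row.names = FALSE)
  mt <- as.data.frame(mv$table)
  mt$statistic_name <- rownames(mt); mt$modality <- m
  mt$partial_eta_sq <- mv$partial_eta_sq
  manova_rows[[m]] <- mt
}
utils::write.csv(do.call(rbind, asg_rows), file.path(out, "assignments.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, manova_rows), file.path(out, "manova.csv"),
                 row.names = FALSE)
cat("wrote assignments.csv, manova.csv and per-modality summaries under",
    out, "\n")
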