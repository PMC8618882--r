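#!/usr/bin/env Rscript
# Stage 3: composite sensitivity scores.
#
# Averages each subject's three chemesthesis cluster labels into the CSS
# (seven-value lattice, hypo/semi/hypersensitive categories) and, when the
# taste blocks are present, the five taste labels into the TSS.

suppressPackageStartupMessages(library(chemsens))

asg <- utils::read.csv("results/assignments.csv", stringsAsFactors = FALSE)
chem <- c("astringency", "pungency", "cooling")
taste <- intersect(c("sour", "sweet", "umami", "bitter", "salty"),
                   unique(asg$modality))

wide <- stats::reshape(asg, idvar = "subject_id", timevar = "modality",
                       direction = "wide")
names(wide) <- sub("^csg_label\\.", "", names(wide))

css <- suppressWarnings(compute_css(wide, chem))
utils::write.csv(css, "results/css_scores.csv", row.names = FALSE)
dist <- css_distribution(css)
cat(sprintf("CSS: N=%d  categories hypo/semi/hyper = %s\n", nrow(css),
            paste(dist$by_category, collapse = "/")))
cat("  lattice counts:",
    paste(names(dist$by_group), dist$by_group, sep = "=", collapse = " "),
    "\n")

grDevices::png("results/css_histogram.png", width = 800, height = 500)
print(css_histogram(css))
invisible(grDevices::dev.off())

if (length(taste) == 5) {
  tss <- suppressWarnings(compute_css(wide, taste))
  utils::write.csv(tss, "results/tss_scores.csv", row.names = FALSE)
  tdist <- css_distribution(tss, 5)
  cat(sprintf("TSS: N=%d  categories hypo/semi/hyper = %s\n", nrow(tss),
              paste(tdist$by_category, collapse = "/")))
}
cat("wrote css_scores.csv, css_histogram.png\n")
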