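# fixture builders shared across test files

# tiny long-format rating table: `ratings` is a named list
# subject -> numeric vector over samples A-E (NA = unrated)
make_rating_table <- function(ratings, modality = "astringency",
                              zero = NULL) {
  rows <- do.call(rbind, lapply(names(ratings), function(id) {
    data.frame(subject_id = id, modality = modality,
               sample_code = c("A", "B", "C", "D", "E"),
               intensity = ratings[[id]], stringsAsFactors = FALSE)
  }))
  if (!is.null(zero)) {
    rows <- rbind(rows, data.frame(subject_id = names(zero),
                                   modality = modality, sample_code = "0",
                                   intensity = unname(zero),
                                   stringsAsFactors = FALSE))
  }
  rows
}

# three well-separated Gaussian groups in 5 dimensions
make_separated_matrix <- function(sizes = c(10, 10, 10),
                                  centers = c(0, 5, 10), sd = 0.3,
                                  seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(sizes), function(k) {
    matrix(rnorm(sizes[k] * 5, centers[k], sd), sizes[k], 5)
  }))
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  colnames(x) <- c("A", "B", "C", "D", "E")
  list(x = x, truth = rep(seq_along(sizes), sizes))
}

# adjusted Rand index from the contingency table (Hubert & Arabie)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# cohort config without taste, small helper
chem_only_config <- function(seed = 1, ...) {
  generator_config(seed = seed, ...)
}
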