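#' Read a long-format rating table from CSV
#'
#' Expects columns `subject_id`, `modality`, `sample_code` (0 or A-E) and
#' `intensity` (0-10, empty field = unrated); a `concentration` column is
#' carried through when present. Rows are validated: duplicated
#' (subject, modality, sample) combinations and intensities outside the
#' 0-10 line scale are rejected with the offending row number.
#'
#' @param path CSV file path
#' @return a validated rating table (data.frame)
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_code = "character"))
  required <- c("subject_id", "modality", "sample_code", "intensity")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("rating CSV is missing column(s): ", paste(miss, collapse = ", "))
  tab$intensity <- as.numeric(tab$intensity)
  validate_rating_table(tab)
}

validate_rating_table <- function(tab) {
  bad_code <- !(tab$sample_code %in% c("0", SAMPLE_CODES))
  if (any(bad_code))
    stop("invalid sample code at row(s): ",
         paste(utils::head(which(bad_code), 5), collapse = ", "))
  oor <- !is.na(tab$intensity) & (tab$intensity < 0 | tab$intensity > 10)
  if (any(oor))
    stop("intensity outside the 0-10 scale at row(s): ",
         paste(utils::head(which(oor), 5), collapse = ", "))
  key <- paste(tab$subject_id, tab$modality, tab$sample_code, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (subject, modality, sample) at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  tab
}

#' Drop the water zero sample
#'
#' Removes every record with sample code "0" (the zero samples were rated
#' inconsistently and are excluded before clustering); all other records
#' are untouched.
#'
#' @param table a rating table
#' @return the table without zero-sample rows
#' @export
drop_zero_sample <- function(table) {
  out <- table[table$sample_code != "0", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude subjects with an incomplete sample series
#'
#' For the given modality, keeps only subjects with a non-missing rating
#' for every concentration sample A-E. Completeness is judged on the five
#' concentration samples only — a subject lacking just the water rating is
#' not excluded. Exclusion is per modality: rows of other modalities are
#' untouched.
#'
#' @param table a rating table
#' @param modality modality whose completeness is enforced
#' @return the filtered table
#' @export
exclude_incomplete_subjects <- function(table, modality) {
  rows <- table$modality == modality & table$sample_code %in% SAMPLE_CODES
  sub <- table[rows & !is.na(table$intensity), , drop = FALSE]
  n_rated <- table(factor(sub$subject_id))
  complete <- names(n_rated)[n_rated == 5L]
  keep <- table$modality != modality | table$subject_id %in% complete
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the N x 5 intensity matrix for one modality
#'
#' Rows are subjects in lexicographic `subject_id` order, columns the five
#' concentration samples A-E in ascending concentration. The table must
#' already be complete for the modality (run [exclude_incomplete_subjects()]
#' and [drop_zero_sample()] first); any gap is an error.
#'
#' @param table a rating table
#' @param modality modality to extract
#' @return numeric matrix with rownames = subject ids, colnames = A-E
#' @export
to_intensity_matrix <- function(table, modality) {
  sub <- table[table$modality == modality &
                 table$sample_code %in% SAMPLE_CODES, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for modality '", modality, "'")
  ids <- sort(unique(sub$subject_id))
  m <- matrix(NA_real_, length(ids), 5,
              dimnames = list(ids, SAMPLE_CODES))
  m[cbind(match(sub$subject_id, ids), match(sub$sample_code, SAMPLE_CODES))] <-
    sub$intensity
  if (anyNA(m)) {
    bad <- ids[rowSums(is.na(m)) > 0]
    stop("incomplete series for subject(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " — run exclude_incomplete_subjects() first")
  }
  m
}

#' Convert a wide-format rating CSV to the long schema
#'
#' Accepts one row per subject with columns named `<modality>_<sample>`
#' (e.g. `astringency_A`) and returns the long rating table.
#'
#' @param path CSV path
#' @return a validated rating table
#' @export
read_ratings_wide_csv <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(wide)) stop("wide CSV needs a subject_id column")
  value_cols <- setdiff(names(wide), "subject_id")
  parts <- regmatches(value_cols, regexec("^(.*)_([0ABCDE])$", value_cols))
  ok <- lengths(parts) == 3L
  if (!all(ok))
    stop("column(s) not of the form modality_sample: ",
         paste(value_cols[!ok], collapse = ", "))
  long <- do.call(rbind, lapply(seq_along(value_cols), function(j) {
    data.frame(subject_id = wide$subject_id,
               modality = parts[[j]][2],
               sample_code = parts[[j]][3],
               intensity = as.numeric(wide[[value_cols[j]]]),
               stringsAsFactors = FALSE)
  }))
  validate_rating_table(long)
}
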