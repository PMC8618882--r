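#' @importFrom stats rnorm qnorm pnorm cor sd quantile
NULL

# Deterministic per-stream seeds: one master integer seed, sub-streams keyed
# by a label (e.g. the modality) via a small polynomial string hash. Keeps
# every stream below 2^31 and stable across platforms.
stream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 10007 + h) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default missingness pattern for the synthetic cohort
#'
#' Which subjects fail to complete which sample series. The default pattern
#' has 8 subjects incomplete for astringency, 6 for pungency and 7 for
#' cooling, with an overlap chosen so that exactly 9 distinct subjects are
#' incomplete somewhere — leaving 197/199/198 complete per modality and 196
#' subjects with all three modalities. A further 7 subjects (beyond those 9)
#' miss the taste series, leaving 189 subjects complete for both test sets.
#'
#' @param n_subjects cohort size
#' @return list with integer index vectors `astringency`, `pungency`,
#'   `cooling`, `taste`
#' @export
default_missing_pattern <- function(n_subjects = 205L) {
  stopifnot(n_subjects >= 16L)
  list(
    astringency = 1:8,             # 5 miss all, +6 (A&P), +7 (A&C), +8 (A only)
    pungency    = 1:6,
    cooling     = c(1:5, 7L, 9L),
    taste       = 1:16
  )
}

#' Build a synthetic cohort generator configuration
#'
#' @param n_subjects cohort size (default 205, the number of volunteers in
#'   the study the default profiles describe)
#' @param chem_profiles per-cluster Gaussian profiles for the chemesthetic
#'   modalities, as returned by [chem_cluster_profiles()]
#' @param taste_profiles optional taste-modality profiles
#'   ([taste_cluster_profiles_synthetic()]), or `NULL` to generate the
#'   chemesthesis block only
#' @param rho_latent shared-latent-trait association strength in `[0,1)`;
#'   0 gives independent modality memberships, values near 1 give nearly
#'   identical memberships. The default 0.43 is calibrated so that the
#'   CSS-TSS correlation of an analyzed cohort (clusters re-estimated from
#'   the generated ratings) is about +0.56.
#' @param missing missingness pattern (see [default_missing_pattern()]);
#'   use empty integer vectors for a fully complete cohort
#' @param include_zero_sample add a water zero sample (code "0") rated near
#'   zero independently of cluster, so downstream exclusion is exercised
#' @param seed master integer seed
#' @return an object of class `chem_generator_config`
#' @export
generator_config <- function(n_subjects = 205L,
                             chem_profiles = chem_cluster_profiles(),
                             taste_profiles = NULL,
                             rho_latent = 0.43,
                             missing = default_missing_pattern(n_subjects),
                             include_zero_sample = TRUE,
                             seed = 1L) {
  if (rho_latent < 0 || rho_latent >= 1)
    stop("rho_latent must lie in [0, 1)")
  profiles <- c(chem_profiles, taste_profiles)
  for (m in names(profiles)) {
    n_miss <- length(missing_for(missing, m))
    n_complete <- sum(vapply(profiles[[m]], `[[`, integer(1), "size"))
    if (n_complete + n_miss != n_subjects)
      stop(sprintf(
        "modality '%s': cluster sizes (%d) + incomplete subjects (%d) != cohort size (%d)",
        m, n_complete, n_miss, n_subjects))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 chem_profiles = chem_profiles,
                 taste_profiles = taste_profiles,
                 rho_latent = rho_latent,
                 missing = missing,
                 include_zero_sample = isTRUE(include_zero_sample),
                 seed = as.integer(seed)),
            class = "chem_generator_config")
}

missing_for <- function(missing, modality) {
  if (modality %in% TASTE_MODALITIES && !is.null(missing$taste))
    return(missing$taste)
  if (!is.null(missing[[modality]])) missing[[modality]] else integer(0)
}

#' Assign latent sensitivity clusters
#'
#' Draws one shared latent trait `z` per subject and a per-modality score
#' `sqrt(rho) * z + sqrt(1 - rho) * eps`; subjects with complete data for a
#' modality are ranked on that score and cut into quota groups whose sizes
#' equal the configured cluster sizes exactly (lowest scores -> cluster 1).
#' Incomplete subjects get `NA`.
#'
#' @param config a [generator_config()]
#' @param seed optional seed overriding `config$seed`
#' @return list with `labels` (data.frame subject x modality columns of
#'   cluster labels) and `z` (latent trait per subject)
#' @export
assign_latent_clusters <- function(config, seed = config$seed) {
  n <- config$n_subjects
  rho <- config$rho_latent
  profiles <- c(config$chem_profiles, config$taste_profiles)
  z <- with_seed(stream_seed(seed, "latent-z"), rnorm(n))
  labels <- data.frame(subject_id = subject_ids(n), stringsAsFactors = FALSE)
  for (m in names(profiles)) {
    sizes <- vapply(profiles[[m]], `[[`, integer(1), "size")
    eps <- with_seed(stream_seed(seed, paste0("eps-", m)), rnorm(n))
    score <- sqrt(rho) * z + sqrt(1 - rho) * eps
    lab <- rep(NA_integer_, n)
    idx <- setdiff(seq_len(n), missing_for(config$missing, m))
    ord <- idx[order(score[idx])]
    lab[ord] <- rep.int(seq_along(sizes), sizes)
    labels[[m]] <- lab
  }
  list(labels = labels, z = z)
}

subject_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Draw censored Gaussian intensity ratings for one modality
#'
#' Ratings for subject i on sample s are drawn from
#' `Normal(mean[cluster(i), s], sd[cluster(i), s])` and clipped to the 0-10
#' line scale. With a zero SD all ratings equal the clipped mean.
#'
#' @param labels integer cluster labels (NA = subject skipped)
#' @param profiles list of 3 cluster profiles for the modality
#' @param seed integer seed for this modality's stream
#' @return matrix `length(labels)` x 5 (columns A-E), NA rows for NA labels
#' @export
sample_ratings <- function(labels, profiles, seed) {
  for (p in profiles) validate_cluster_profile(p)
  mu <- t(vapply(profiles, `[[`, numeric(5), "means"))
  sg <- t(vapply(profiles, `[[`, numeric(5), "sds"))
  n <- length(labels)
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, SAMPLE_CODES))
  ok <- !is.na(labels)
  noise <- with_seed(seed, matrix(rnorm(n * 5), n, 5))
  raw <- mu[labels[ok], , drop = FALSE] +
    sg[labels[ok], , drop = FALSE] * noise[ok, , drop = FALSE]
  out[ok, ] <- pmin(pmax(raw, 0), 10)
  out
}

#' Generate a full synthetic cohort
#'
#' Produces a long-format rating table (with optional zero samples and the
#' configured missingness) plus the ground-truth latent cluster labels and
#' latent trait, deterministically for a fixed seed. Incomplete subjects
#' appear in the table with one sample left unrated (NA intensity) so that
#' completeness filtering downstream is exercised.
#'
#' @param config a [generator_config()]
#' @param seed optional override of `config$seed`
#' @return object of class `chem_cohort`: list with `ratings` (long
#'   data.frame: subject_id, modality, sample_code, concentration,
#'   intensity), `truth` (long data.frame: subject_id, modality,
#'   latent_cluster, z) and `config`
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "chem_generator_config"))
  asg <- assign_latent_clusters(config, seed)
  profiles <- c(config$chem_profiles, config$taste_profiles)
  conc <- chem_sample_series()
  n <- config$n_subjects
  ids <- subject_ids(n)

  blocks <- lapply(names(profiles), function(m) {
    lab <- asg$labels[[m]]
    ratings <- sample_ratings(lab, profiles[[m]],
                              stream_seed(seed, paste0("ratings-", m)))
    miss_idx <- missing_for(config$missing, m)
    if (length(miss_idx)) {
      # incomplete subjects: one unrated sample apiece (deterministic choice)
      drop_col <- 1L + (miss_idx %% 5L)
      ratings[cbind(miss_idx, drop_col)] <- NA_real_
    }
    cc <- conc$concentration[conc$modality == m]
    if (!length(cc)) cc <- rep(NA_real_, 5)  # taste: no concentration ladder here
    block <- data.frame(
      subject_id = rep(ids, each = 5L),
      modality = m,
      sample_code = rep(SAMPLE_CODES, n),
      concentration = rep(cc, n),
      intensity = as.vector(t(ratings)),
      stringsAsFactors = FALSE)
    if (config$include_zero_sample) {
      zero <- with_seed(stream_seed(seed, paste0("zero-", m)),
                        pmin(pmax(rnorm(n, 0.3, 0.4), 0), 10))
      block <- rbind(data.frame(subject_id = ids, modality = m,
                                sample_code = "0", concentration = 0,
                                intensity = zero, stringsAsFactors = FALSE),
                     block)
    }
    block
  })
  ratings <- do.call(rbind, blocks)
  ratings <- ratings[order(ratings$subject_id, ratings$modality,
                           ratings$sample_code), ]
  rownames(ratings) <- NULL

  truth <- do.call(rbind, lapply(names(profiles), function(m) {
    data.frame(subject_id = ids, modality = m,
               latent_cluster = asg$labels[[m]],
               z = asg$z, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  structure(list(ratings = ratings, truth = truth, config = config),
            class = "chem_cohort")
}

#' Read or write a generator configuration as JSON
#'
#' The JSON mirrors the configuration object: cohort size, association
#' strength, missingness pattern, zero-sample flag, seed, and the full set
#' of per-cluster profiles. The packaged default
#' (`system.file("extdata", "default_config.json", package = "chemsens")`)
#' reproduces the published sample series and cluster profiles.
#'
#' @param path JSON file path
#' @return a `chem_generator_config`
#' @export
generator_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_profiles <- function(block) {
    lapply(block, function(pl) {
      lapply(seq_len(nrow(pl)), function(i) {
        list(modality = pl$modality[i], cluster = as.integer(pl$cluster[i]),
             size = as.integer(pl$size[i]),
             means = as.numeric(pl$means[[i]]), sds = as.numeric(pl$sds[[i]]))
      })
    })
  }
  generator_config(
    n_subjects = as.integer(j$n_subjects),
    chem_profiles = parse_profiles(j$chem_profiles),
    taste_profiles = if (!is.null(j$taste_profiles))
      parse_profiles(j$taste_profiles) else NULL,
    rho_latent = j$rho_latent,
    missing = lapply(j$missing, as.integer),
    include_zero_sample = isTRUE(j$include_zero_sample),
    seed = as.integer(j$seed))
}

#' @rdname generator_config_from_json
#' @param config a `chem_generator_config` to serialize
#' @export
generator_config_to_json <- function(config, path) {
  stopifnot(inherits(config, "chem_generator_config"))
  ser_profiles <- function(block) {
    lapply(block, function(pl) {
      data.frame(modality = vapply(pl, `[[`, character(1), "modality"),
                 cluster = vapply(pl, `[[`, integer(1), "cluster"),
                 size = vapply(pl, `[[`, integer(1), "size"),
                 means = I(lapply(pl, `[[`, "means")),
                 sds = I(lapply(pl, `[[`, "sds")))
    })
  }
  j <- list(n_subjects = config$n_subjects,
            rho_latent = config$rho_latent,
            include_zero_sample = config$include_zero_sample,
            seed = config$seed,
            missing = config$missing,
            chem_profiles = ser_profiles(config$chem_profiles))
  if (!is.null(config$taste_profiles))
    j$taste_profiles <- ser_profiles(config$taste_profiles)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a cohort's ratings and truth labels as CSV
#'
#' @param cohort a `chem_cohort`
#' @param dir output directory (created if absent)
#' @return invisibly, the two file paths written
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "chem_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ratings_path <- file.path(dir, "ratings.csv")
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(cohort$ratings, ratings_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE, na = "")
  invisible(c(ratings = ratings_path, truth = truth_path))
}
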