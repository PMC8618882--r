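#' Chemesthetic sample series
#'
#' The three modality-specific sample series used in the sensory test:
#' five ascending concentrations (codes A-E) per modality on a quarter
#' logarithmic dilution ladder (constant ratio of about 10^(1/4) between
#' successive samples), plus a water zero sample. Astringency was elicited
#' by aluminum ammonium sulfate (mM), pungency by capsaicin (uM) and
#' cooling by menthol (mM).
#'
#' @return A data.frame with one row per modality x sample code, columns
#'   `modality`, `compound`, `sample_code` ("A".."E"), `concentration`
#'   and `unit`.
#' @export
chem_sample_series <- function() {
  series <- list(
    astringency = list(compound = "aluminum ammonium sulfate", unit = "mM",
                       conc = c(0.22, 0.39, 0.70, 1.24, 2.21)),
    pungency    = list(compound = "capsaicin", unit = "uM",
                       conc = c(0.049, 0.088, 0.154, 0.275, 0.491)),
    cooling     = list(compound = "menthol", unit = "mM",
                       conc = c(0.013, 0.023, 0.040, 0.072, 0.128))
  )
  do.call(rbind, lapply(names(series), function(m) {
    s <- series[[m]]
    data.frame(modality = m, compound = s$compound,
               sample_code = SAMPLE_CODES, concentration = s$conc,
               unit = s$unit, stringsAsFactors = FALSE)
  }))
}

SAMPLE_CODES <- c("A", "B", "C", "D", "E")
CHEM_MODALITIES <- c("astringency", "pungency", "cooling")
TASTE_MODALITIES <- c("sour", "sweet", "umami", "bitter", "salty")

#' Per-cluster intensity profiles for the chemesthetic modalities
#'
#' Gaussian intensity profiles (mean, SD per sample A-E) and group sizes for
#' the three sensitivity clusters of each chemesthetic modality, as estimated
#' from the study cohort. Cluster 1 is the least sensitive, cluster 3 the
#' most sensitive. These profiles parameterize the synthetic cohort
#' generator.
#'
#' @return A list keyed by modality; each element is a list of three
#'   cluster profiles with fields `modality`, `cluster`, `size`, `means`
#'   (length 5) and `sds` (length 5).
#' @export
chem_cluster_profiles <- function() {
  p <- function(modality, cluster, size, means, sds) {
    prof <- list(modality = modality, cluster = cluster, size = size,
                 means = means, sds = sds)
    validate_cluster_profile(prof)
    prof
  }
  list(
    astringency = list(
      p("astringency", 1L, 91L, c(1.05, 1.08, 1.78, 4.03, 6.21),
                                 c(1.02, 1.11, 1.41, 1.72, 1.81)),
      p("astringency", 2L, 62L, c(0.86, 1.18, 4.47, 7.00, 8.63),
                                 c(0.95, 1.11, 1.33, 1.55, 1.10)),
      p("astringency", 3L, 44L, c(3.58, 4.71, 4.83, 7.19, 8.18),
                                 c(2.25, 2.15, 2.57, 1.55, 1.40))),
    pungency = list(
      p("pungency", 1L, 56L, c(1.04, 1.21, 2.01, 2.97, 5.18),
                              c(1.05, 1.08, 1.51, 1.61, 1.57)),
      p("pungency", 2L, 59L, c(0.84, 1.03, 1.97, 4.98, 8.15),
                              c(0.76, 1.01, 1.28, 1.71, 0.82)),
      p("pungency", 3L, 84L, c(2.50, 3.46, 5.06, 7.09, 8.75),
                              c(1.94, 1.86, 1.70, 1.72, 1.10))),
    cooling = list(
      p("cooling", 1L, 81L, c(0.67, 1.47, 1.75, 2.59, 3.99),
                             c(0.97, 1.12, 1.13, 1.59, 1.66)),
      p("cooling", 2L, 96L, c(1.96, 3.01, 3.92, 5.06, 6.32),
                             c(1.38, 1.73, 1.54, 1.44, 1.47)),
      p("cooling", 3L, 21L, c(3.76, 4.70, 6.54, 8.06, 8.78),
                             c(1.51, 1.94, 1.61, 1.69, 0.97)))
  )
}

#' Synthetic per-cluster profiles for the five taste modalities
#'
#' The taste side of the cohort (sour, sweet, umami, bitter, salty) was
#' measured in a companion study whose per-cluster profiles are not
#' reproduced here; these are synthetic stand-ins with the same 3-group
#' structure (ascending intensity with concentration and with cluster)
#' so that taste sensitivity groups, the TSS and chemesthesis-taste
#' interaction models can be exercised. They are not estimates of any
#' real panel.
#'
#' @return A list keyed by taste modality, same shape as
#'   [chem_cluster_profiles()].
#' @export
taste_cluster_profiles_synthetic <- function() {
  p <- function(modality, cluster, size, means, sds) {
    prof <- list(modality = modality, cluster = cluster, size = size,
                 means = means, sds = sds)
    validate_cluster_profile(prof)
    prof
  }
  sizes <- list(sour  = c(57L, 95L, 37L), sweet = c(52L, 88L, 49L),
                umami = c(70L, 83L, 36L), bitter = c(60L, 90L, 39L),
                salty = c(55L, 92L, 42L))
  base_means <- list(c(0.9, 1.4, 2.2, 3.5, 5.0),
                     c(1.5, 2.5, 4.0, 5.8, 7.5),
                     c(3.0, 4.5, 6.0, 7.6, 8.8))
  out <- lapply(names(sizes), function(m) {
    lapply(1:3, function(k) {
      p(m, as.integer(k), sizes[[m]][k], base_means[[k]],
        rep(1.5, 5))
    })
  })
  names(out) <- names(sizes)
  out
}

validate_cluster_profile <- function(prof) {
  stopifnot(length(prof$means) == 5L, length(prof$sds) == 5L)
  if (any(prof$sds < 0)) stop("cluster profile SDs must be non-negative")
  # means outside [0,10] are allowed and get censored at sampling time
  if (prof$size <= 0) stop("cluster size must be positive")
  invisible(prof)
}
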