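#' Pairwise squared Euclidean distances
#'
#' `d(i,j) = sum_s (x[i,s] - x[j,s])^2` over the five samples. Squared
#' Euclidean distances are the dissimilarity the Ward agglomeration here
#' operates on.
#'
#' @param matrix numeric N x p intensity matrix
#' @return symmetric N x N matrix of squared distances, zero diagonal
#' @export
squared_euclidean_distances <- function(matrix) {
  if (anyNA(matrix)) stop("intensity matrix has missing cells")
  x <- as.matrix(matrix)
  g <- tcrossprod(x)
  n2 <- diag(g)
  d <- outer(n2, n2, "+") - 2 * g
  d[d < 0] <- 0  # numerical guard
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Agglomerative Ward clustering on squared distances
#'
#' Classic agglomerative hierarchy under Ward's criterion: at each step the
#' pair of clusters whose merge is cheapest under the current dissimilarity
#' is joined, and dissimilarities to the new cluster are updated with the
#' Lance-Williams recurrence for Ward linkage,
#' `d(k, i+j) = ((n_i + n_k) d(k,i) + (n_j + n_k) d(k,j) - n_k d(i,j)) /
#' (n_i + n_j + n_k)`.
#' Applied to squared Euclidean distances this reproduces the conventional
#' "Ward on squared distances" hierarchy (heights on the squared-distance
#' scale, equal to twice the increase in within-cluster sum of squares).
#' Ties are broken deterministically by the lexicographically smallest pair
#' of cluster codes.
#'
#' @param d symmetric dissimilarity matrix (from
#'   [squared_euclidean_distances()])
#' @param sizes optional initial cluster sizes (default all 1)
#' @return object of class `chem_dendrogram`: list with `merge` (N-1 x 2,
#'   negative = singleton as in [stats::hclust()]), `height`, `labels`
#' @export
ward_agglomerate <- function(d, sizes = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two observations to agglomerate")
  labels <- rownames(d)
  size <- if (is.null(sizes)) rep(1, n) else as.numeric(sizes)
  code <- -(seq_len(n))           # hclust convention: negatives = singletons
  active <- rep(TRUE, n)
  # full symmetric working copy; Inf marks unusable entries
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    best <- min(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (min code, max code) pair
    cand_i <- idx[hit[, 1]]; cand_j <- idx[hit[, 2]]
    pick <- order(pmin(cand_i, cand_j), pmax(cand_i, cand_j))[1]
    i <- cand_i[pick]; j <- cand_j[pick]

    ni <- size[i]; nj <- size[j]
    merge[step, ] <- sort_merge_pair(code[i], code[j])
    height[step] <- best

    k <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(k)) {
      nk <- size[k]
      upd <- ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * best) /
        (ni + nj + nk)
      D[i, k] <- upd
      D[k, i] <- upd
    }
    size[i] <- ni + nj
    code[i] <- step
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "chem_dendrogram")
}

sort_merge_pair <- function(a, b) {
  # hclust convention: singletons (ascending index) before clusters
  if (a < 0 && b < 0) c(-min(-a, -b), -max(-a, -b))
  else if (a > 0 && b > 0) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b) else c(b, a)
}

#' Convert a `chem_dendrogram` to an `hclust` object
#'
#' @param dend a `chem_dendrogram`
#' @return an object of class `hclust` (order computed for plotting)
#' @export
as_hclust <- function(dend) {
  stopifnot(inherits(dend, "chem_dendrogram"))
  h <- list(merge = dend$merge, height = dend$height,
            order = dendrogram_leaf_order(dend$merge, dend$n),
            labels = dend$labels, method = "ward(squared euclidean)",
            call = NULL, dist.method = "squared euclidean")
  class(h) <- "hclust"
  h
}

dendrogram_leaf_order <- function(merge, n) {
  members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    left <- if (merge[s, 1] < 0) -merge[s, 1] else members[[merge[s, 1]]]
    right <- if (merge[s, 2] < 0) -merge[s, 2] else members[[merge[s, 2]]]
    members[[s]] <- c(left, right)
  }
  members[[n - 1L]]
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges; the resulting connected components are
#' the clusters. Raw labels are numbered by first appearance in row order.
#'
#' @param dend a `chem_dendrogram`
#' @param k number of clusters, `1 <= k <= N`
#' @return integer vector of raw cluster labels (named by subject when the
#'   input matrix had rownames)
#' @export
cut_k <- function(dend, k) {
  stopifnot(inherits(dend, "chem_dendrogram"))
  n <- dend$n
  if (k < 1 || k > n) stop("k must be between 1 and N = ", n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  leaf_of_code <- function(code)
    if (code < 0) -code else first_leaf[code]
  first_leaf <- integer(n - 1L)
  n_merge <- n - k
  for (s in seq_len(n - 1L)) {
    a <- leaf_of_code(dend$merge[s, 1])
    first_leaf[s] <- a
    if (s <= n_merge) {
      b <- leaf_of_code(dend$merge[s, 2])
      ra <- find(a); rb <- find(b)
      parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  raw <- match(roots, unique(roots))
  names(raw) <- dend$labels
  raw
}

#' Order clusters by mean intensity and build a cluster solution
#'
#' Relabels raw clusters so that label 1 is the least sensitive and label
#' `k` the most sensitive, judged by the cluster grand mean (the average of
#' its five per-sample mean intensities). Ties on the grand mean are broken
#' by the strongest-sample mean, then by the smallest raw label.
#'
#' @param raw integer raw cluster labels
#' @param matrix the N x 5 intensity matrix the clusters were built from
#' @param modality optional modality name carried into the result
#' @return object of class `chem_cluster_solution`: `assignments` (named
#'   integer vector), `sizes`, `means` and `sds` (k x 5), `grand_means`
#' @export
order_clusters_by_intensity <- function(raw, matrix, modality = NA_character_) {
  x <- as.matrix(matrix)
  stopifnot(length(raw) == nrow(x))
  ks <- sort(unique(raw))
  means <- t(vapply(ks, function(k) colMeans(x[raw == k, , drop = FALSE]),
                    numeric(ncol(x))))
  sds <- t(vapply(ks, function(k) apply(x[raw == k, , drop = FALSE], 2, sd),
                  numeric(ncol(x))))
  grand <- rowMeans(means)
  ord <- order(grand, means[, ncol(means)], ks)
  relabel <- match(raw, ks[ord])
  names(relabel) <- rownames(x)
  structure(list(modality = modality,
                 assignments = relabel,
                 sizes = as.integer(table(factor(relabel, levels = seq_along(ks)))),
                 means = means[ord, , drop = FALSE],
                 sds = sds[ord, , drop = FALSE],
                 grand_means = grand[ord]),
            class = "chem_cluster_solution")
}

#' Cluster one modality end to end
#'
#' Squared Euclidean distances, Ward agglomeration, cut at `k`, clusters
#' ordered by ascending mean intensity.
#'
#' @param matrix N x 5 intensity matrix (see [to_intensity_matrix()])
#' @param k number of clusters (default 3)
#' @param modality optional modality name
#' @return a `chem_cluster_solution` with the dendrogram attached as
#'   attribute `"dendrogram"`
#' @export
cluster_modality <- function(matrix, k = 3L, modality = NA_character_) {
  d <- squared_euclidean_distances(matrix)
  dend <- ward_agglomerate(d)
  raw <- cut_k(dend, k)
  sol <- order_clusters_by_intensity(raw, matrix, modality)
  attr(sol, "dendrogram") <- dend
  sol
}
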