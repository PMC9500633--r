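#' K-means categorization of components in descriptor space
#'
#' Partitions pure components into `k` categories by minimizing the total
#' within-cluster sum of squared Euclidean distances in descriptor space.
#' For the small panels this workflow targets (`k = 2`, at most 16
#' components) the optimal bipartition is found exactly by enumerating all
#' bipartitions; larger problems use Lloyd's k-means with the best of
#' `n_restarts` seeded random starts by inertia. Descriptors are standardized
#' to zero mean and unit variance per column by default, so the raw energy
#' scales do not dominate the distance; set `scale = FALSE` for distances on
#' the raw descriptor values.
#'
#' @param panel Component descriptor panel (data frame with `name` plus the
#'   eight descriptor columns). Supply the variable components only; the
#'   fixed co-component does not belong in the categorization.
#' @param k Number of clusters (default 2).
#' @param seed Integer seed making the restarts reproducible.
#' @param n_restarts Random restarts; best solution by inertia is kept.
#' @param scale Standardize descriptor columns before clustering.
#' @return Object of class `cluster_assignment`: `k`, `labels` (named
#'   integer vector, component -> cluster in 1..k), `centroids` (k x 8 matrix
#'   on the clustering scale), `inertia`, `scaled`.
#' @export
kmeans_components <- function(panel, k = 2L, seed = 1L, n_restarts = 10L,
                              scale = TRUE) {
  if (nrow(panel) < k) {
    stop("panel must contain at least k components", call. = FALSE)
  }
  X <- as.matrix(panel[, descriptor_names(), drop = FALSE])
  if (scale) {
    X <- base::scale(X)
    # constant columns scale to NaN; they carry no distance information
    X[, apply(!is.finite(X), 2, any)] <- 0
  }
  if (k == 2L && nrow(X) <= 16L) {
    sol <- exact_kmeans2(X)
    labels <- sol$labels
    centroids <- sol$centroids
    inertia <- sol$inertia
  } else {
    set.seed(seed)
    fit <- NULL
    for (attempt in 1:20) {
      fit <- tryCatch(
        stats::kmeans(X, centers = k, nstart = n_restarts,
                      algorithm = "Lloyd", iter.max = 100L),
        error = function(e) e, warning = function(w) w)
      if (inherits(fit, "kmeans")) break
    }
    if (!inherits(fit, "kmeans")) {
      stop("k-means failed to converge without empty clusters", call. = FALSE)
    }
    labels <- as.integer(fit$cluster)
    centroids <- fit$centers
    inertia <- fit$tot.withinss
  }
  names(labels) <- panel$name
  structure(list(k = as.integer(k), labels = labels,
                 centroids = centroids,
                 inertia = inertia, scaled = scale),
            class = "cluster_assignment")
}

# globally optimal 2-partition by enumeration; the first point anchors
# cluster 1 so the labeling is deterministic
exact_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  best_lab <- NULL
  for (code in seq_len(2L^(n - 1L) - 1L)) {
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1L)] + 1L)
    ss <- 0
    for (g in 1:2) {
      Xg <- X[lab == g, , drop = FALSE]
      ss <- ss + sum(sweep(Xg, 2L, colMeans(Xg))^2)
    }
    if (ss < best) { best <- ss; best_lab <- lab }
  }
  centroids <- rbind(colMeans(X[best_lab == 1L, , drop = FALSE]),
                     colMeans(X[best_lab == 2L, , drop = FALSE]))
  rownames(centroids) <- c("1", "2")
  list(labels = best_lab, centroids = centroids, inertia = best)
}

#' Propagate component categories to mixture samples
#'
#' Each mixture sample inherits the cluster of its variable (non-fixed)
#' component; the resulting partition of the samples is exhaustive and
#' disjoint.
#'
#' @param assignment A `cluster_assignment` from [kmeans_components()].
#' @param samples Data frame of mixture samples with a `component` column.
#' @return Named list of length `k`; element `g` holds the integer row
#'   indices of `samples` whose component belongs to cluster `g`.
#' @export
assign_mixtures <- function(assignment, samples) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  out <- stats::setNames(vector("list", assignment$k),
                         paste0("category_", seq_len(assignment$k)))
  for (g in seq_len(assignment$k)) out[[g]] <- integer(0)
  if (nrow(samples) == 0L) return(out)
  lab <- assignment$labels[samples$component]
  if (anyNA(lab)) {
    stop("unknown component(s): ",
         paste(unique(samples$component[is.na(lab)]), collapse = ", "),
         call. = FALSE)
  }
  for (g in seq_len(assignment$k)) out[[g]] <- which(lab == g)
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions up to label permutation, 0 is the expected
#' agreement of random labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return Adjusted Rand index in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
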