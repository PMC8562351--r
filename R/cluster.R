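#' Principal component analysis of a spectrum matrix
#'
#' Mean-centered (unscaled) PCA. Used to report the explained-variance
#' structure of the spectrum set and to visualize groups in the first two
#' components; the clustering itself operates on the full spectra.
#'
#' @param x Numeric matrix, spectra in rows (at least 3).
#' @return A list (`pca_result`) with `scores` (spectra x components),
#'   `explained_variance_fractions` and `sdev`.
#' @export
pca_project <- function(x) {
  if (nrow(x) < 3) stop("need at least 3 spectra for PCA")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, explained_variance_fractions = frac,
                 sdev = p$sdev),
            class = "pca_result")
}

#' Pairwise squared Euclidean distances between rows
#' @keywords internal
pairwise_sqdist <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

#' Graph spectral clustering of spectra
#'
#' Builds a Gaussian affinity `exp(-d^2 / (2 sigma^2))` on pairwise
#' Euclidean distances, forms the symmetric normalized graph Laplacian,
#' embeds each spectrum in the `k` smallest eigenvectors (rows normalized to
#' unit length) and partitions the embedding with seeded k-means. The
#' ascending Laplacian eigenvalues are returned for eigengap model
#' selection.
#'
#' The default kernel scale (`sigma = "auto"`) is the 0.1 quantile of the
#' pairwise distances, which sits at the within-group distance scale when
#' groups occupy a modest share of all pairs; it can be fixed numerically.
#' Per-feature standardization before the distance computation is available
#' but off by default: on long spectra it inflates noise-only features and
#' drives all affinities to zero.
#'
#' @param x Numeric matrix, spectra in rows.
#' @param k Number of clusters, `2 <= k < nrow(x)`.
#' @param seed Integer seed for the k-means stage (default 0).
#' @param sigma Kernel scale: `"auto"` or a positive number.
#' @param standardize Standardize features to unit variance first
#'   (default FALSE).
#' @param nstart k-means restarts (default 10).
#' @return A list (`cluster_assignment`) with `labels` (1..k),
#'   `n_clusters`, `laplacian_eigenvalues` (ascending) and `sigma`.
#' @export
spectral_cluster <- function(x, k, seed = 0L, sigma = "auto",
                             standardize = FALSE, nstart = 10) {
  n <- nrow(x)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < number of spectra")
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  d2 <- pairwise_sqdist(x)
  if (identical(sigma, "auto")) {
    d <- sqrt(d2[upper.tri(d2)])
    sigma <- stats::quantile(d, 0.1, names = FALSE)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  a <- exp(-d2 / (2 * sigma^2))
  diag(a) <- 0
  deg <- rowSums(a)
  if (any(deg <= 0))
    stop("degenerate affinity graph: isolated spectra at kernel scale ",
         signif(sigma, 4))
  dis <- 1 / sqrt(deg)
  lap <- diag(n) - (dis * a) * rep(dis, each = n)  # I - D^-1/2 A D^-1/2
  e <- eigen(lap, symmetric = TRUE)
  evals <- rev(e$values)
  evals[evals < 0] <- 0
  embed <- e$vectors[, n:(n - k + 1), drop = FALSE]
  rn <- sqrt(rowSums(embed^2))
  rn[rn == 0] <- 1
  embed <- embed / rn
  set.seed(seed)
  km <- stats::kmeans(embed, centers = k, nstart = nstart, iter.max = 100)
  structure(list(labels = km$cluster, n_clusters = as.integer(k),
                 laplacian_eigenvalues = evals, sigma = sigma),
            class = "cluster_assignment")
}

#' Choose the cluster count from the Laplacian eigengap
#'
#' Returns the `k` in `[2, k_max]` with the largest gap
#' `lambda[k+1] - lambda[k]` of the ascending Laplacian eigenvalues. For an
#' affinity graph with `m` ideally disconnected components the first `m`
#' eigenvalues are zero and the estimate is `m`.
#'
#' @param laplacian_eigenvalues Ascending numeric vector of eigenvalues.
#' @param k_max Largest cluster count considered (default 10).
#' @return Integer estimate of the number of clusters.
#' @export
estimate_cluster_count <- function(laplacian_eigenvalues, k_max = 10) {
  ev <- laplacian_eigenvalues
  if (k_max < 2) stop("k_max must be >= 2")
  if (length(ev) < k_max + 1)
    stop("need at least k_max + 1 = ", k_max + 1, " eigenvalues")
  if (is.unsorted(ev, strictly = FALSE))
    stop("eigenvalues must be sorted ascending")
  gaps <- ev[3:(k_max + 1)] - ev[2:k_max]
  ks <- 2:k_max
  ks[which.max(gaps)]
}

#' Order clusters by mean nuclear density
#'
#' Fills per-cluster ND summaries (mean, SD, n) and relabels the clusters so
#' that cluster ids increase with mean ND (cluster 1 = lowest density). The
#' relabeling is a pure permutation: co-membership is unchanged.
#'
#' @param assignment A `cluster_assignment` from [spectral_cluster()].
#' @param nd Per-spectrum ND annotation (same order as the clustered rows).
#' @return The assignment with relabeled `labels` and an `nd_summary` data
#'   frame (`cluster`, `mean_nd`, `sd_nd`, `n`).
#' @export
associate_clusters_with_nd <- function(assignment, nd) {
  if (length(nd) != length(assignment$labels) || anyNA(nd))
    stop("every spectrum needs an ND annotation")
  means <- tapply(nd, assignment$labels, mean)
  ord <- order(means)  # old label ids sorted by ascending mean ND
  relabel <- integer(assignment$n_clusters)
  relabel[as.integer(names(means))[ord]] <- seq_along(ord)
  assignment$labels <- relabel[assignment$labels]
  assignment$nd_summary <- data.frame(
    cluster = seq_len(assignment$n_clusters),
    mean_nd = as.numeric(tapply(nd, assignment$labels, mean)),
    sd_nd = as.numeric(tapply(nd, assignment$labels, stats::sd)),
    n = as.integer(table(factor(assignment$labels,
                                levels = seq_len(assignment$n_clusters))))
  )
  assignment
}

#' Count spectra assigned outside their sample's majority cluster
#'
#' For each tissue sample the majority cluster of its spectra is found (ties
#' broken toward the lower cluster id); every spectrum assigned elsewhere is
#' counted as miscategorized.
#'
#' @param assignment A `cluster_assignment`.
#' @param sample_ids Per-spectrum sample identifiers.
#' @return Integer count of miscategorized spectra.
#' @export
count_miscategorized <- function(assignment, sample_ids) {
  stopifnot(length(sample_ids) == length(assignment$labels))
  sum(vapply(split(assignment$labels, sample_ids), function(lab) {
    tab <- table(lab)
    maj <- as.integer(names(tab)[which.max(tab)])  # which.max: first = lowest id
    sum(lab != maj)
  }, numeric(1)))
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Tests whether group means differ (one-way F test) and identifies the
#' significantly different pairs with the Tukey-Kramer honestly-significant-
#' difference procedure at level `alpha`.
#'
#' @param groups Named (or unnamed) list of numeric vectors, each with at
#'   least 2 values.
#' @param alpha Significance level (default 0.05).
#' @return A list (`group_comparison`) with `F_statistic`, `p_value`,
#'   `tukey` (full comparison table) and `significant_pairs` (character
#'   vector like `"2-1"`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = dat)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  structure(list(
    F_statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    tukey = tk,
    significant_pairs = rownames(tk)[tk[, "p adj"] < alpha],
    alpha = alpha
  ), class = "group_comparison")
}

#' Full unsupervised analysis of a spectrum set
#'
#' PCA, eigengap selection of the cluster count (via a probe clustering at
#' `k_max`), spectral clustering at the selected `k`, ND ordering of the
#' clusters and the ANOVA/Tukey comparison of cluster NDs.
#'
#' @param x Spectrum matrix (rows = spectra).
#' @param nd Per-spectrum ND annotation.
#' @param sample_ids Per-spectrum sample ids.
#' @param k_max Eigengap search bound (default 10).
#' @param seed Seed for the k-means stages (default 0).
#' @return A list with `pca`, `assignment`, `k`, `miscategorized`,
#'   `comparison`.
#' @export
cluster_spectrum_set <- function(x, nd, sample_ids, k_max = 10, seed = 0L) {
  pca <- pca_project(x)
  probe <- spectral_cluster(x, k = k_max, seed = seed)
  k <- estimate_cluster_count(probe$laplacian_eigenvalues, k_max)
  assignment <- spectral_cluster(x, k = k, seed = seed)
  assignment <- associate_clusters_with_nd(assignment, nd)
  comparison <- anova_tukey(split(nd, assignment$labels))
  list(pca = pca, assignment = assignment, k = k,
       miscategorized = count_miscategorized(assignment, sample_ids),
       comparison = comparison)
}
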