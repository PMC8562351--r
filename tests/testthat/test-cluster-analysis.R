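make_blobs <- function(centers, n_per, sd = 0.05, seed = 5) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), rep(centers[i, ], each = n_per), sd),
           n_per)))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("PCA reports valid, ordered variance fractions", {
  # rank-1 data: a single direction carries all variance
  set.seed(1)
  t_ <- rnorm(50)
  line <- outer(t_, c(1, 2, 3))
  p <- pca_project(line)
  expect_equal(p$explained_variance_fractions[1], 1, tolerance = 1e-9)

  x <- matrix(rnorm(200), 20, 10)
  p2 <- pca_project(x)
  expect_equal(sum(p2$explained_variance_fractions), 1)
  expect_true(all(diff(p2$explained_variance_fractions) <= 1e-12))
  expect_error(pca_project(x[1:2, ]), "at least 3")
})

test_that("spectral clustering separates well-spaced blobs exactly", {
  b <- make_blobs(rbind(c(0, 0), c(10, 10)), 20)
  cl <- spectral_cluster(b$x, 2, seed = 0)
  # brute-force separability: all within-blob pairs share a label,
  # all across-blob pairs differ
  same <- outer(cl$labels, cl$labels, "==")
  truth_same <- outer(b$truth, b$truth, "==")
  expect_identical(same, truth_same)
  expect_error(spectral_cluster(b$x, 1), "k must satisfy")
  expect_error(spectral_cluster(b$x, 40), "k must satisfy")
})

test_that("duplicating every point leaves the partition unchanged", {
  b <- make_blobs(rbind(c(0, 0), c(8, 0), c(0, 8)), 12)
  cl1 <- spectral_cluster(b$x, 3, seed = 0)
  cl2 <- spectral_cluster(rbind(b$x, b$x), 3, seed = 0)
  n <- nrow(b$x)
  # duplicates land with their originals and co-membership is preserved
  expect_identical(outer(cl2$labels[1:n], cl2$labels[1:n], "=="),
                   outer(cl1$labels, cl1$labels, "=="))
  expect_identical(cl2$labels[1:n], cl2$labels[(n + 1):(2 * n)])
})

test_that("clustering is invariant to input order up to relabeling", {
  b <- make_blobs(rbind(c(0, 0), c(6, 6), c(-6, 6)), 15)
  set.seed(2)
  perm <- sample(nrow(b$x))
  cl <- spectral_cluster(b$x, 3, seed = 0)
  clp <- spectral_cluster(b$x[perm, ], 3, seed = 0)
  unpermuted <- integer(length(perm)); unpermuted[perm] <- clp$labels
  expect_identical(outer(unpermuted, unpermuted, "=="),
                   outer(cl$labels, cl$labels, "=="))
})

test_that("k = n - 1 on distinct points forces a singleton cluster", {
  set.seed(8)
  x <- matrix(rnorm(24), 12, 2) * 5
  cl <- spectral_cluster(x, 11, seed = 0)
  expect_true(any(table(cl$labels) == 1))
  expect_true(all(table(cl$labels) >= 1))
})

test_that("the eigengap selects the planted component count", {
  expect_equal(estimate_cluster_count(c(0, 0, 0, 0.9, 1.0, 1.1), k_max = 5), 3)
  expect_error(estimate_cluster_count(c(0, 0.5), k_max = 5), "at least")
  expect_error(estimate_cluster_count(c(0.5, 0.1, 0.2, 0.3, 0.4, 0.6), 5),
               "ascending")
  # near-disconnected components: first m eigenvalues ~ 0, estimate = m
  for (m in c(3, 4)) {
    centers <- matrix(rnorm(2 * m, sd = 40), m, 2)
    b <- make_blobs(centers, 10, sd = 0.05, seed = m)
    cl <- spectral_cluster(b$x, 6, seed = 0)
    expect_equal(estimate_cluster_count(cl$laplacian_eigenvalues, 6), m)
  }
})

test_that("eigengap recovery holds across seeded cohort replicates", {
  # reduced acquisition count keeps the planted five-group structure
  hits <- 0
  for (s in 1:20) {
    cfg <- cohort_config(n_acquisitions_per_sample = 5, seed = 1000 + s)
    ds <- simulate_spectrum_dataset(cfg, seed = 1000 + s)
    cl <- spectral_cluster(ds$x, 10, seed = 0)
    k <- estimate_cluster_count(cl$laplacian_eigenvalues, 10)
    hits <- hits + (k == 5)
  }
  expect_gte(hits, 19)  # >= 95% of runs
})

test_that("clusters are relabeled by increasing mean ND", {
  labels <- c(1, 1, 2, 2, 3)
  nd <- c(4000, 4100, 1500, 1600, 2500)
  asg <- structure(list(labels = labels, n_clusters = 3L),
                   class = "cluster_assignment")
  out <- associate_clusters_with_nd(asg, nd)
  expect_identical(out$labels, c(3L, 3L, 1L, 1L, 2L))
  expect_equal(out$nd_summary$mean_nd, c(1550, 2500, 4050))
  # relabeling preserves co-membership
  expect_identical(outer(out$labels, out$labels, "=="),
                   outer(labels, labels, "=="))
  # single cluster: unchanged
  one <- structure(list(labels = rep(1, 4), n_clusters = 1L),
                   class = "cluster_assignment")
  expect_identical(associate_clusters_with_nd(one, 1:4)$labels,
                   rep(1L, 4))
  expect_error(associate_clusters_with_nd(asg, c(1, 2, NA, 4, 5)),
               "ND annotation")
})

test_that("miscategorized spectra are counted against sample majorities", {
  asg <- function(l) structure(list(labels = l, n_clusters = 3L),
                               class = "cluster_assignment")
  ids <- rep(c("a", "b"), each = 20)
  expect_equal(count_miscategorized(asg(rep(c(1, 2), each = 20)), ids), 0)
  split1 <- c(rep(1, 19), 2, rep(2, 20))
  expect_equal(count_miscategorized(asg(split1), ids), 1)
  # tie broken toward the lower cluster id
  tie <- c(rep(1, 10), rep(2, 10), rep(3, 20))
  expect_equal(count_miscategorized(asg(tie), ids), 10)
})

test_that("ANOVA with Tukey-Kramer matches the hand-computed oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(20, 21, 22))
  # oracle: group means 2, 3, 21; MSE = 1 on 6 df; F = MSB / MSE = 343
  cmp <- anova_tukey(groups)
  expect_equal(cmp$F_statistic, 343, tolerance = 1e-9)
  expect_setequal(cmp$significant_pairs, c("c-a", "c-b"))
  expect_lt(cmp$p_value, 0.001)

  # identical groups: F ~ 0, nothing significant
  same <- list(x = c(1, 2, 3), y = c(1, 2, 3))
  cmp0 <- anova_tukey(same)
  expect_equal(cmp0$F_statistic, 0, tolerance = 1e-12)
  expect_length(cmp0$significant_pairs, 0)

  # permuting group order permutes but does not change the significant set
  cmpP <- anova_tukey(groups[c(3, 1, 2)])
  norm_pair <- function(p) vapply(strsplit(p, "-"), function(q)
    paste(sort(q), collapse = "|"), "")
  expect_setequal(norm_pair(cmpP$significant_pairs),
                  norm_pair(cmp$significant_pairs))
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "at least 2 values")
})
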