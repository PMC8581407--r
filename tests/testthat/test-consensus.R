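# two tight, well-separated clouds in 5-d used by several blocks
two_clouds <- function(n_per = 10, gap = 20, sd = 0.3, seed = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 5, 0, sd), n_per, 5),
             matrix(rnorm(n_per * 5, gap, sd), n_per, 5))
  rownames(x) <- paste0("S", seq_len(2 * n_per))
  x
}

test_that("perfect separation gives a 0/1 consensus matrix at K = 2", {
  x <- two_clouds()
  cc <- consensus_cluster(x, k_range = 2, resamples = 50, seed = 3)
  M <- cc$consensus[["2"]]
  truth <- rep(1:2, each = 10)
  within <- M[outer(truth, truth, "==")]
  between <- M[outer(truth, truth, "!=")]
  expect_true(all(within[!is.na(within)] == 1))
  expect_true(all(between[!is.na(between)] == 0))
})

test_that("consensus entries are frequencies: symmetric, in [0,1], unit diagonal", {
  x <- two_clouds(n_per = 12, gap = 3, sd = 1, seed = 6)
  cc <- consensus_cluster(x, k_range = 2:4, resamples = 40, seed = 8)
  for (k in names(cc$consensus)) {
    M <- cc$consensus[[k]]
    expect_true(all(M >= 0 & M <= 1, na.rm = TRUE))
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 1, na.rm = TRUE))
  }
})

test_that("same seed reproduces the consensus result exactly", {
  x <- two_clouds(n_per = 8, gap = 4, sd = 1, seed = 5)
  a <- consensus_cluster(x, k_range = 2:3, resamples = 30, seed = 42)
  b <- consensus_cluster(x, k_range = 2:3, resamples = 30, seed = 42)
  expect_identical(a, b)
})

test_that("consensus matrix equals a naive recomputation from the resample log", {
  x <- two_clouds(n_per = 15, gap = 2.5, sd = 1, seed = 9)
  cc <- consensus_cluster(x, k_range = 2:3, resamples = 50, seed = 7,
                          keep_log = TRUE)
  n <- nrow(x)
  for (k in c(2L, 3L)) {
    num <- den <- matrix(0, n, n)
    for (entry in cc$log) {
      idx <- entry$idx
      lab <- entry$assignments[[as.character(k)]]
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          den[idx[a], idx[b]] <- den[idx[a], idx[b]] + 1
          if (lab[a] == lab[b]) num[idx[a], idx[b]] <- num[idx[a], idx[b]] + 1
        }
      }
    }
    oracle <- num / den
    oracle[den == 0] <- NA
    diag(oracle)[diag(den) > 0] <- 1
    expect_equal(unname(cc$consensus[[as.character(k)]]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("consensus guards K against sample count and distinct points", {
  x <- two_clouds(n_per = 4, seed = 1)
  expect_error(consensus_cluster(x, k_range = 2:5, resamples = 5), "n/3")
  y <- matrix(rep(c(0, 1), each = 10), 20, 1)
  rownames(y) <- paste0("S", 1:20)
  expect_error(consensus_cluster(y, k_range = 2:3, resamples = 5), "distinct")
})

test_that("silhouette widths match a brute-force pairwise computation", {
  set.seed(12)
  x <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(paste0("S", 1:12), NULL))
  labels <- rep(1:3, each = 4)
  sw <- silhouette_width(x, labels)
  d <- as.matrix(dist(x))
  for (i in 1:12) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(d[i, own])
    b <- min(sapply(setdiff(1:3, labels[i]), function(cl) mean(d[i, labels == cl])))
    expect_equal(unname(sw$widths[i]), (b - a) / max(a, b), tolerance = 1e-9)
  }
  # cross-check against the cluster package's reference implementation
  ref <- cluster::silhouette(labels, dist(x))
  expect_equal(unname(sw$widths), unname(ref[, "sil_width"]), tolerance = 1e-9)
  # tight clusters far apart approach 1; labels invariant to renaming
  y <- rbind(matrix(0, 2, 2), matrix(100, 2, 2))
  rownames(y) <- paste0("S", 1:4)
  expect_gt(silhouette_width(y + rnorm(8, 0, 1e-6), c(1, 1, 2, 2))$average, 0.99)
  sw2 <- silhouette_width(x, c("b", "c", "a")[labels])
  expect_equal(sw2$widths, sw$widths)
  expect_error(silhouette_width(x, rep(1, 12)), "2 clusters")
})

test_that("select_k recovers planted K and is deterministic", {
  cohort <- default_cohort()
  sm <- default_scores()
  # three planted clusters: subset the cohort to planted 1, 3, 6
  keep <- cohort$true_labels %in% c(1, 3, 6)
  cc3 <- consensus_cluster(sm$scores[keep, ], k_range = 2:8, resamples = 100,
                           seed = 7)
  k3 <- select_k(cc3)
  expect_identical(as.integer(k3), 3L)
  expect_equal(ari(consensus_labels(cc3, k3), cohort$true_labels[keep]), 1)
  expect_identical(as.integer(select_k(cc3)), as.integer(k3))  # deterministic
  trace <- attr(k3, "trace")
  expect_true(all(c("k", "delta_area", "silhouette", "qualifies") %in% names(trace)))
})

test_that("null structure takes the silhouette-argmax fallback with a warning", {
  cfg <- synthetic_config(seed = 5, delta_high = 0, delta_low = 0,
                          samples_per_cluster = rep(30L, 6))
  sm <- score_matrix(generate_cohort(cfg)$expr, default_scheme())
  cc <- consensus_cluster(sm, k_range = 2:5, resamples = 40, seed = 5)
  expect_warning(k <- select_k(cc), "argmax silhouette")
  expect_identical(as.integer(k), cc$k_range[which.max(cc$silhouette_avg)])
})

test_that("higher noise lowers the silhouette at the planted K", {
  sils <- sapply(c(0.7, 2.5), function(noise) {
    mean(sapply(1:3, function(s) {
      cfg <- synthetic_config(seed = s, noise_sd = noise,
                              samples_per_cluster = rep(25L, 6))
      cohort <- generate_cohort(cfg)
      sm <- score_matrix(cohort$expr, default_scheme())
      silhouette_width(sm, cohort$true_labels)$average
    }))
  })
  expect_gt(sils[1], sils[2])
})

test_that("semantic labels follow the centroid pattern and survive renumbering", {
  # centroids built directly from the six-cluster score pattern
  set.seed(31)
  pattern <- rbind(
    c(-1.5, -0.6, -0.6, -1.5, -0.6),
    c(-1.5, -0.6,  0.0,  1.5,  0.0),
    c( 0.0,  1.5,  0.0,  0.0, -0.6),
    c( 0.0, -0.6,  0.6,  0.0,  1.5),
    c( 1.5,  0.6,  0.0,  0.6, -1.5),
    c( 1.5,  0.6,  0.6,  0.6,  1.5))
  colnames(pattern) <- c("IC", "CASP1", "GSDMD", "IL1B", "IL18")
  labels <- rep(1:6, each = 5)
  x <- pattern[labels, ] + matrix(rnorm(30 * 5, 0, 0.05), 30, 5)
  colnames(x) <- colnames(pattern)
  lab <- label_clusters(x, labels)
  expect_identical(lab$semantic,
                   c("IC^Low IL1B^Low", "IC^Low IL1B^High", "IC^Mid CASP1^High",
                     "IC^Mid IL18^High", "IC^High IL18^Low", "IC^High IL18^High"))
  # permuting the input numbering leaves per-sample semantic names unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  lab_p <- label_clusters(x, perm[labels])
  expect_identical(attr(lab_p, "sample_semantic"), attr(lab, "sample_semantic"))
  expect_identical(attr(lab_p, "sample_labels"), attr(lab, "sample_labels"))
})

test_that("non-six K yields numeric labels only", {
  set.seed(13)
  x <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, c("IC", "CASP1", "GSDMD", "IL1B", "IL18")))
  expect_message(lab <- label_clusters(x, rep(1:4, each = 10)), "K = 6")
  expect_true(all(is.na(lab$semantic)))
  expect_setequal(attr(lab, "sample_labels"), 1:4)
})
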