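test_that("hypergeometric p matches exhaustive enumeration at N = 20", {
  # cohort of 20: 8 of the type, cluster of 5 holding 4 of them
  types <- rep(c("A", "B"), c(8, 12))
  clusters <- rep(2, 20)
  clusters[c(1, 2, 3, 4, 9)] <- 1  # overlap k = 4, cluster size 5
  res <- hypergeom_enrichment(clusters, types)
  row <- res[res$tumor_type == "A" & res$cluster == 1, ]
  expect_identical(row$overlap, 4L)
  # oracle: enumerate all C(20,5) cluster draws, count those with >= 4 type-A
  draws <- combn(20, 5)
  k_draw <- colSums(matrix(draws %in% 1:8, nrow = 5))
  expect_equal(row$p, mean(k_draw >= 4), tolerance = 1e-9)
})

test_that("hypergeometric edge cases: zero overlap and whole-cohort cluster", {
  types <- rep(c("A", "B"), c(5, 15))
  clusters <- rep(c(1, 2), c(15, 5))  # cluster 2 holds no type-A samples
  res <- hypergeom_enrichment(clusters, types)
  expect_equal(res$p[res$tumor_type == "A" & res$cluster == 2], 1)
  # a cluster spanning the whole cohort draws everything: p = 1
  res2 <- hypergeom_enrichment(rep(1, 20), types)
  expect_true(all(res2$p == 1))
  expect_warning(hypergeom_enrichment(clusters, rep("A", 20)), "single tumor type")
})

test_that("hypergeometric p is non-increasing in the overlap", {
  ps <- sapply(0:5, function(k) phyper(k - 1, 8, 12, 5, lower.tail = FALSE))
  expect_true(all(diff(ps) <= 0))
  # and BH preserves order while never decreasing p
  set.seed(20)
  types <- sample(paste0("T", 1:4), 60, replace = TRUE)
  clusters <- sample(1:3, 60, replace = TRUE)
  res <- hypergeom_enrichment(clusters, types)
  expect_true(all(res$fdr >= res$p))
  expect_true(all(diff(res$fdr[order(res$p)]) >= -1e-12))
})

test_that("generator enrichment design is flagged and only it", {
  cohort <- default_cohort()
  res <- hypergeom_enrichment(cohort$true_labels, cohort$tumor_types)
  hits <- res[res$fdr < 0.05, c("tumor_type", "cluster")]
  # design: cluster k over-samples type Tk (k = 1..6); T7, T8 are background
  expect_setequal(paste(hits$tumor_type, hits$cluster),
                  paste(paste0("T", 1:6), 1:6))
})

test_that("chi-square screen equals the closed-form 2x2 statistic", {
  labels <- rep(c(1, 2), each = 50)
  feat <- cbind(F1 = c(rep(1, 50), rep(0, 50)))
  res <- chisq_feature_screen(labels, feat)
  # closed form n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on the 2x2 table
  a <- 50; b <- 0; cc <- 0; d <- 50
  stat <- 100 * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  r1 <- res[res$cluster == 1, ]
  expect_equal(r1$statistic, stat, tolerance = 1e-9)
  expect_equal(r1$effect, 1)
  expect_false(r1$exact)
})

test_that("chi-square screen handles no-association, 0/1 swap, and degenerate columns", {
  set.seed(21)
  labels <- rep(c(1, 2), each = 40)
  f <- rep(c(1, 0), 40)  # identical frequency in and out
  res <- chisq_feature_screen(labels, cbind(F1 = f))
  expect_equal(res$statistic[1], 0, tolerance = 1e-12)
  # swapping 0/1 leaves the statistic unchanged
  res_sw <- chisq_feature_screen(labels, cbind(F1 = 1 - f))
  expect_equal(res_sw$statistic, res$statistic)
  # constant columns are skipped with a notice
  expect_message(res2 <- chisq_feature_screen(labels, cbind(F1 = f, F2 = rep(0, 80))),
                 "constant")
  expect_setequal(unique(res2$feature), "F1")
  expect_error(suppressMessages(chisq_feature_screen(labels, cbind(F = rep(0, 80)))),
               "no testable")
  expect_error(chisq_feature_screen(labels, cbind(F = rep(2, 80))), "binary")
})

test_that("sparse tables fall back to the exact test and are flagged", {
  labels <- rep(c(1, 2), c(6, 60))
  feat <- cbind(RARE = c(rep(1, 3), rep(0, 63)))
  res <- chisq_feature_screen(labels, feat)
  r1 <- res[res$cluster == 1, ]
  expect_true(r1$exact)
  tab <- rbind(c(3, 3), c(0, 60))
  expect_equal(r1$p, fisher.test(tab)$p.value, tolerance = 1e-9)
})

test_that("planted program genes are called up in their cluster at coding thresholds", {
  cohort <- default_cohort()
  scheme <- default_scheme()
  de <- diff_expression_one_vs_rest(cohort$expr, cohort$true_labels, "coding")
  il18_up <- scheme$scores$IL18$positive$members
  calls <- de[de$cluster == 6 & de$feature %in% il18_up, ]
  expect_true(all(calls$significant))
  expect_true(all(calls$effect > 1))
})

test_that("differential expression respects per-class thresholds", {
  set.seed(22)
  v <- matrix(rnorm(40 * 24, 5, 0.3), 40, 24,
              dimnames = list(paste0("g", 1:40), paste0("S", 1:24)))
  labels <- rep(c(1, 2), each = 12)
  v["g1", labels == 1] <- v["g1", labels == 1] + 1.5  # logFC ~ 1.5
  expr <- expression_matrix(v)
  lnc <- diff_expression_one_vs_rest(expr, labels, "lncRNA")
  g1 <- lnc[lnc$feature == "g1" & lnc$cluster == 1, ]
  expect_lt(g1$fdr, 0.01)
  expect_false(g1$significant)  # lncRNA needs |logFC| > 2
  cod <- diff_expression_one_vs_rest(expr, labels, "coding")
  expect_true(cod[cod$feature == "g1" & cod$cluster == 1, "significant"])
  # constant gene: p = 1, effect 0
  v2 <- v; v2["g2", ] <- 3
  de2 <- diff_expression_one_vs_rest(expression_matrix(v2), labels, "coding")
  expect_true(all(de2[de2$feature == "g2", "p"] == 1))
  expect_true(all(de2[de2$feature == "g2", "effect"] == 0))
  expect_error(diff_expression_one_vs_rest(expr, rep(c(1, 2), c(2, 22))), ">= 3")
})

test_that("label permutation keeps the false-positive rate at nominal level", {
  set.seed(23)
  genes <- paste0("G", 1:200)
  v <- matrix(rnorm(200 * 120, 5, 1), 200, 120,
              dimnames = list(genes, paste0("S", 1:120)))
  expr <- expression_matrix(v)
  fr <- vapply(1:100, function(p) {
    labs <- sample(rep(c(1, 2), c(20, 100)))
    de <- diff_expression_one_vs_rest(expr, labs, "coding")
    mean(de$p[de$cluster == 1] < 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (200 * 100))
  expect_gt(mean(fr), 0.05 - 3 * se)
  expect_lt(mean(fr), 0.05 + 3 * se)
})

test_that("tumor-map similarity follows 1/(1+d) with its invariants", {
  # printed arithmetic: d = 0 -> 1, d = 1 -> 0.5, d = 3 -> 0.25
  x <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 3))
  S <- tumor_map_similarity(x)
  expect_equal(S["a", "a"], 1)
  expect_equal(S["a", "b"], 0.5)
  expect_equal(S["a", "c"], 0.25)
  # oracle: loop-based pairwise distances on a random score matrix
  set.seed(24)
  y <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("S", 1:10), NULL))
  Sy <- tumor_map_similarity(y)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(Sy[i, j], 1 / (1 + sqrt(sum((y[i, ] - y[j, ])^2))),
                 tolerance = 1e-9)
  }
  expect_identical(Sy, t(Sy))
  expect_true(all(Sy > 0 & Sy <= 1))
  expect_true(all((Sy == 1) == (as.matrix(dist(y)) == 0)))
})

test_that("log-rank statistic matches hand-tabulated risk sets on an 8-subject toy", {
  # group 1: deaths at 1, 3; censored 5, 7.  group 2: deaths at 2, 4; censored 6, 8
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 0, 0, 1, 1, 0, 0)
  grp <- rep(c(1, 2), each = 4)
  res <- survival_contrasts(grp, time, event)
  # hand computation: at each death time, O - E for group 1 and the variance
  d <- data.frame(t = c(1, 2, 3, 4), dead_g1 = c(1, 0, 1, 0))
  oe <- 0; v <- 0
  for (i in seq_len(nrow(d))) {
    at_risk <- time >= d$t[i]
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    oe <- oe + d$dead_g1[i] - n1 / n
    v <- v + (n1 / n) * (1 - n1 / n)  # single death per time: no tie factor
  }
  expect_equal(res$logrank$chisq, oe^2 / v, tolerance = 1e-9)
  expect_equal(res$logrank$p, pchisq(oe^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("identical survival distributions give statistic 0 and the HR table masks ns pairs", {
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  grp <- rep(c(1, 2), each = 4)
  res <- survival_contrasts(grp, time, event)
  expect_equal(res$logrank$chisq, 0, tolerance = 1e-9)
  expect_true(all(is.na(res$pairwise$hr_shown)))
  expect_error(survival_contrasts(grp, time, rep(0, 8)), "no events")
  expect_error(survival_contrasts(grp, c(time[-1], -1), event), "positive")
})

test_that("planted hazard structure yields HR(cluster 6 vs 1) > 1 and log-rank signal", {
  cohort <- default_cohort()
  res <- survival_contrasts(cohort$true_labels, cohort$survival$time,
                            cohort$survival$event)
  expect_lt(res$logrank$p, 0.05)
  hr61 <- res$pairwise[res$pairwise$row_cluster == 6 & res$pairwise$col_cluster == 1, ]
  expect_gt(hr61$hr, 1)
  # orientation check: the reciprocal pair inverts the hazard ratio
  hr16 <- res$pairwise[res$pairwise$row_cluster == 1 & res$pairwise$col_cluster == 6, ]
  expect_equal(hr61$hr, 1 / hr16$hr, tolerance = 1e-6)
})
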