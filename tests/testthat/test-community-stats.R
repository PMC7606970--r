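two_cluster_dm <- function(n_per = 5, sep = 10) {
  withr::with_seed(41, {
    xy <- rbind(matrix(rnorm(n_per * 2, 0, 0.1), ncol = 2),
                matrix(rnorm(n_per * 2, sep, 0.1), ncol = 2))
  })
  dm <- as.matrix(dist(xy))
  rownames(dm) <- colnames(dm) <- paste0("s", seq_len(2 * n_per))
  dm
}

test_that("PERMANOVA separates clusters and agrees with vegan on the pseudo-F", {
  # groups large enough that no random permutation recreates the partition
  dm <- two_cluster_dm(n_per = 10)
  grp <- rep(c("a", "b"), each = 10)
  res <- permanova(dm, grp, n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)   # maximal separation: no permutation beats it
  expect_gt(res$f, 100)

  # observed pseudo-F equals vegan::adonis2 on random data
  withr::with_seed(42, tab <- random_count_table(12, 8))
  dmr <- bray_curtis(tab)
  grp2 <- rep(c("x", "y", "z"), each = 4)
  ours <- permanova(dmr, grp2, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(dmr) ~ g,
                        data = data.frame(g = grp2), permutations = 99)
  expect_equal(ours$f, ref$F[1], tolerance = 1e-10)

  expect_error(permanova(dm, c("a", rep("b", 19)), n_perm = 99),
               "at least two")
})

test_that("duplicating every sample does not reduce the observed pseudo-F", {
  withr::with_seed(43, tab <- random_count_table(10, 6))
  dm <- bray_curtis(tab)
  grp <- rep(c("a", "b"), 5)
  f1 <- permanova(dm, grp, n_perm = 99, seed = 1)$f
  idx <- rep(seq_len(10), 2)
  dm2 <- dm[idx, idx]
  rownames(dm2) <- colnames(dm2) <- paste0("d", seq_len(20))
  f2 <- permanova(dm2, rep(grp, 2), n_perm = 99, seed = 1)$f
  expect_gte(f2, f1)
})

test_that("PERMANOVA p-values are deterministic under a seed", {
  dm <- two_cluster_dm(4, 1)
  grp <- rep(c("a", "b"), each = 4)
  expect_identical(permanova(dm, grp, n_perm = 199, seed = 5),
                   permanova(dm, grp, n_perm = 199, seed = 5))
})

test_that("group alpha test is the tie-corrected Kruskal-Wallis", {
  # identical value sets in both groups
  res <- group_alpha_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p, 1)
  # maximal rank separation at n = 6: H = 27/7 = 3.857...
  res <- group_alpha_test(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(res$h, 27 / 7, tolerance = 1e-12)
  # rank-based: invariant under monotone transforms
  v <- c(3, 9, 1, 27, 81, 5, 12, 2)
  g <- rep(c("a", "b"), 4)
  expect_equal(group_alpha_test(v, g)$h, group_alpha_test(log(v), g)$h)
  # matches the hand rank formula with ties
  withr::with_seed(44, vt <- sample(1:5, 12, replace = TRUE))
  gt <- rep(c("a", "b", "c"), 4)
  expect_equal(group_alpha_test(vt, gt)$h, kw_oracle(vt, gt),
               tolerance = 1e-10)
  # identical values across the board: H = 0, p = 1
  expect_equal(group_alpha_test(rep(2, 6), rep(c("a", "b"), 3)),
               list(h = 0, p = 1, df = 1))
})

test_that("ANCOM W counts rejected pairwise log-ratio tests", {
  # one taxon multiplied 10x in group A attains W = 2 of 2 with 3 taxa
  withr::with_seed(45, {
    base <- matrix(rpois(20 * 3, 100), 20, 3,
                   dimnames = list(paste0("s", 1:20), c("up", "t2", "t3")))
  })
  grp <- rep(c("A", "B"), each = 10)
  tab <- base
  tab[grp == "A", "up"] <- tab[grp == "A", "up"] * 10L
  res <- ancom(tab, grp)
  expect_equal(res$w[res$taxon == "up"], 2L)
  expect_true(all(res$w <= ncol(tab) - 1))
  expect_true(res$flagged[res$taxon == "up"])

  expect_error(ancom(tab[, 1, drop = FALSE], grp), "two taxa")
  tab0 <- cbind(tab, zero = 0L)
  expect_error(ancom(tab0, grp), "all-zero")
})

test_that("ANCOM equals brute-force enumeration on small random tables", {
  withr::with_seed(46, {
    for (i in 1:10) {
      k <- sample(3:6, 1)
      tab <- random_count_table(16, k, max_count = 200)
      grp <- rep(c("A", "B"), each = 8)
      # add a real shift for some tables so both regimes are exercised
      if (i %% 2 == 0) tab[grp == "A", 1] <- tab[grp == "A", 1] * 5L
      expect_equal(ancom(tab, grp)$w, ancom_oracle(tab, grp))
    }
  })
})

test_that("ANCOM stays quiet on exchangeable groups", {
  withr::with_seed(47, {
    flags <- sapply(1:10, function(i) {
      tab <- matrix(rpois(24 * 5, 80), 24, 5,
                    dimnames = list(paste0("s", 1:24), paste0("t", 1:5)))
      sum(ancom(tab, rep(c("A", "B"), each = 12))$flagged)
    })
  })
  expect_lte(mean(flags), 0.1)
})

test_that("slice standardisation divides by the within-slice taxon mean", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.5, 0.5, 0.5, 0, 0, 0), 3,
              dimnames = list(paste0("s", 1:3), c("t1", "t2", "t3")))
  std <- slice_standardize(m, rep("sliceA", 3))
  expect_equal(unname(std[, "t1"]), c(0.5, 1.0, 1.5))
  expect_equal(unname(std[, "t2"]), c(1, 1, 1))
  expect_true(all(is.na(std[, "t3"])))

  # within-slice means are exactly 1 wherever the slice mean is positive
  withr::with_seed(48, {
    rel <- random_count_table(12, 6)
    rel <- rel / rowSums(rel)
    sl <- rep(c("x", "y", "z"), each = 4)
    std <- slice_standardize(rel, sl)
    for (lev in unique(sl)) {
      mu <- colMeans(std[sl == lev, , drop = FALSE])
      expect_equal(unname(mu[!is.na(mu)]),
                   rep(1, sum(!is.na(mu))), tolerance = 1e-12)
    }
  })
})

test_that("position tests pair on slice and flag degenerate contrasts", {
  md <- expand.grid(slice = paste0("L", 1:4), position = c("top", "middle"),
                    stringsAsFactors = FALSE)
  ids <- paste(md$slice, md$position, sep = ".")
  base <- c(1, 1.2, 0.9, 1.1)
  # identical positions: t = 0, p = 1
  m <- matrix(c(base, base), ncol = 1,
              dimnames = list(ids, "taxon1"))
  res <- position_test(m, stats::setNames(md$position, ids),
                       stats::setNames(md$slice, ids))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # constant positive difference with zero variance: degenerate, p -> 0
  m2 <- matrix(c(base + 0.5, base), ncol = 1, dimnames = list(ids, "taxon1"))
  res2 <- position_test(m2, stats::setNames(md$position, ids),
                        stats::setNames(md$slice, ids))
  expect_equal(res2$p, 0)
  expect_equal(res2$mean_diff, 0.5)
  expect_match(res2$note, "degenerate")

  # fewer than two complete pairs: skipped with a notice
  m3 <- m2[c(1, 5), , drop = FALSE]
  res3 <- position_test(m3, stats::setNames(md$position[c(1, 5)], ids[c(1, 5)]),
                        stats::setNames(md$slice[c(1, 5)], ids[c(1, 5)]))
  expect_true(is.na(res3$p))
  expect_match(res3$note, "pairs")
})

test_that("distance trends report Spearman, paired halves and smoothed curves", {
  ids <- paste0("s", 1:8)
  d <- stats::setNames(c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4), ids)
  inc <- matrix(seq(0.1, 0.8, 0.1), ncol = 1, dimnames = list(ids, "t1"))
  res <- distance_trend(inc, d, slices = rep(c("a", "b"), 4))
  expect_equal(res$tests$rho, 1)
  expect_true("t1" %in% names(res$curves))

  cst <- matrix(rep(1, 8), ncol = 1, dimnames = list(ids, "t1"))
  res2 <- distance_trend(cst, d, slices = rep(c("a", "b"), 4))
  expect_true(is.na(res2$tests$rho))

  # null calibration: independent abundance rejects at about the alpha level
  withr::with_seed(49, {
    p <- replicate(200, {
      dd <- runif(20, 0.5, 4)
      v <- matrix(rnorm(20), ncol = 1,
                  dimnames = list(paste0("s", 1:20), "t"))
      suppressWarnings(
        distance_trend(v, stats::setNames(dd, rownames(v)))$tests$p_spearman)
    })
  })
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("scale classes partition pairs by the finest shared level", {
  des <- design_spec(2, 2, 2, 1, reads_per_sample = 500, n_taxa = 4)
  md <- generate_metadata(des, seed = 7)
  ps <- pair_scales(md)
  n <- nrow(md)
  expect_equal(nrow(ps), n * (n - 1) / 2)
  # every cross-region pair is at the 20 km scale; count is the product of
  # per-region sample counts
  n_per_region <- table(md$region)
  expect_equal(sum(ps$scale == "20 km"),
               unname(n_per_region[1] * n_per_region[2]))
  cross <- md$region[match(ps$a, md$sample_id)] !=
    md$region[match(ps$b, md$sample_id)]
  expect_true(all(ps$scale[cross] == "20 km"))
  expect_true(all(ps$scale[!cross] != "20 km"))

  # n samples in one nodule-position class give n(n-1)/2 pairs at 3 cm
  des2 <- design_spec(1, 1, 1, 4, positions = "top",
                      reads_per_sample = 500, n_taxa = 4)
  md2 <- generate_metadata(des2, seed = 1)
  ps2 <- pair_scales(md2)
  expect_equal(sum(ps2$scale == "3 cm"), 4 * 3 / 2)

  # degenerate single-sample design: no pairs
  md1 <- generate_metadata(design_spec(1, 1, 1, 1, positions = "top",
                                       reads_per_sample = 500, n_taxa = 4))
  expect_equal(nrow(pair_scales(md1)), 0)
})

test_that("scale decay pools dissimilarities per class and tests neighbours", {
  des <- design_spec(2, 1, 2, 2, reads_per_sample = 1000, n_taxa = 6)
  md <- generate_metadata(des, seed = 3)
  # identical samples: every class at 0, adjacent tests p = 1
  n <- nrow(md)
  dm0 <- matrix(0, n, n, dimnames = list(md$sample_id, md$sample_id))
  res <- scale_decay(dm0, md)
  expect_true(all(res$summary$mean[res$summary$n_pairs > 0] == 0))
  expect_true(all(res$adjacent_tests$p == 1))
  # classes partition all pairs
  expect_equal(sum(res$summary$n_pairs) + res$n_excluded, n * (n - 1) / 2)
})

test_that("replicate dissimilarity summarises the technical noise floor", {
  dm <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  dm["s1", "s2"] <- dm["s2", "s1"] <- 0.09
  dm["s3", "s4"] <- dm["s4", "s3"] <- 0.105
  dm["s5", "s6"] <- dm["s6", "s5"] <- 0.12
  pairs <- cbind(c("s1", "s3", "s5"), c("s2", "s4", "s6"))
  res <- replicate_dissimilarity(dm, pairs)
  expect_equal(res$mean, 0.105)
  expect_equal(res$n_pairs, 3)

  single <- replicate_dissimilarity(dm, pairs[1, , drop = FALSE])
  expect_true(is.na(single$sd))
  # identical samples: 0 +/- 0
  same <- replicate_dissimilarity(dm, cbind("s1", "s3"))
  expect_equal(same$mean, 0)
  expect_error(replicate_dissimilarity(dm, pairs[0, , drop = FALSE]), "pairs")
})
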