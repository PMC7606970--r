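#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F from a dissimilarity matrix: total sum of squares
#' `SST = sum_{i<j} d_ij^2 / n`, within-group
#' `SSW = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `F = (SSA / (a - 1)) / (SSW / (n - a))` with `SSA = SST - SSW`. The
#' p-value is obtained by freely permuting sample labels:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Deterministic under
#' `seed`. Labels are permuted without strata, matching one-way use on
#' site/position groupings.
#'
#' @param dm symmetric dissimilarity matrix with sample ids.
#' @param groups group label per sample (named by sample id, or positional).
#' @param n_perm number of permutations (at least 99).
#' @param seed integer seed.
#' @return list: `f` (pseudo-F), `p`, `n_perm`, `df` (between, within).
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  .check_dissimilarity(dm)
  stopifnot(n_perm >= 99)
  groups <- factor(.align_labels(groups, rownames(dm)))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  d2 <- dm^2
  n <- nrow(dm)
  a <- nlevels(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  fstat <- function(g) {
    ssw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat(groups)
  count <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) fstat(sample(groups)) >= f_obs, logical(1)))
  })
  list(f = f_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm,
       df = c(between = a - 1, within = n - a))
}

#' Kruskal-Wallis test of an alpha-diversity metric between groups
#'
#' Rank-based comparison (with tie correction, via [stats::kruskal.test()])
#' of a per-sample quantity across two or more groups. When every value is
#' identical the statistic is 0 and p is 1 (no evidence against exchange).
#'
#' @param values per-sample numeric vector (named by sample id or
#'   positional with respect to `groups`).
#' @param groups group label per sample.
#' @return list: `h` (chi-squared approximation statistic), `p`, `df`.
#' @export
group_alpha_test <- function(values, groups) {
  if (!is.null(names(values))) groups <- .align_labels(groups, names(values))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(unique(values)) == 1) {
    return(list(h = 0, p = 1, df = nlevels(groups) - 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(h = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' ANCOM compositional differential-abundance test
#'
#' For every ordered taxon i, the additive log-ratio
#' `log((x_i + pseudocount) / (x_j + pseudocount))` against every other
#' taxon j is tested for a group difference; `W_i` counts how many of those
#' `n_taxa - 1` hypotheses are rejected after Benjamini-Hochberg correction
#' within taxon i's family. A high W means taxon i shifts against most of
#' the composition, which is robust to the compositional constraint. Taxa
#' with `W >= cutoff * (n_taxa - 1)` are flagged.
#'
#' @param table samples x taxa count matrix (drop all-zero taxa first).
#' @param groups group label per sample (2 or more groups).
#' @param alpha per-family significance level for the corrected tests.
#' @param test `"t"` (two-group t-test / k-group one-way ANOVA) or
#'   `"wilcox"` (Mann-Whitney / Kruskal-Wallis).
#' @param cutoff W fraction of `n_taxa - 1` above which a taxon is flagged.
#' @param pseudocount added to counts before the log-ratio.
#' @return data.frame of class `ancom_result`: `taxon`, `w`, `flagged`.
#' @export
ancom <- function(table, groups, alpha = 0.05, test = c("t", "wilcox"),
                  cutoff = 0.7, pseudocount = 1) {
  test <- match.arg(test)
  .check_count_table(table)
  if (ncol(table) < 2) stop("ANCOM needs at least two taxa")
  if (any(colSums(table) == 0)) {
    stop("remove all-zero taxa before running ANCOM")
  }
  groups <- factor(.align_labels(groups, rownames(table)))
  if (nlevels(groups) < 2) stop("need at least two groups")
  lx <- log(table + pseudocount)
  k <- ncol(table)
  pair_p <- function(v) {
    if (length(unique(v)) == 1) return(1)
    if (nlevels(groups) == 2) {
      if (test == "t") {
        sp <- split(v, groups)
        if (stats::var(sp[[1]]) == 0 && stats::var(sp[[2]]) == 0) {
          return(if (mean(sp[[1]]) == mean(sp[[2]])) 1 else 0)
        }
        stats::t.test(v ~ groups)$p.value
      } else {
        stats::wilcox.test(v ~ groups, exact = FALSE)$p.value
      }
    } else {
      if (test == "t") {
        stats::anova(stats::lm(v ~ groups))[["Pr(>F)"]][1]
      } else {
        stats::kruskal.test(v, groups)$p.value
      }
    }
  }
  w <- integer(k)
  for (i in seq_len(k)) {
    ps <- vapply(setdiff(seq_len(k), i),
                 function(j) pair_p(lx[, i] - lx[, j]), numeric(1))
    w[i] <- sum(stats::p.adjust(ps, "BH") < alpha)
  }
  structure(data.frame(taxon = colnames(table), w = w,
                       flagged = w >= cutoff * (k - 1)),
            class = c("ancom_result", "data.frame"))
}

#' Standardise relative abundances to the within-slice taxon mean
#'
#' Divides every entry by the mean relative abundance of that taxon over the
#' samples of the same slice, so each taxon's standardised values average
#' exactly 1 within each slice. This removes inter-nodule and inter-slice
#' variability and exposes the vertical (top/middle/bottom) structure. Taxa
#' absent from an entire slice give `NA` there, not infinities.
#'
#' @param rel_abund samples x taxa matrix of relative abundances (or
#'   counts; standardisation is scale-invariant within a slice only for
#'   equal sample totals, so pass relative abundances).
#' @param slices slice label per sample (named or positional).
#' @return matrix of standardised abundances, same shape, with attribute
#'   `slices`.
#' @export
slice_standardize <- function(rel_abund, slices) {
  stopifnot(is.matrix(rel_abund))
  slices <- factor(.align_labels(slices, rownames(rel_abund)))
  out <- rel_abund
  for (lev in levels(slices)) {
    idx <- which(slices == lev)
    mu <- colMeans(rel_abund[idx, , drop = FALSE])
    denom <- ifelse(mu > 0, mu, NA_real_)
    out[idx, ] <- sweep(rel_abund[idx, , drop = FALSE], 2, denom, "/")
  }
  attr(out, "slices") <- slices
  out
}

#' Per-taxon paired tests between vertical positions
#'
#' For each taxon, a two-sided t-test of the standardised abundance at
#' position `pair[1]` versus `pair[2]`, pairing observations on the slice
#' they came from (the classic Student's t-test on phylum abundances).
#' Slices lacking either position, or taxa with fewer than two complete
#' pairs, are skipped with a notice. Degenerate zero-variance differences
#' are flagged rather than given a fabricated p. An unpaired pooled-variance
#' test (or Welch) is available for site-level comparisons.
#'
#' @param std samples x taxa matrix (typically from [slice_standardize()]).
#' @param positions position label per sample.
#' @param slices slice (pairing) label per sample.
#' @param pair length-2 character: the two positions to contrast
#'   (difference is `pair[1] - pair[2]`).
#' @param paired pair on slice (default) or treat groups as independent.
#' @param var_equal pooled-variance t-test when unpaired (classic Student);
#'   `FALSE` gives Welch.
#' @return data.frame: `taxon`, `mean_diff`, `t`, `p`, `p_adj` (BH across
#'   taxa), `n_pairs`, `note`.
#' @export
position_test <- function(std, positions, slices = NULL,
                          pair = c("top", "middle"), paired = TRUE,
                          var_equal = TRUE) {
  stopifnot(is.matrix(std), length(pair) == 2)
  positions <- .align_labels(positions, rownames(std))
  if (paired) {
    if (is.null(slices)) slices <- attr(std, "slices")
    if (is.null(slices)) stop("paired tests need slice labels")
    slices <- .align_labels(slices, rownames(std))
  }
  res <- data.frame(taxon = colnames(std), mean_diff = NA_real_,
                    t = NA_real_, p = NA_real_, p_adj = NA_real_,
                    n_pairs = 0L, note = "")
  for (ti in seq_len(ncol(std))) {
    v <- std[, ti]
    if (paired) {
      ag <- function(pos) tapply(v[positions == pos], slices[positions == pos],
                                 mean, na.rm = TRUE)
      x <- ag(pair[1]); y <- ag(pair[2])
      common <- intersect(names(x), names(y))
      x <- x[common]; y <- y[common]
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      res$n_pairs[ti] <- length(x)
      if (length(x) < 2) {
        res$note[ti] <- "skipped: <2 complete pairs"
        next
      }
      d <- x - y
      res$mean_diff[ti] <- mean(d)
      if (.near_constant(d)) {
        res$t[ti] <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
        res$p[ti] <- if (mean(d) == 0) 1 else 0
        res$note[ti] <- if (mean(d) == 0) "" else "degenerate: zero-variance difference"
        next
      }
      tt <- stats::t.test(x, y, paired = TRUE)
    } else {
      x <- v[positions == pair[1]]; y <- v[positions == pair[2]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      res$n_pairs[ti] <- min(length(x), length(y))
      if (length(x) < 2 || length(y) < 2) {
        res$note[ti] <- "skipped: <2 observations per group"
        next
      }
      res$mean_diff[ti] <- mean(x) - mean(y)
      if (.near_constant(c(x - mean(x), y - mean(y)),
                         scale = max(abs(mean(x)), abs(mean(y)), 1e-300))) {
        res$t[ti] <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
        res$p[ti] <- if (mean(x) == mean(y)) 1 else 0
        res$note[ti] <- if (mean(x) == mean(y)) "" else "degenerate: zero-variance groups"
        next
      }
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    res$t[ti] <- unname(tt$statistic)
    res$p[ti] <- tt$p.value
  }
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res
}

#' Per-taxon trend of standardised abundance with distance to the surface
#'
#' For each taxon: Spearman rank correlation of standardised abundance with
#' the sample's shortest distance to the nodule surface; a paired two-sided
#' t-test contrasting the near-surface half (distance below
#' `near_threshold`) against the interior half, paired on slice when slice
#' labels are available; and a smoothed abundance-versus-distance curve
#' (order-0 local average, [kernel_smooth()]).
#'
#' @param std samples x taxa matrix from [slice_standardize()].
#' @param distance distance to the nearest surface per sample, cm.
#' @param slices optional slice labels for pairing (defaults to the
#'   attribute left by [slice_standardize()]).
#' @param near_threshold near-surface cut, cm.
#' @param bandwidth smoother bandwidth, cm. The default of 0.5 cm (half the
#'   width of a sampled position band) keeps the boundary bias of the
#'   order-0 kernel small at the edges of the sampled depth range; wider
#'   bandwidths visibly drag interior maxima toward the deep edge.
#' @return list: `tests` (data.frame: `taxon`, `rho`, `p_spearman`,
#'   `p_spearman_adj`, `interior_minus_near`, `p_paired`), `curves` (named
#'   list of smoothed data.frames).
#' @export
distance_trend <- function(std, distance, slices = NULL, near_threshold = 1.5,
                           bandwidth = 0.5) {
  stopifnot(is.matrix(std))
  distance <- .align_labels(distance, rownames(std))
  if (length(unique(distance)) < 4) stop("need at least 4 distinct distances")
  if (is.null(slices)) slices <- attr(std, "slices")
  near <- distance < near_threshold
  tests <- data.frame(taxon = colnames(std), rho = NA_real_,
                      p_spearman = NA_real_, p_spearman_adj = NA_real_,
                      interior_minus_near = NA_real_, p_paired = NA_real_)
  curves <- list()
  for (ti in seq_len(ncol(std))) {
    v <- std[, ti]
    ok <- is.finite(v)
    if (length(unique(v[ok])) > 1) {
      ct <- suppressWarnings(
        stats::cor.test(distance[ok], v[ok], method = "spearman"))
      tests$rho[ti] <- unname(ct$estimate)
      tests$p_spearman[ti] <- ct$p.value
      if (!is.null(slices)) {
        sl <- factor(slices[ok])
        xi <- tapply(v[ok][!near[ok]], droplevels(sl[!near[ok]]), mean)
        yi <- tapply(v[ok][near[ok]], droplevels(sl[near[ok]]), mean)
        common <- intersect(names(xi), names(yi))
        if (length(common) >= 2) {
          dd <- xi[common] - yi[common]
          tests$interior_minus_near[ti] <- mean(dd)
          tests$p_paired[ti] <- if (.near_constant(dd)) {
            if (mean(dd) == 0) 1 else 0
          } else {
            stats::t.test(xi[common], yi[common], paired = TRUE)$p.value
          }
        }
      }
      curves[[colnames(std)[ti]]] <-
        kernel_smooth(distance[ok], v[ok], bandwidth = bandwidth, degree = 0)
    }
  }
  tests$p_spearman_adj <- stats::p.adjust(tests$p_spearman, "BH")
  list(tests = tests, curves = curves)
}

#' Classify sample pairs into spatial-scale classes
#'
#' Assigns every sample pair to the finest nesting level it shares: same
#' nodule and position (~3 cm, e.g. along the horizontal axis of a nodule),
#' same nodule (~10 cm), same site but different nodule (~10 m), same region
#' but different site (~300 m), different region (~20 km). Pairs with any
#' missing label are excluded and counted.
#'
#' @param metadata data.frame with columns `sample_id`, `region`, `site`,
#'   `nodule`, `position`.
#' @return data.frame: `a`, `b` (sample ids), `scale` (ordered factor).
#'   Attribute `n_excluded` counts pairs dropped for incomplete labels.
#' @export
pair_scales <- function(metadata) {
  need <- c("sample_id", "region", "site", "nodule", "position")
  stopifnot(all(need %in% names(metadata)))
  n <- nrow(metadata)
  if (n < 2) {
    out <- data.frame(a = character(0), b = character(0),
                      scale = factor(character(0), levels = .scale_levels))
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- function(col) !is.na(metadata[[col]][i]) &
    !is.na(metadata[[col]][j]) & metadata[[col]][i] == metadata[[col]][j]
  complete <- stats::complete.cases(metadata[need])
  keep <- complete[i] & complete[j]
  sr <- same("region"); ss <- sr & same("site")
  sn <- ss & same("nodule"); sp <- sn & same("position")
  scale <- ifelse(sp, "3 cm",
           ifelse(sn, "10 cm",
           ifelse(ss, "10 m",
           ifelse(sr, "300 m", "20 km"))))
  out <- data.frame(a = metadata$sample_id[i][keep],
                    b = metadata$sample_id[j][keep],
                    scale = factor(scale[keep], levels = .scale_levels))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

.scale_levels <- c("3 cm", "10 cm", "10 m", "300 m", "20 km")

#' Distance-scale decay of community similarity
#'
#' Pools all pairwise dissimilarities by spatial-scale class (see
#' [pair_scales()]) and tests adjacent classes against each other with
#' two-sided Student's t-tests, the comparison behind the
#' dissimilarity-versus-distance-scale boxplots.
#'
#' @param dm dissimilarity matrix over the metadata's samples.
#' @param metadata sample metadata with nesting labels (see [pair_scales()]).
#' @return list of class `scale_decay`: `values` (data.frame `a`, `b`,
#'   `scale`, `dissimilarity`), `summary` (per-class n/mean/sd),
#'   `adjacent_tests` (data.frame of adjacent-class t-tests),
#'   `n_excluded`.
#' @export
scale_decay <- function(dm, metadata) {
  .check_dissimilarity(dm)
  pairs <- pair_scales(metadata)
  miss <- setdiff(unique(c(pairs$a, pairs$b)), rownames(dm))
  if (length(miss)) {
    stop("samples missing from the dissimilarity matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  pairs$dissimilarity <- dm[cbind(pairs$a, pairs$b)]
  summ <- do.call(rbind, lapply(levels(pairs$scale), function(lev) {
    v <- pairs$dissimilarity[pairs$scale == lev]
    data.frame(scale = lev, n_pairs = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  present <- summ$scale[summ$n_pairs > 0]
  adj <- NULL
  if (length(present) > 1) {
    adj <- do.call(rbind, lapply(seq_len(length(present) - 1), function(k) {
      x <- pairs$dissimilarity[pairs$scale == present[k]]
      y <- pairs$dissimilarity[pairs$scale == present[k + 1]]
      if (length(x) < 2 || length(y) < 2 ||
          (stats::sd(x) == 0 && stats::sd(y) == 0)) {
        p <- if (length(x) && length(y) && mean(x) == mean(y)) 1 else NA_real_
        t <- if (!is.na(p) && p == 1) 0 else NA_real_
      } else {
        tt <- stats::t.test(x, y, var.equal = TRUE)
        p <- tt$p.value; t <- unname(tt$statistic)
      }
      data.frame(scale_a = present[k], scale_b = present[k + 1],
                 t = t, p = p)
    }))
  }
  structure(list(values = pairs, summary = summ, adjacent_tests = adj,
                 n_excluded = attr(pairs, "n_excluded")),
            class = "scale_decay")
}

#' Dissimilarity between designated replicate pairs
#'
#' Mean and SD of the dissimilarity over listed sample pairs -- the
#' pipeline's technical-noise floor when the pairs are biological replicates
#' of the same nodule powder.
#'
#' @param dm dissimilarity matrix.
#' @param replicate_pairs 2-column matrix or data.frame of sample-id pairs.
#' @return list: `mean`, `sd` (`NA` for a single pair), `n_pairs`, `values`.
#' @export
replicate_dissimilarity <- function(dm, replicate_pairs) {
  .check_dissimilarity(dm)
  replicate_pairs <- as.matrix(replicate_pairs)
  if (!nrow(replicate_pairs)) stop("no replicate pairs given")
  miss <- setdiff(unique(as.character(replicate_pairs)), rownames(dm))
  if (length(miss)) {
    stop("replicate samples missing from the matrix: ",
         paste(miss, collapse = ", "))
  }
  v <- dm[replicate_pairs[, 1:2, drop = FALSE]]
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n_pairs = length(v), values = v)
}
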