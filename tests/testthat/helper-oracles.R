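# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths.

random_count_table <- function(n_samples, n_taxa, max_count = 50) {
  m <- matrix(sample.int(max_count + 1, n_samples * n_taxa, replace = TRUE) - 1L,
              n_samples, n_taxa,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  # guarantee positive sample totals
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  m
}

# Bray-Curtis by direct summation over taxa
bc_oracle <- function(a, b) sum(abs(a - b)) / sum(a + b)

# weighted UniFrac by explicit branch enumeration using phangorn descendants
wu_oracle <- function(pa, pb, tree, normalized = FALSE) {
  tips <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    ta <- sum(pa[tree$tip.label[tips[[e]]]])
    tb <- sum(pb[tree$tip.label[tips[[e]]]])
    num <- num + tree$edge.length[e] * abs(ta - tb)
    den <- den + tree$edge.length[e] * (ta + tb)
  }
  if (normalized) (if (den > 0) num / den else 0) else num
}

# Faith PD by explicit branch enumeration
faith_oracle <- function(present_tips, tree) {
  tips <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    if (any(tree$tip.label[tips[[e]]] %in% present_tips)) {
      total <- total + tree$edge.length[e]
    }
  }
  total
}

# Kruskal-Wallis by the rank formula with tie correction
kw_oracle <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rg^2 / ng) - 3 * (n + 1)
  t_sizes <- table(r)
  correction <- 1 - sum(t_sizes^3 - t_sizes) / (n^3 - n)
  h / correction
}

# Welch two-sample t p-value written out by hand
welch_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# Benjamini-Hochberg written out by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# ANCOM W by full enumeration of pairwise log-ratio Welch tests
ancom_oracle <- function(table, groups, alpha = 0.05, pseudocount = 1) {
  lx <- log(table + pseudocount)
  k <- ncol(table)
  g <- factor(groups)
  w <- integer(k)
  for (i in seq_len(k)) {
    ps <- numeric(0)
    for (j in seq_len(k)) {
      if (j == i) next
      v <- lx[, i] - lx[, j]
      sp <- split(v, g)
      p <- if (length(unique(v)) == 1 ||
               (var(sp[[1]]) == 0 && var(sp[[2]]) == 0)) {
        if (mean(sp[[1]]) == mean(sp[[2]])) 1 else 0
      } else {
        welch_p(sp[[1]], sp[[2]])
      }
      ps <- c(ps, p)
    }
    w[i] <- sum(bh_oracle(ps) < alpha)
  }
  w
}

# slice-position metadata helpers for the local (intra-nodule) design
local_design <- function(reads = 5000, n_taxa = 12) {
  design_spec(1, 1, 6, 3, reads_per_sample = reads, n_taxa = n_taxa)
}

slice_labels <- function(md) {
  stats::setNames(paste(md$nodule, md$slice, sep = "."), md$sample_id)
}
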