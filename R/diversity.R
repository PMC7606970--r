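#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`;
#' samples whose total falls below `depth` are dropped (their ids are
#' attached as attribute `dropped`). Deterministic under `seed`.
#'
#' @param table samples x taxa integer count matrix.
#' @param depth target depth; `"auto"` uses the minimum sample total.
#' @param seed integer seed.
#' @return rarefied count matrix with attribute `dropped`.
#' @export
rarefy <- function(table, depth = "auto", seed = 1) {
  .check_count_table(table)
  tot <- rowSums(table)
  if (identical(depth, "auto")) depth <- min(tot)
  stopifnot(depth >= 1)
  keep <- tot >= depth
  if (!any(keep)) stop("rarefaction depth ", depth, " exceeds every sample total")
  out <- table[keep, , drop = FALSE]
  withr::with_seed(seed, {
    for (i in seq_len(nrow(out))) {
      reads <- rep.int(seq_len(ncol(out)), out[i, ])
      sub <- if (length(reads) == depth) reads else sample(reads, depth)
      out[i, ] <- tabulate(sub, nbins = ncol(out))
    }
  })
  attr(out, "dropped") <- rownames(table)[!keep]
  out
}

#' Per-sample alpha diversity
#'
#' Shannon entropy (log base 2, in bits), Simpson index (1 - sum p^2),
#' Pielou evenness (Shannon / log2 richness; `NA` for single-taxon samples,
#' where evenness is undefined), or Faith phylogenetic diversity (total
#' branch length of the minimal rooted subtree spanning the taxa present).
#'
#' @param table samples x taxa count matrix; every sample must have a
#'   positive total.
#' @param metric one of `"shannon"`, `"simpson"`, `"pielou"`, `"faith_pd"`.
#' @param tree rooted `ape::phylo` with tip labels covering the table's
#'   taxa; required for `faith_pd`.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "simpson", "pielou",
                                              "faith_pd"), tree = NULL) {
  metric <- match.arg(metric)
  .check_count_table(table)
  if (any(rowSums(table) == 0)) stop("empty sample(s) in count table")
  if (metric == "faith_pd") {
    if (is.null(tree)) stop("faith_pd requires a phylogeny")
    return(.faith_pd(table, tree))
  }
  p <- .rel_abund(table)
  vals <- apply(p, 1, function(pi) {
    pi <- pi[pi > 0]
    sh <- -sum(pi * log2(pi))
    switch(metric,
           shannon = sh,
           simpson = 1 - sum(pi^2),
           pielou = if (length(pi) > 1) sh / log2(length(pi)) else NA_real_)
  })
  stats::setNames(vals, rownames(table))
}

# tip-descendant indicator matrix (tips x edges) by postorder accumulation
.edge_tip_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  tips_under <- vector("list", nnode)
  for (i in seq_len(ntip)) tips_under[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    tips_under[[par]] <- c(tips_under[[par]], tips_under[[chi]])
  }
  m <- matrix(0, ntip, nrow(tree$edge),
              dimnames = list(tree$tip.label, NULL))
  for (e in seq_len(nrow(tree$edge))) {
    m[tips_under[[tree$edge[e, 2]]], e] <- 1
  }
  m
}

.match_tree <- function(table, tree) {
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
}

.faith_pd <- function(table, tree) {
  .match_tree(table, tree)
  m <- .edge_tip_matrix(tree)[colnames(table), , drop = FALSE]
  pres <- (table > 0) %*% m          # samples x edges: n present tips below
  vals <- as.numeric((pres > 0) %*% tree$edge.length)
  stats::setNames(vals, rownames(table))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` over taxa, computed on the
#' table as given (counts or relative abundances; the two agree when sample
#' totals are equal, e.g. after rarefaction).
#'
#' @param table samples x taxa matrix with positive sample totals.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
bray_curtis <- function(table) {
  .check_count_table(table)
  if (nrow(table) < 2) stop("need at least two samples")
  tot <- rowSums(table)
  if (any(tot == 0)) stop("samples with zero total counts")
  manhattan <- as.matrix(stats::dist(table, method = "manhattan"))
  dm <- manhattan / outer(tot, tot, "+")
  diag(dm) <- 0
  dm
}

#' Weighted UniFrac dissimilarity matrix
#'
#' For each branch, the fraction of each sample's reads descending from it
#' is computed; the unnormalized weighted UniFrac distance between two
#' samples is `sum_branches length * |P_a - P_b|`. The normalized variant
#' divides by `sum_branches length * (P_a + P_b)`, bounding values by 1.
#' The unnormalized variant is the default (the convention of the QIIME
#' lineage of pipelines).
#'
#' @param table samples x taxa count matrix.
#' @param tree rooted `ape::phylo` whose tips cover the table's taxa.
#' @param normalized divide by the abundance-weighted total branch length.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  .check_count_table(table)
  .match_tree(table, tree)
  p <- .rel_abund(table)
  m <- .edge_tip_matrix(tree)[colnames(table), , drop = FALSE]
  P <- p %*% m                        # samples x edges
  len <- tree$edge.length
  n <- nrow(table)
  dm <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      num <- sum(len * abs(P[i, ] - P[j, ]))
      d <- if (normalized) {
        den <- sum(len * (P[i, ] + P[j, ]))
        if (den > 0) num / den else 0
      } else num
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres `-D^2 / 2` and eigen-decomposes it. Coordinates are
#' returned for axes with positive eigenvalues; negative eigenvalues (which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis) are reported
#' alongside, never silently clipped. Proportions of variance explained are
#' computed over the positive eigenvalues only.
#'
#' @param dm symmetric dissimilarity matrix with zero diagonal.
#' @return list of class `pcoa_ordination`: `points` (samples x axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (positive axes).
#' @export
pcoa <- function(dm) {
  .check_dissimilarity(dm)
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dm^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(1e-10, 1e-8 * max(abs(e$values), 1))
  pts <- if (any(pos)) {
    sweep(e$vectors[, pos, drop = FALSE], 2, sqrt(e$values[pos]), "*")
  } else {
    matrix(numeric(0), n, 0)
  }
  rownames(pts) <- rownames(dm)
  if (ncol(pts)) colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  structure(list(points = pts,
                 eigenvalues = e$values,
                 proportion_explained = if (any(pos))
                   e$values[pos] / sum(e$values[pos]) else numeric(0)),
            class = "pcoa_ordination")
}
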