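# internal helpers shared across modules

# trapezoidal integral, delegating to pracma on a strictly increasing grid
.trapz <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x, strictly = TRUE))
  pracma::trapz(x, y)
}

# relative abundances by row; errors on zero-total samples
.rel_abund <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("samples with zero total counts: ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts, 1, tot, "/")
}

.check_count_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table)) {
    stop("count table must be a numeric matrix (samples x taxa)")
  }
  if (any(table < 0)) stop("counts must be non-negative")
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop("count table needs sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table))) {
    stop("duplicate sample or taxon ids")
  }
  invisible(table)
}

.check_dissimilarity <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("dissimilarity must be a square matrix")
  }
  if (max(abs(dm - t(dm))) > 1e-10) stop("dissimilarity matrix not symmetric")
  if (any(diag(dm) != 0)) stop("dissimilarity diagonal must be zero")
  if (any(dm < 0)) stop("dissimilarities must be non-negative")
  invisible(dm)
}

# effectively zero spread: the same guard stats::t.test applies before
# refusing "essentially constant" data
.near_constant <- function(x, scale = max(abs(mean(x)), 1e-300)) {
  stats::sd(x) / sqrt(length(x)) <= 10 * .Machine$double.eps * scale
}

# match a vector of per-sample labels (named or positional) to dm/table rows
.align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing)) {
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels length ", length(labels), " != number of samples ",
         length(ids))
  }
  labels
}
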