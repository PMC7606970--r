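#' Counting constants for epifluorescence cell-density estimation
#'
#' Geometry and processing constants converting per-image DAPI cell counts
#' to cells per gram of dissolved halite. Defaults follow the imaging setup:
#' effective field of view 0.203 mm^2 at 400x, 25-mm filter area 226.98
#' mm^2, 2 ml filtered, 0.5 g of ground halite per sample.
#'
#' `volume_total` (the volume of the dissolution suspension the filtered
#' aliquot was drawn from) is not a fixed property of the setup; the default
#' of 10 ml is a documented convention and absolute densities scale linearly
#' with it -- set it to the volume actually used.
#'
#' @param efov effective field of view, mm^2.
#' @param filter_area total filter area, mm^2.
#' @param volume_filtered volume filtered onto the membrane, ml.
#' @param volume_total total suspension volume, ml (must be at least
#'   `volume_filtered`).
#' @param mass mass of halite dissolved, g.
#' @return list of class `counting_constants`.
#' @export
counting_constants <- function(efov = 0.203, filter_area = 226.98,
                               volume_filtered = 2, volume_total = 10,
                               mass = 0.5) {
  vals <- c(efov, filter_area, volume_filtered, volume_total, mass)
  if (any(vals <= 0)) stop("all counting constants must be positive")
  if (volume_filtered > volume_total) {
    stop("volume_filtered exceeds volume_total")
  }
  structure(list(efov = efov, filter_area = filter_area,
                 volume_filtered = volume_filtered,
                 volume_total = volume_total, mass = mass),
            class = "counting_constants")
}

#' One-pass outlier rejection by distance from the mean
#'
#' Computes the mean and (sample) SD of all values once and discards values
#' farther than `k` SDs from the mean (default `k = 2`, i.e. replicates
#' outside two standard deviations of the mean). No iteration: the mean and
#' SD are not recomputed after removal. A zero SD retains everything.
#'
#' @param values numeric vector, length at least 2.
#' @param k SD multiplier, positive.
#' @return list: `retained` (values kept), `discarded` (integer indices into
#'   `values` of the dropped entries).
#' @export
reject_outliers <- function(values, k = 2) {
  stopifnot(length(values) >= 2, k > 0)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    return(list(retained = values, discarded = integer(0)))
  }
  out <- which(abs(values - m) > k * s)
  list(retained = if (length(out)) values[-out] else values,
       discarded = out)
}

#' Cells per gram of halite from per-image field counts
#'
#' Each image count is scaled up to the whole filter (`filter_area / efov`),
#' to the whole suspension (`volume_total / volume_filtered`) and divided by
#' the dissolved mass, giving a per-image density estimate; per-image
#' replicates outside `k` SDs of their mean are discarded
#' ([reject_outliers()]) and the estimate is the mean of the retained
#' densities.
#'
#' @param counts integer vector of per-image cell counts (pooled technical
#'   replicates of one biological sample; typically 3 filters x 5 images).
#' @param constants a [counting_constants()] object.
#' @param k outlier-rejection SD multiplier; `Inf` disables rejection.
#' @return list of class `density_estimate`: `cells_per_gram`, `n_used`,
#'   `n_discarded`, `per_image` (all per-image densities), `discarded`
#'   (indices).
#' @export
cells_per_gram <- function(counts, constants = counting_constants(), k = 2) {
  stopifnot(inherits(constants, "counting_constants"), length(counts) >= 1)
  if (any(counts < 0)) stop("counts must be non-negative")
  dens <- counts * (constants$filter_area / constants$efov) *
    (constants$volume_total / constants$volume_filtered) / constants$mass
  if (length(dens) >= 2 && is.finite(k)) {
    rej <- reject_outliers(dens, k = k)
  } else {
    rej <- list(retained = dens, discarded = integer(0))
  }
  if (!length(rej$retained)) stop("all images discarded as outliers")
  structure(list(cells_per_gram = mean(rej$retained),
                 n_used = length(rej$retained),
                 n_discarded = length(rej$discarded),
                 per_image = dens,
                 discarded = rej$discarded),
            class = "density_estimate")
}
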