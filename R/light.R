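#' Construct a spectrum
#'
#' Per-wavelength intensity in arbitrary detector units, e.g. a lamp
#' emission spectrum or a measurement taken inside a nodule.
#'
#' @param wavelength_nm strictly increasing wavelengths in nm.
#' @param intensity non-negative intensities.
#' @return data.frame of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, intensity) {
  stopifnot(length(wavelength_nm) == length(intensity))
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  out <- data.frame(wavelength_nm = wavelength_nm, intensity = intensity)
  class(out) <- c("spectrum", "data.frame")
  out
}

# interpolate a spectrum-like data.frame onto a wavelength grid
.interp_spec <- function(spec, grid) {
  stats::approx(spec$wavelength_nm, spec[[2]], xout = grid)$y
}

#' Effective light transmission from a measured and a source spectrum
#'
#' Pointwise ratio of the intra-nodule measurement to the unfiltered source
#' (lamp) spectrum, on a common grid by linear interpolation, restricted to
#' the analysis window (default 500-900 nm, where the detector response is
#' usable). Normalising by the lamp spectrum nullifies differences between
#' the lamp and the sun.
#'
#' @param measured,source [spectrum()] objects with overlapping ranges.
#' @param window analysis window in nm (length-2).
#' @param position,nodule optional labels carried on the result.
#' @return data.frame of class `transmission_profile` with columns
#'   `wavelength_nm`, `transmission`; attributes `position`, `nodule`.
#' @export
effective_transmission <- function(measured, source, window = c(500, 900),
                                   position = NA_character_,
                                   nodule = NA_character_) {
  lo <- max(min(measured$wavelength_nm), min(source$wavelength_nm), window[1])
  hi <- min(max(measured$wavelength_nm), max(source$wavelength_nm), window[2])
  grid <- sort(unique(c(measured$wavelength_nm, source$wavelength_nm)))
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2) {
    stop("no usable wavelength overlap within the analysis window [",
         window[1], ", ", window[2], "] nm")
  }
  s <- .interp_spec(source, grid)
  if (any(s <= 0)) {
    stop("source intensity is zero within the window at wavelengths: ",
         paste(utils::head(grid[s <= 0], 5), collapse = ", "))
  }
  m <- .interp_spec(measured, grid)
  out <- data.frame(wavelength_nm = grid, transmission = m / s)
  attr(out, "position") <- position
  attr(out, "nodule") <- nodule
  class(out) <- c("transmission_profile", "data.frame")
  out
}

# mean profile over a list of transmission profiles, on the grid of the first
.mean_profile <- function(profiles) {
  grid <- profiles[[1]]$wavelength_nm
  vals <- sapply(profiles, function(p) {
    stats::approx(p$wavelength_nm, p$transmission, xout = grid)$y
  })
  data.frame(wavelength_nm = grid, transmission = rowMeans(vals))
}

#' Standardise transmission profiles to a reference position
#'
#' Divides every profile pointwise by the mean profile of the reference
#' position (default "top"), removing inter-nodule variability so positions
#' can be compared across nodules. The standardised reference profiles
#' average to 1 at every wavelength.
#'
#' @param profiles list of [effective_transmission()] results carrying a
#'   `position` attribute.
#' @param reference_position label of the reference position.
#' @return list of standardised profiles (same classes and labels).
#' @export
standardize_to_reference <- function(profiles, reference_position = "top") {
  pos <- vapply(profiles, function(p) attr(p, "position"), character(1))
  ref <- profiles[pos == reference_position]
  if (!length(ref)) {
    stop("no profile at reference position '", reference_position, "'")
  }
  mref <- .mean_profile(ref)
  lapply(profiles, function(p) {
    denom <- stats::approx(mref$wavelength_nm, mref$transmission,
                           xout = p$wavelength_nm)$y
    out <- p
    out$transmission <- p$transmission / denom
    out
  })
}

#' Band-integrated PAR reduction ratio
#'
#' Trapezoidal area of the transmitted solar intensity over the area of the
#' unobstructed solar spectrum, on the photosynthetically active band
#' (default 400-700 nm). Because the transmission profile is only defined on
#' its measured window, the integral runs over the intersection of the band
#' with the data coverage (extrapolation is refused); the band actually
#' integrated is attached as attribute `effective_band`.
#'
#' @param trans a `transmission_profile`.
#' @param solar the solar [spectrum()].
#' @param band integration band in nm.
#' @return the reduction ratio (fraction), with attribute `effective_band`.
#' @export
par_reduction_ratio <- function(trans, solar, band = c(400, 700)) {
  lo <- max(band[1], min(trans$wavelength_nm), min(solar$wavelength_nm))
  hi <- min(band[2], max(trans$wavelength_nm), max(solar$wavelength_nm))
  if (hi <= lo) {
    stop("band [", band[1], ", ", band[2],
         "] nm lies outside the data coverage")
  }
  grid <- sort(unique(c(trans$wavelength_nm, solar$wavelength_nm)))
  grid <- grid[grid >= lo & grid <= hi]
  tt <- stats::approx(trans$wavelength_nm, trans$transmission, xout = grid)$y
  ss <- .interp_spec(solar, grid)
  ratio <- .trapz(grid, tt * ss) / .trapz(grid, ss)
  attr(ratio, "effective_band") <- c(lo, hi)
  ratio
}

#' PAR estimate from a reduction ratio
#'
#' Multiplies the band-integrated reduction ratio by the maximum observed
#' midday solar PAR (default 2100 umol/m2/s). The isotropy correction (see
#' [isotropy_correction()]) is off by default (`correction = 1`); pass 1.3
#' to account for light scattered from all directions inside the pores.
#'
#' @param ratio reduction ratio, non-negative fraction.
#' @param par_max maximum solar PAR in umol/m2/s.
#' @param correction multiplicative correction factor, at least 1.
#' @return list of class `par_estimate`: `par` (umol/m2/s),
#'   `reduction_ratio`, `par_max`, `correction`.
#' @export
estimate_par <- function(ratio, par_max = 2100, correction = 1.0) {
  stopifnot(ratio >= 0, par_max > 0, correction >= 1)
  structure(list(par = as.numeric(ratio) * par_max * correction,
                 reduction_ratio = as.numeric(ratio),
                 par_max = par_max,
                 correction = correction),
            class = "par_estimate")
}

#' Isotropy correction factor from paired up/down measurements
#'
#' Inside the salt matrix, light scatters in all directions: a probe aimed
#' downward (away from the incident light) still records a fraction of the
#' upward-probe intensity. The correction factor is
#' `1 + integral(downward) / integral(upward)`; a downward/upward ratio of
#' 30\% yields the factor 1.3.
#'
#' @param downward,upward scalar intensities or [spectrum()] objects on a
#'   common wavelength range.
#' @return the correction factor (at least 1).
#' @export
isotropy_correction <- function(downward, upward) {
  band_int <- function(x) {
    if (is.data.frame(x)) .trapz(x$wavelength_nm, x$intensity) else as.numeric(x)
  }
  up <- band_int(upward)
  if (up <= 0) stop("upward intensity must be positive")
  1 + band_int(downward) / up
}

#' Ratio of two transmission profiles in a narrow band
#'
#' Mean transmission of `trans_a` over `wavelength +/- halfwidth` divided by
#' that of `trans_b`; with `halfwidth = 0` the pointwise interpolated ratio.
#' Used, e.g., to compare middle versus top transmission at the chlorophyll
#' a excitation wavelength (680 nm).
#'
#' @param trans_a,trans_b `transmission_profile`s covering the window.
#' @param wavelength band centre in nm.
#' @param halfwidth band half-width in nm.
#' @return the ratio (fraction).
#' @export
band_ratio <- function(trans_a, trans_b, wavelength = 680, halfwidth = 5) {
  win <- c(wavelength - halfwidth, wavelength + halfwidth)
  for (p in list(trans_a, trans_b)) {
    if (min(p$wavelength_nm) > win[1] || max(p$wavelength_nm) < win[2]) {
      stop("window [", win[1], ", ", win[2], "] nm not covered by a profile")
    }
  }
  if (halfwidth == 0) {
    a <- stats::approx(trans_a$wavelength_nm, trans_a$transmission, wavelength)$y
    b <- stats::approx(trans_b$wavelength_nm, trans_b$transmission, wavelength)$y
    return(a / b)
  }
  mean_in <- function(p) {
    grid <- sort(unique(c(p$wavelength_nm[p$wavelength_nm >= win[1] &
                                            p$wavelength_nm <= win[2]], win)))
    vals <- stats::approx(p$wavelength_nm, p$transmission, xout = grid)$y
    .trapz(grid, vals) / diff(win)
  }
  mean_in(trans_a) / mean_in(trans_b)
}
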