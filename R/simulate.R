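#' Nested sampling design specification
#'
#' Describes the hierarchical sampling design emulated by the generators:
#' regions (separated by tens of km), hill sites within regions (hundreds
#' of m), nodules within sites (m), vertical slices within nodules, and
#' top/middle/bottom positions within slices. One sample per
#' (region, site, nodule, slice, position).
#'
#' @param n_regions,sites_per_region,nodules_per_site,slices_per_nodule
#'   counts, each at least 1.
#' @param positions ordered position labels within a slice.
#' @param reads_per_sample sequencing depth per sample (at least 100).
#' @param n_taxa number of taxa simulated.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(n_regions = 2, sites_per_region = 2,
                        nodules_per_site = 6, slices_per_nodule = 3,
                        positions = c("top", "middle", "bottom"),
                        reads_per_sample = 5000, n_taxa = 12) {
  stopifnot(n_regions >= 1, sites_per_region >= 1, nodules_per_site >= 1,
            slices_per_nodule >= 1, length(positions) >= 1,
            reads_per_sample >= 100, n_taxa >= 1)
  structure(list(n_regions = n_regions, sites_per_region = sites_per_region,
                 nodules_per_site = nodules_per_site,
                 slices_per_nodule = slices_per_nodule,
                 positions = positions, reads_per_sample = reads_per_sample,
                 n_taxa = n_taxa),
            class = "design_spec")
}

#' Per-taxon environmental responses and drift magnitudes
#'
#' Couples taxa to the two deterministic drivers (water availability and
#' light) and sets the SDs of the nested community-drift random effects.
#' `beta_rh` is log-abundance change per unit of the humidity index,
#' `beta_light` per unit of log-PAR.
#'
#' @param n_taxa number of taxa.
#' @param beta_rh,beta_light numeric vectors of length `n_taxa`.
#' @param sd_region,sd_site,sd_nodule,sd_slice,sd_resid non-negative drift
#'   SDs at each nesting level (per taxon, log scale).
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(n_taxa, beta_rh = rep(0, n_taxa),
                        beta_light = rep(0, n_taxa),
                        sd_region = 0.9, sd_site = 0.5, sd_nodule = 0.35,
                        sd_slice = 0.15, sd_resid = 0.10) {
  stopifnot(length(beta_rh) == n_taxa, length(beta_light) == n_taxa,
            sd_region >= 0, sd_site >= 0, sd_nodule >= 0, sd_slice >= 0,
            sd_resid >= 0)
  structure(list(n_taxa = n_taxa, beta_rh = beta_rh, beta_light = beta_light,
                 sd_region = sd_region, sd_site = sd_site,
                 sd_nodule = sd_nodule, sd_slice = sd_slice,
                 sd_resid = sd_resid),
            class = "effect_spec")
}

#' Default taxon archetypes for the study conditions
#'
#' Taxon 1 ("surface_phototroph") is light-dependent; its coefficient is
#' sized so that the expected top-versus-middle relative-abundance ratio,
#' including the compositional renormalisation against the humidity-boosted
#' interior taxa, is about 1.8 (an ~80\% surface enrichment) at
#' representative probe depths of 1 and 3 cm below the top. Taxa 2-4
#' ("interior_heterotroph") track the humidity index, which peaks 2-3 cm
#' below the surface. Remaining taxa are neutral (drift only).
#'
#' @param n_taxa number of taxa (at least 4).
#' @param ... overrides passed to [effect_spec()].
#' @return an `effect_spec` with taxon archetypes in attribute `archetype`.
#' @export
default_effects <- function(n_taxa = 12, ...) {
  stopifnot(n_taxa >= 4)
  beta_light <- c(0.10, rep(0, n_taxa - 1))
  beta_rh <- c(0, rep(1.2, 3), rep(0, n_taxa - 4))
  eff <- effect_spec(n_taxa, beta_rh = beta_rh, beta_light = beta_light, ...)
  attr(eff, "archetype") <- c("surface_phototroph",
                              rep("interior_heterotroph", 3),
                              rep("neutral", n_taxa - 4))
  eff
}

# humidity index: water availability bump peaking 2.5 cm below the surface
.rh_bump <- function(depth_cm) exp(-(depth_cm - 2.5)^2 / (2 * 1.2^2))

#' Generate sample metadata for a nested design
#'
#' One row per (region, site, nodule, slice, position). Distance to the
#' nearest surface (`depth_cm`) is drawn uniformly per position band
#' (top/bottom 0.5-1.5 cm, middle 2-4 cm, matching interior sampling
#' positions); `depth_top_cm` is the depth below the top surface of a
#' nominally 6-cm nodule, which drives light attenuation. The humidity
#' index is the intra-nodule water-availability bump (peaking 2-3 cm below
#' the surface) plus a per-region offset; the light index is log
#' attenuated PAR, `-k_light * depth_top_cm`.
#'
#' @param design a [design_spec()].
#' @param seed integer seed.
#' @param region_rh_offsets per-region humidity-index offsets (default
#'   evenly spaced 0.25 apart, emulating the more humid southern region).
#' @param k_light light attenuation per cm (log scale).
#' @param nodule_height_cm nominal nodule height.
#' @return data.frame: `sample_id`, `region`, `site`, `nodule`, `slice`,
#'   `position`, `depth_cm`, `depth_top_cm`, `rh_index`, `light_index`.
#' @export
generate_metadata <- function(design, seed = 1, region_rh_offsets = NULL,
                              k_light = 1.8, nodule_height_cm = 6) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(region_rh_offsets)) {
    region_rh_offsets <- 0.25 * (seq_len(design$n_regions) - 1)
  }
  stopifnot(length(region_rh_offsets) == design$n_regions)
  grid <- expand.grid(position = design$positions,
                      slice = seq_len(design$slices_per_nodule),
                      nodule = seq_len(design$nodules_per_site),
                      site = seq_len(design$sites_per_region),
                      region = seq_len(design$n_regions),
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(names(grid))]
  n <- nrow(grid)
  md <- withr::with_seed(seed, {
    depth <- ifelse(grid$position == "middle",
                    stats::runif(n, 2, 4), stats::runif(n, 0.5, 1.5))
    depth_top <- ifelse(grid$position == "bottom",
                        nodule_height_cm - depth, depth)
    data.frame(sample_id = sprintf("R%d.S%d.N%02d.L%d.%s", grid$region,
                                   grid$site, grid$nodule, grid$slice,
                                   grid$position),
               region = paste0("R", grid$region),
               site = paste0("S", grid$site),
               nodule = sprintf("N%02d", grid$nodule),
               slice = paste0("L", grid$slice),
               position = as.character(grid$position),
               depth_cm = depth,
               depth_top_cm = depth_top,
               stringsAsFactors = FALSE)
  })
  md$rh_index <- .rh_bump(md$depth_cm) +
    region_rh_offsets[as.integer(sub("R", "", md$region))]
  md$light_index <- -k_light * md$depth_top_cm
  md
}

#' Generate a community count table from metadata and effects
#'
#' Logistic-normal-multinomial model: per-sample, per-taxon log abundance
#' `eta = baseline + beta_rh * rh_index + beta_light * light_index +
#' region + site + nodule + slice random effects + residual`, with each
#' nesting unit drawing an independent per-taxon Gaussian effect of the
#' level's SD; counts are multinomial with the design's reads per sample on
#' `softmax(eta)`. Identical seeds give identical output.
#'
#' @param metadata from [generate_metadata()], consistent with `design`.
#' @param effects an [effect_spec()].
#' @param design the [design_spec()] used for the metadata.
#' @param seed integer seed.
#' @param baseline per-taxon baseline log abundance (default 0).
#' @return list: `counts` (samples x taxa integer matrix), `truth` (list:
#'   per-sample covariates, per-level random-effect matrices, `eta`).
#' @export
generate_counts <- function(metadata, effects, design, seed = 1,
                            baseline = rep(0, effects$n_taxa)) {
  stopifnot(inherits(effects, "effect_spec"), inherits(design, "design_spec"))
  n_expect <- design$n_regions * design$sites_per_region *
    design$nodules_per_site * design$slices_per_nodule *
    length(design$positions)
  if (nrow(metadata) != n_expect) {
    stop("metadata has ", nrow(metadata), " rows but the design implies ",
         n_expect)
  }
  if (effects$n_taxa != design$n_taxa) {
    stop("effects specify ", effects$n_taxa, " taxa but the design ",
         design$n_taxa)
  }
  k <- effects$n_taxa
  taxa <- sprintf("ASV%02d", seq_len(k))
  unit <- function(...) interaction(..., drop = TRUE)
  u_region <- unit(metadata$region)
  u_site <- unit(metadata$region, metadata$site)
  u_nodule <- unit(metadata$region, metadata$site, metadata$nodule)
  u_slice <- unit(metadata$region, metadata$site, metadata$nodule,
                  metadata$slice)
  withr::with_seed(seed, {
    draw <- function(f, sdv) {
      m <- matrix(stats::rnorm(nlevels(f) * k, 0, sdv), nlevels(f), k,
                  dimnames = list(levels(f), taxa))
      m
    }
    re_region <- draw(u_region, effects$sd_region)
    re_site <- draw(u_site, effects$sd_site)
    re_nodule <- draw(u_nodule, effects$sd_nodule)
    re_slice <- draw(u_slice, effects$sd_slice)
    resid <- matrix(stats::rnorm(nrow(metadata) * k, 0, effects$sd_resid),
                    nrow(metadata), k)
    eta <- matrix(baseline, nrow(metadata), k, byrow = TRUE) +
      outer(metadata$rh_index, effects$beta_rh) +
      outer(metadata$light_index, effects$beta_light) +
      re_region[u_region, , drop = FALSE] +
      re_site[u_site, , drop = FALSE] +
      re_nodule[u_nodule, , drop = FALSE] +
      re_slice[u_slice, , drop = FALSE] +
      resid
    dimnames(eta) <- list(metadata$sample_id, taxa)
    prob <- exp(eta - apply(eta, 1, max))
    prob <- prob / rowSums(prob)
    counts <- t(apply(prob, 1, function(p) {
      stats::rmultinom(1, design$reads_per_sample, p)[, 1]
    }))
    dimnames(counts) <- list(metadata$sample_id, taxa)
    list(counts = counts,
         truth = list(rh_index = metadata$rh_index,
                      light_index = metadata$light_index,
                      probabilities = prob, eta = eta,
                      re_region = re_region, re_site = re_site,
                      re_nodule = re_nodule, re_slice = re_slice))
  })
}

#' Generate a diel RH/temperature sensor series with injected events
#'
#' Produces a regular 48-samples-per-day series: temperature and relative
#' humidity follow opposite-phase diel sinusoids (coolest and most humid
#' before dawn) plus site offsets plus Gaussian noise, with RH clamped to
#' \[0, 100\]. Injected events force RH above the dew (95\%) or fog (99\%)
#' threshold for their stated span, so an event detector can be validated
#' against exact ground truth.
#'
#' @param n_days length of the series in days.
#' @param site_offset_T,site_offset_RH additive site offsets (degC, \%RH).
#' @param events data.frame with columns `type` ("dew" or "fog"), `day`
#'   (1-based), `start_hour`, `duration_h`; overlapping events of the same
#'   type are an error.
#' @param seed integer seed.
#' @param rh_base,rh_amp,temp_base,temp_amp diel sinusoid parameters.
#' @param noise_sd_rh,noise_sd_temp Gaussian noise SDs.
#' @param start first timestamp (UTC midnight of day 1).
#' @param label series label.
#' @return list: `series` (a [sensor_series()]), `truth` (the injected
#'   event table with forced RH levels).
#' @export
generate_sensor_series <- function(n_days, site_offset_T = 0,
                                   site_offset_RH = 0, events = NULL,
                                   seed = 1, rh_base = 50, rh_amp = 25,
                                   temp_base = 20, temp_amp = 10,
                                   noise_sd_rh = 2, noise_sd_temp = 1,
                                   start = "2019-01-01", label = "site") {
  stopifnot(n_days >= 1)
  n <- n_days * 48
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_len(n) - 1) * 1800
  hour <- (as.numeric(ts) - as.numeric(t0)) / 3600
  tod <- hour %% 24
  if (!is.null(events) && nrow(events)) {
    stopifnot(all(events$duration_h > 0),
              all(events$type %in% c("dew", "fog")))
    ev_start <- (events$day - 1) * 24 + events$start_hour
    ev_end <- ev_start + events$duration_h
    if (any(ev_end > n_days * 24) || any(ev_start < 0)) {
      stop("injected events fall outside the series span")
    }
    for (ty in c("dew", "fog")) {
      sel <- which(events$type == ty)
      if (length(sel) > 1) {
        o <- order(ev_start[sel])
        s <- ev_start[sel][o]; e <- ev_end[sel][o]
        if (any(s[-1] < e[-length(e)])) {
          stop("overlapping injected ", ty, " events")
        }
      }
    }
  }
  series <- withr::with_seed(seed, {
    temp <- temp_base + temp_amp * sin(2 * pi * (tod - 8) / 24) +
      site_offset_T + stats::rnorm(n, 0, noise_sd_temp)
    rh <- rh_base - rh_amp * sin(2 * pi * (tod - 8) / 24) +
      site_offset_RH + stats::rnorm(n, 0, noise_sd_rh)
    rh <- pmin(pmax(rh, 0), 100)
    if (!is.null(events) && nrow(events)) {
      for (r in seq_len(nrow(events))) {
        lo <- (events$day[r] - 1) * 24 + events$start_hour[r]
        hi <- lo + events$duration_h[r]
        in_ev <- hour >= lo & hour < hi
        rh[in_ev] <- if (events$type[r] == "fog") 99.5 else 97
      }
    }
    sensor_series(ts, rh, temp, label = label)
  })
  list(series = series,
       truth = list(events = events,
                    forced_rh = c(dew = 97, fog = 99.5)))
}

#' Generate depth-attenuated spectra by the Beer-Lambert law
#'
#' `intensity(lambda, d) = source(lambda) * exp(-k(lambda) * d)`; depth 0
#' returns the source spectrum unchanged.
#'
#' @param depths non-negative depths in cm.
#' @param k data.frame `wavelength_nm`, `k` (attenuation per cm, positive),
#'   on exactly the source's wavelength grid.
#' @param source a [spectrum()].
#' @return named list of [spectrum()] objects, one per depth.
#' @export
generate_spectra <- function(depths, k, source) {
  stopifnot(all(depths >= 0), all(k$k > 0))
  if (!isTRUE(all.equal(k$wavelength_nm, source$wavelength_nm))) {
    stop("wavelength grids of k and source do not match")
  }
  out <- lapply(depths, function(d) {
    spectrum(source$wavelength_nm, source$intensity * exp(-k$k * d))
  })
  names(out) <- paste0("d", depths)
  out
}

#' Generate per-image field counts around a true cell density
#'
#' Inverts the [cells_per_gram()] scaling to get the expected cells per
#' field implied by `true_density`, then draws Poisson counts. Applying the
#' estimator to the noiseless expectation recovers `true_density` exactly.
#'
#' @param true_density cells per gram, positive.
#' @param constants a [counting_constants()].
#' @param n_images number of fields imaged (default 15: 3 filters x 5).
#' @param seed integer seed.
#' @return list: `counts` (integer vector), `expected_per_field`.
#' @export
generate_field_counts <- function(true_density, constants = counting_constants(),
                                  n_images = 15, seed = 1) {
  stopifnot(true_density > 0, n_images >= 1,
            inherits(constants, "counting_constants"))
  lambda <- true_density * constants$mass /
    ((constants$filter_area / constants$efov) *
       (constants$volume_total / constants$volume_filtered))
  counts <- withr::with_seed(seed, stats::rpois(n_images, lambda))
  list(counts = counts, expected_per_field = lambda)
}

#' Random rooted phylogeny over the simulated taxa
#'
#' Convenience wrapper producing a rooted ultrametric-ish tree (via
#' `ape::rtree`) whose tips are the generator's taxon labels, for use with
#' [weighted_unifrac()] and Faith PD on synthetic tables.
#'
#' @param n_taxa number of tips.
#' @param seed integer seed.
#' @return an `ape::phylo`.
#' @export
generate_tree <- function(n_taxa, seed = 1) {
  withr::with_seed(seed,
    ape::rtree(n_taxa, tip.label = sprintf("ASV%02d", seq_len(n_taxa))))
}
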