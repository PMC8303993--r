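#' Specification of a synthetic band-intensity experiment
#'
#' Describes a synthetic venom-profiling experiment with the same design as
#' the study: 3 rearing temperatures x 5 replicates x 7 females per cell
#' (105 individuals per line), ~35 reference bands, replicate (gel/batch)
#' offsets, a set of "direct" bands whose expected intensity is linear in
#' temperature, and "indirect" bands that equal a direct parent band plus
#' independent link noise (so their partial correlation with the trend given
#' the parent is 0 by construction).
#'
#' @param n_temperatures number of temperature levels.
#' @param temperatures the levels themselves (degrees C).
#' @param n_replicates replicates per line (crossed with temperature).
#' @param n_per_cell females per temperature x replicate cell.
#' @param n_bands number of reference bands.
#' @param direct_bands indices of bands with a monotone temperature effect.
#' @param indirect_bands named integer vector mapping band index (name) to
#'   its parent direct band (value).
#' @param effect_size intensity-unit shift per degree C for direct bands.
#' @param replicate_sd SD of replicate offsets (drawn per replicate x band,
#'   shared by all individuals of the replicate).
#' @param noise_sd residual SD.
#' @param link_noise_sd SD of the noise linking an indirect band to its
#'   parent.
#' @param baseline baseline intensity of every band.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `band_sim_spec`.
#' @export
band_sim_spec <- function(n_temperatures = 3, temperatures = c(20, 25, 30),
                          n_replicates = 5, n_per_cell = 7, n_bands = 35,
                          direct_bands = c(5, 12, 22),
                          indirect_bands = c(`6` = 5, `13` = 12, `23` = 22),
                          effect_size = 2, replicate_sd = 1.5, noise_sd = 4.5,
                          link_noise_sd = 4.5, baseline = 100, seed = NULL) {
  stopifnot(length(temperatures) == n_temperatures,
            n_replicates >= 1, n_per_cell >= 1, n_bands >= 1)
  if (replicate_sd < 0 || noise_sd < 0 || link_noise_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  direct_bands <- as.integer(direct_bands)
  ind_idx <- as.integer(names(indirect_bands))
  if (length(indirect_bands) > 0 && is.null(names(indirect_bands))) {
    stop("'indirect_bands' must be a named vector: names are band indices, values their parent direct band")
  }
  parents <- as.integer(indirect_bands)
  if (length(intersect(direct_bands, ind_idx)) > 0) {
    stop("direct and indirect band sets must be disjoint")
  }
  if (any(c(direct_bands, ind_idx, parents) > n_bands) ||
      any(c(direct_bands, ind_idx, parents) < 1)) {
    stop("band indices must lie in 1..n_bands")
  }
  if (!all(parents %in% direct_bands)) {
    stop("every indirect band's parent must be a direct band")
  }
  structure(
    list(n_temperatures = n_temperatures, temperatures = sort(temperatures),
         n_replicates = n_replicates, n_per_cell = n_per_cell,
         n_bands = n_bands, direct_bands = direct_bands,
         indirect_bands = indirect_bands, effect_size = effect_size,
         replicate_sd = replicate_sd, noise_sd = noise_sd,
         link_noise_sd = link_noise_sd, baseline = baseline, seed = seed),
    class = "band_sim_spec"
  )
}

#' Simulate a band-intensity matrix with ground truth
#'
#' Generates intensities on a linear scale and clips at 0 (silver-stain
#' volumes are non-negative). Direct bands get `effect_size * (T - 25)` added
#' to the baseline; indirect bands equal their parent's value plus
#' independent Gaussian link noise; every band receives a replicate offset
#' shared by all individuals of that replicate.
#'
#' @param spec a [band_sim_spec()].
#' @return list with elements `matrix` (a [band_matrix()]) and `truth` (data
#'   frame with one row per band: `band`, `class` in
#'   direct/indirect/unaffected, `sign` in -1/0/+1).
#' @export
simulate_band_matrix <- function(spec) {
  stopifnot(inherits(spec, "band_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  temps <- rep(spec$temperatures, each = spec$n_replicates * spec$n_per_cell)
  reps <- rep(rep(seq_len(spec$n_replicates), each = spec$n_per_cell),
              times = spec$n_temperatures)
  n <- length(temps)
  # replicate x band offsets, shared across temperatures within a replicate
  offs <- matrix(stats::rnorm(spec$n_replicates * spec$n_bands, 0, spec$replicate_sd),
                 spec$n_replicates, spec$n_bands)
  vals <- matrix(spec$baseline, n, spec$n_bands) + offs[reps, , drop = FALSE] +
    matrix(stats::rnorm(n * spec$n_bands, 0, spec$noise_sd), n, spec$n_bands)
  tc <- temps - stats::median(spec$temperatures)
  for (b in spec$direct_bands) {
    vals[, b] <- vals[, b] + spec$effect_size * tc
  }
  ind_idx <- as.integer(names(spec$indirect_bands))
  for (k in seq_along(ind_idx)) {
    parent <- as.integer(spec$indirect_bands[[k]])
    vals[, ind_idx[k]] <- vals[, parent] + stats::rnorm(n, 0, spec$link_noise_sd)
  }
  vals <- pmax(vals, 0)
  colnames(vals) <- paste0("band_", seq_len(spec$n_bands))
  cls <- rep("unaffected", spec$n_bands)
  cls[spec$direct_bands] <- "direct"
  cls[ind_idx] <- "indirect"
  sgn <- integer(spec$n_bands)
  sgn[spec$direct_bands] <- sign(spec$effect_size)
  sgn[ind_idx] <- sign(spec$effect_size)
  list(
    matrix = band_matrix(vals, temperature = temps,
                         replicate = paste0("rep_", reps), line = "synthetic"),
    truth = data.frame(band = colnames(vals), class = cls, sign = sgn,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate gel lane intensity profiles with planted peak volumes
#'
#' Each lane profile is a sum of Gaussian peaks (one per band, area equal to
#' the planted volume) centred at the band positions, plus a baseline and
#' optional Gaussian noise. Serves as the front end for round-trip tests of
#' [quantify_reference_bands()].
#'
#' @param band_positions strictly increasing peak centres.
#' @param true_volumes matrix of planted peak volumes (lanes x bands), >= 0.
#' @param peak_sd Gaussian peak width (SD) in position units.
#' @param baseline constant value or function of position added to every lane.
#' @param noise_sd SD of pointwise noise added to the profile (intensities
#'   are clipped at 0).
#' @param positions sampling grid; defaults to 2001 points spanning the band
#'   range plus a margin of `4 * peak_sd`.
#' @param window_halfwidth integration half-width recorded in the returned
#'   reference-band table; defaults to `4 * peak_sd`.
#' @param metadata optional data frame (one row per lane) with columns
#'   `individual_id`, `line`, `temperature`, `replicate`.
#' @param seed integer seed, or `NULL`.
#' @return list with `profiles` (list of [lane_profile()]), `bands` (a
#'   [reference_bands()] table) and `overlap_warning` (`TRUE` when adjacent
#'   peaks are closer than `4 * peak_sd` and thus not cleanly resolvable).
#' @export
simulate_lane_profiles <- function(band_positions, true_volumes, peak_sd = 1,
                                   baseline = 0, noise_sd = 0, positions = NULL,
                                   window_halfwidth = NULL, metadata = NULL,
                                   seed = NULL) {
  band_positions <- as.numeric(band_positions)
  if (any(diff(band_positions) <= 0)) stop("'band_positions' must be strictly increasing")
  true_volumes <- rbind(true_volumes)
  if (ncol(true_volumes) != length(band_positions)) {
    stop("'true_volumes' must have one column per band position")
  }
  if (any(true_volumes < 0)) stop("'true_volumes' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  overlap <- length(band_positions) > 1 && any(diff(band_positions) < 4 * peak_sd)
  if (overlap) {
    warning("adjacent peaks closer than 4 * peak_sd; band windows will overlap")
  }
  if (is.null(positions)) {
    margin <- 4 * peak_sd
    positions <- seq(min(band_positions) - margin, max(band_positions) + margin,
                     length.out = 2001)
  }
  base_val <- if (is.function(baseline)) baseline(positions) else rep(baseline, length(positions))
  peak_shapes <- vapply(band_positions, function(p) stats::dnorm(positions, p, peak_sd),
                        numeric(length(positions)))
  n_lane <- nrow(true_volumes)
  profiles <- lapply(seq_len(n_lane), function(i) {
    y <- as.vector(peak_shapes %*% true_volumes[i, ]) + base_val
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    md <- if (is.null(metadata)) {
      list(individual_id = sprintf("lane_%03d", i), line = NA_character_,
           temperature = NA_real_, replicate = NA_character_)
    } else as.list(metadata[i, ])
    lane_profile(positions, pmax(y, 0), individual_id = md$individual_id,
                 line = md$line, temperature = md$temperature,
                 replicate = md$replicate)
  })
  if (is.null(window_halfwidth)) window_halfwidth <- 4 * peak_sd
  list(profiles = profiles,
       bands = reference_bands(band_positions, window_halfwidth),
       overlap_warning = overlap)
}

#' Specification of a synthetic parasitism-outcome experiment
#'
#' Dishes of host larvae exposed to a parasitoid female at one of the study
#' temperatures. Per dish, the number of parasitized larvae is binomial on
#' the logit scale with a dish-level random intercept (the source of
#' extra-binomial variation); parasitized larvae are split into multi- and
#' mono-parasitized, and mono-parasitized larvae into the L / LOC / CC
#' dissection outcomes via a baseline-category trinomial model (CC is the
#' reference category) whose two logits receive a shared dish-level
#' intercept.
#'
#' @param n_dishes_per_temperature dishes per temperature.
#' @param larvae_per_dish host larvae per dish.
#' @param temperatures temperature levels (degrees C).
#' @param logit_parasitism per-temperature logit of the parasitism
#'   probability.
#' @param category_logits matrix with one row per temperature and columns
#'   `L` and `LOC`: baseline-category logits of L and LOC relative to CC.
#' @param multi_fraction probability that a parasitized larva is
#'   multi-parasitized.
#' @param replicate_sd SD of the dish-level random intercepts.
#' @param n_replicates number of replicate labels (dishes are assigned
#'   round-robin).
#' @param host,line labels carried into the records.
#' @param seed integer seed, or `NULL`.
#' @return object of class `outcome_sim_spec`.
#' @export
outcome_sim_spec <- function(n_dishes_per_temperature = 10, larvae_per_dish = 30,
                             temperatures = c(20, 25, 30),
                             logit_parasitism = c(1, 1, 1),
                             category_logits = cbind(L = c(1, 1, 1), LOC = c(0, 0, 0)),
                             multi_fraction = 0.1, replicate_sd = 0.5,
                             n_replicates = 5, host = "D. melanogaster",
                             line = "ISm", seed = NULL) {
  stopifnot(larvae_per_dish >= 1, n_dishes_per_temperature >= 1)
  if (multi_fraction < 0 || multi_fraction > 1) stop("'multi_fraction' must be in [0, 1]")
  if (replicate_sd < 0) stop("'replicate_sd' must be >= 0")
  category_logits <- rbind(category_logits)
  stopifnot(length(logit_parasitism) == length(temperatures),
            nrow(category_logits) == length(temperatures),
            ncol(category_logits) == 2)
  structure(
    list(n_dishes_per_temperature = n_dishes_per_temperature,
         larvae_per_dish = larvae_per_dish, temperatures = temperatures,
         logit_parasitism = logit_parasitism, category_logits = category_logits,
         multi_fraction = multi_fraction, replicate_sd = replicate_sd,
         n_replicates = n_replicates, host = host, line = line, seed = seed),
    class = "outcome_sim_spec"
  )
}

#' Simulate per-dish parasitism outcome records
#'
#' @param spec an [outcome_sim_spec()].
#' @return data frame with one row per dish: `dish_id`, `replicate_id`,
#'   `temperature`, `host`, `line`, and counts `non_parasitized`, `mono_L`,
#'   `mono_LOC`, `mono_CC`, `multi_parasitized` summing to the dish size.
#' @export
simulate_outcomes <- function(spec) {
  stopifnot(inherits(spec, "outcome_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rows <- list()
  dish <- 0L
  for (t in seq_along(spec$temperatures)) {
    for (d in seq_len(spec$n_dishes_per_temperature)) {
      dish <- dish + 1L
      u <- stats::rnorm(1, 0, spec$replicate_sd)
      n_par <- stats::rbinom(1, spec$larvae_per_dish,
                             stats::plogis(spec$logit_parasitism[t] + u))
      n_multi <- stats::rbinom(1, n_par, spec$multi_fraction)
      n_mono <- n_par - n_multi
      v <- stats::rnorm(1, 0, spec$replicate_sd)
      lg <- spec$category_logits[t, ] + v
      p <- exp(c(lg, 0))
      p <- p / sum(p)
      mono <- if (n_mono > 0) as.vector(stats::rmultinom(1, n_mono, p)) else c(0L, 0L, 0L)
      rows[[dish]] <- data.frame(
        dish_id = sprintf("dish_%03d", dish),
        replicate_id = sprintf("rep_%d", ((dish - 1L) %% spec$n_replicates) + 1L),
        temperature = spec$temperatures[t], host = spec$host, line = spec$line,
        non_parasitized = spec$larvae_per_dish - n_par,
        mono_L = mono[1], mono_LOC = mono[2], mono_CC = mono[3],
        multi_parasitized = n_multi, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Specification of a synthetic oil-drop melanization experiment
#'
#' Ordinal melanization classes 0-5 are drawn from a cumulative-logit model:
#' a larva's latent response is a per-temperature shift plus a capillary
#' random intercept plus standard-logistic noise, and the class is the number
#' of cutpoints the latent value exceeds.
#'
#' @param n_larvae_per_cell larvae per temperature.
#' @param temperatures temperature levels (degrees C).
#' @param cumulative_logits 5 strictly increasing cutpoints separating
#'   classes 0|1, 1|2, ..., 4|5 on the latent scale.
#' @param temperature_effect per-temperature shift of the latent scale (same
#'   length as `temperatures`).
#' @param capillary_sd SD of capillary random intercepts.
#' @param n_capillaries number of capillaries (larvae assigned round-robin).
#' @param species host species label.
#' @param seed integer seed, or `NULL`.
#' @return object of class `melanization_sim_spec`.
#' @export
melanization_sim_spec <- function(n_larvae_per_cell = 35,
                                  temperatures = c(20, 25, 30),
                                  cumulative_logits = qlogis(c(0.10, 0.25, 0.45, 0.65, 0.85)),
                                  temperature_effect = c(0, 0, 0),
                                  capillary_sd = 0.5, n_capillaries = 5,
                                  species = "D. melanogaster", seed = NULL) {
  stopifnot(n_larvae_per_cell >= 1, n_capillaries >= 1,
            length(temperature_effect) == length(temperatures))
  if (length(cumulative_logits) != 5 || any(diff(cumulative_logits) <= 0)) {
    stop("'cumulative_logits' must be 5 strictly increasing cutpoints (classes 0..5)")
  }
  if (capillary_sd < 0) stop("'capillary_sd' must be >= 0")
  structure(
    list(n_larvae_per_cell = n_larvae_per_cell, temperatures = temperatures,
         cumulative_logits = cumulative_logits,
         temperature_effect = temperature_effect, capillary_sd = capillary_sd,
         n_capillaries = n_capillaries, species = species, seed = seed),
    class = "melanization_sim_spec"
  )
}

#' Simulate per-larva melanization class records
#'
#' @param spec a [melanization_sim_spec()].
#' @return data frame with one row per larva: `larva_id`, `capillary_id`,
#'   `temperature`, `species`, `class` (integer 0-5).
#' @export
simulate_melanization <- function(spec) {
  stopifnot(inherits(spec, "melanization_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  cap_eff <- stats::rnorm(spec$n_capillaries, 0, spec$capillary_sd)
  rows <- list()
  k <- 0L
  for (t in seq_along(spec$temperatures)) {
    for (i in seq_len(spec$n_larvae_per_cell)) {
      k <- k + 1L
      cap <- ((i - 1L) %% spec$n_capillaries) + 1L
      latent <- spec$temperature_effect[t] + cap_eff[cap] + stats::rlogis(1)
      rows[[k]] <- data.frame(
        larva_id = sprintf("larva_%04d", k),
        capillary_id = sprintf("cap_%d", cap),
        temperature = spec$temperatures[t], species = spec$species,
        class = sum(latent > spec$cumulative_logits), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
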