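#' Lane intensity profile
#'
#' One silver-stained gel lane as extracted by densitometry software: a
#' migration coordinate grid and the stain intensity at each position, plus
#' the metadata of the individual whose venom was loaded.
#'
#' @param positions strictly increasing migration coordinates (arbitrary
#'   units).
#' @param intensities non-negative intensities, same length as `positions`.
#' @param individual_id,line,temperature,replicate lane metadata.
#' @return object of class `lane_profile`.
#' @export
lane_profile <- function(positions, intensities, individual_id = NA_character_,
                         line = NA_character_, temperature = NA_real_,
                         replicate = NA_character_) {
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities)) {
    stop("'positions' and 'intensities' must have the same length")
  }
  if (any(diff(positions) <= 0)) stop("'positions' must be strictly increasing")
  if (any(intensities < 0)) stop("'intensities' must be non-negative")
  structure(
    list(positions = positions, intensities = intensities,
         individual_id = individual_id, line = line,
         temperature = as.numeric(temperature), replicate = replicate),
    class = "lane_profile"
  )
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("lane_profile: %s (%s, %g degC, replicate %s), %d points on [%g, %g]\n",
              x$individual_id, x$line, x$temperature, x$replicate,
              length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Reference-band definitions
#'
#' A set of recurring band positions of known molecular weight used as
#' quantification landmarks across lanes. Each band is integrated over a
#' fixed window about its nominal migration position.
#'
#' @param nominal_position migration coordinate of each band.
#' @param window_halfwidth half-width of the integration window, same units;
#'   recycled if length 1. Must be > 0.
#' @param band_id band identifiers; defaults to 1..n in position order.
#' @return data frame of class `reference_bands`.
#' @export
reference_bands <- function(nominal_position, window_halfwidth, band_id = NULL) {
  nominal_position <- as.numeric(nominal_position)
  window_halfwidth <- rep_len(as.numeric(window_halfwidth), length(nominal_position))
  if (any(window_halfwidth <= 0)) stop("'window_halfwidth' must be > 0 (non-degenerate windows)")
  if (is.null(band_id)) band_id <- seq_along(nominal_position)
  out <- data.frame(band_id = band_id, nominal_position = nominal_position,
                    window_halfwidth = window_halfwidth)
  class(out) <- c("reference_bands", "data.frame")
  out
}

# trapezoidal integral of (x, y) over [lo, hi]; endpoints interpolated
.trapz_window <- function(x, y, lo, hi) {
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside], stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Quantify reference-band intensities from a lane profile
#'
#' Computes the "peak volume" of every reference band: the trapezoidal
#' integral of the raw lane intensity over the band's window
#' `[nominal_position - window_halfwidth, nominal_position + window_halfwidth]`.
#' No background is subtracted (`background_mode = "none"`), matching the
#' quantification configuration used for both parasitoid lines.
#'
#' @param profile a [lane_profile()].
#' @param bands a [reference_bands()] table.
#' @param background_mode only `"none"` is supported.
#' @param quantity only `"peak_volume"` is supported.
#' @return named numeric vector, one peak volume per band in `band_id` order.
#' @export
quantify_reference_bands <- function(profile, bands,
                                     background_mode = c("none"),
                                     quantity = c("peak_volume")) {
  background_mode <- match.arg(background_mode)
  quantity <- match.arg(quantity)
  stopifnot(inherits(profile, "lane_profile"))
  lo <- bands$nominal_position - bands$window_halfwidth
  hi <- bands$nominal_position + bands$window_halfwidth
  rng <- range(profile$positions)
  if (any(lo < rng[1]) || any(hi > rng[2])) {
    stop("band window(s) outside the profile's position range")
  }
  o <- order(lo)
  if (any(hi[o][-length(o)] > lo[o][-1])) {
    warning("overlapping band windows; overlapping regions are integrated in both bands")
  }
  vols <- vapply(seq_len(nrow(bands)), function(i) {
    .trapz_window(profile$positions, profile$intensities, lo[i], hi[i])
  }, numeric(1))
  names(vols) <- as.character(bands$band_id)
  vols
}

#' Quantify a set of lanes into a band matrix
#'
#' Convenience wrapper applying [quantify_reference_bands()] to each lane and
#' assembling the results with the lane metadata.
#'
#' @param profiles list of [lane_profile()] objects.
#' @param bands a [reference_bands()] table.
#' @return a [band_matrix()].
#' @export
quantify_lanes <- function(profiles, bands) {
  vals <- t(vapply(profiles, quantify_reference_bands, numeric(nrow(bands)),
                   bands = bands))
  colnames(vals) <- paste0("band_", bands$band_id)
  band_matrix(vals,
              temperature = vapply(profiles, `[[`, numeric(1), "temperature"),
              replicate = vapply(profiles, function(p) as.character(p$replicate), character(1)),
              line = vapply(profiles, function(p) as.character(p$line), character(1)),
              individual_id = vapply(profiles, function(p) as.character(p$individual_id), character(1)))
}

#' Quantile normalization of a band matrix
#'
#' Forces every individual (row) to share one common intensity distribution:
#' each row's sorted values are replaced by the across-row means of the
#' sorted values, preserving within-row ranks; ties receive the mean of the
#' tied quantiles. This is the normalization used for the ISm line.
#'
#' Internally delegates to [limma::normalizeQuantiles()] (lanes as columns).
#'
#' @param x a `band_matrix` or numeric matrix with >= 2 rows.
#' @return object of the same type with normalized intensities.
#' @export
quantile_normalize <- function(x) {
  vals <- band_values(x)
  if (nrow(vals) < 2) stop("quantile normalization needs at least 2 individuals (rows)")
  norm <- t(limma::normalizeQuantiles(t(vals), ties = TRUE))
  dimnames(norm) <- dimnames(vals)
  if (is.matrix(x)) norm else set_band_values(x, norm)
}

#' Cyclic loess normalization of a band matrix
#'
#' Iteratively removes smooth intensity-dependent differences between every
#' pair of lanes on the log2 scale: for each pair, a loess curve is fitted to
#' M (log difference) versus A (log average) and half the fitted trend is
#' removed from each lane. Intensities are shifted by `offset` before the log
#' transform and back-transformed afterwards. This is the normalization used
#' for the ISy line.
#'
#' Internally delegates to [limma::normalizeCyclicLoess()] on
#' `log2(intensity + offset)`.
#'
#' @param x a `band_matrix` or numeric matrix with >= 2 rows.
#' @param span loess span in (0, 1].
#' @param max_iterations number of cycles over all lane pairs.
#' @param offset value added to intensities before taking log2; must be > 0
#'   if any intensity is 0.
#' @return object of the same type with normalized intensities (>= 0).
#' @export
cyclic_loess_normalize <- function(x, span = 0.7, max_iterations = 3, offset = 1) {
  vals <- band_values(x)
  if (nrow(vals) < 2) stop("cyclic loess normalization needs at least 2 individuals (rows)")
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  if (any(vals + offset <= 0)) {
    stop("non-positive intensities after adding 'offset'; increase 'offset'")
  }
  lv <- log2(t(vals) + offset)
  ln <- limma::normalizeCyclicLoess(lv, span = span, iterations = max_iterations,
                                    method = "pairs")
  norm <- pmax(t(2^ln) - offset, 0)
  dimnames(norm) <- dimnames(vals)
  if (is.matrix(x)) norm else set_band_values(x, norm)
}

#' Per-individual total band intensity
#'
#' The sum of the intensities of all reference bands of a lane, used as a
#' proxy for the total amount of protein in the venom.
#'
#' @param x a `band_matrix` or numeric matrix.
#' @return for a `band_matrix`, a data frame with the metadata and a
#'   `total_intensity` column; for a matrix, a numeric vector of row sums.
#' @export
total_band_intensity <- function(x) {
  vals <- band_values(x)
  totals <- rowSums(vals)
  if (is.matrix(x)) return(totals)
  out <- band_meta(x)
  out$total_intensity <- totals
  out
}
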