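# Readout: background correction, per-pixel Final/Start ratios, Normalized
# Fluorescence (NF), Gaussian histogram fit, per-spot results and
# condition-level aggregation.
#
# The central quantity is computed pixel by pixel from the four images:
#   Ratio_RED  = RED_Final / RED_Start     (density of surviving Cy5)
#   Ratio_FRET = FRET_Final / FRET_Start   (fraction never loaded)
#   CE         = 1 - Ratio_FRET            (coupling efficiency)
#   NF         = (Ratio_RED - Ratio_FRET) / (1 - Ratio_FRET)
# NF is the fraction of loaded probes whose reference duplex broke: 0.5
# means protein and reference bonds are equally strong. NOTE: the NF formula
# is reconstructed from the assay's verbal description and boundary
# semantics (never-loaded probes are subtracted from the RED ratio, then
# normalized to CE; NF = 0.5 iff equal strength, NF -> 1 iff the protein
# outlasts the reference); treat it as the package's documented convention.

#' Analysis configuration
#'
#' Tunable thresholds of the quantification; every default is a documented
#' choice, not an experimentally fixed constant.
#'
#' @param min_start_counts Minimum background-corrected Start signal (both
#'   channels) for a pixel to be valid, counts. Default 10 = 5 x the default
#'   read-noise SD of 2 counts.
#' @param fret_ratio_max Pixels with `Ratio_FRET` at or above this are
#'   excluded (the NF denominator `1 - Ratio_FRET` blows up). Default 0.995.
#' @param nf_window NF values outside this window are excluded as outliers.
#' @param bins Histogram bin count over `nf_window` for the Gaussian fit.
#' @param min_pixels Minimum valid pixels required for a histogram fit.
#' @param ce_floor Spots with coupling efficiency below this are flagged
#'   invalid ("not under load").
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_start_counts = 10, fret_ratio_max = 0.995,
                            nf_window = c(-0.25, 1.25), bins = 100,
                            min_pixels = 100, ce_floor = 0.05) {
  stopifnot(length(nf_window) == 2L, nf_window[1] < nf_window[2],
            bins >= 10, min_pixels >= 10)
  structure(list(min_start_counts = min_start_counts,
                 fret_ratio_max = fret_ratio_max,
                 nf_window = nf_window, bins = as.integer(bins),
                 min_pixels = as.integer(min_pixels), ce_floor = ce_floor),
            class = "analysis_config")
}

#' Estimate the image background outside the spot
#'
#' The median of all pixels outside the spot mask; robust to the few bright
#' outliers a real slide shows. Subtracting it from a constant-background
#' image leaves a residual median of zero.
#'
#' @param image Numeric matrix.
#' @param spot_mask Logical matrix, `TRUE` inside the spot.
#' @param min_outside Minimum number of outside pixels required.
#' @return Background level in counts.
#' @export
estimate_background <- function(image, spot_mask, min_outside = 100) {
  stopifnot(is.matrix(image), is.logical(spot_mask),
            all(dim(image) == dim(spot_mask)))
  outside <- image[!spot_mask]
  if (length(outside) < min_outside) {
    stop("too few pixels outside the spot mask for background estimation (",
         length(outside), " < ", min_outside, ")")
  }
  stats::median(outside)
}

#' Per-pixel ratio images and Normalized Fluorescence map
#'
#' Computes `Ratio_RED`, `Ratio_FRET` and the per-pixel NF from four
#' background-corrected, registered images. A pixel is valid when both Start
#' signals exceed the threshold, `Ratio_FRET` stays below `fret_ratio_max`,
#' all ratios are finite, and the NF lies inside the outlier window.
#'
#' @param images A `spot_imageset` whose four channels are already
#'   background-corrected.
#' @param config An [analysis_config()].
#' @return A list of class `ratio_images`: matrices `ratio_red`,
#'   `ratio_fret`, `nf` (NA outside `valid_mask`), logical `valid_mask`,
#'   and the vector `nf_values` of valid per-pixel NFs.
#' @export
pixel_nf_map <- function(images, config = analysis_config()) {
  stopifnot(inherits(images, "spot_imageset"), inherits(config, "analysis_config"))
  mask <- images$spot_mask
  rs <- images$red_start; fs <- images$fret_start
  rf <- images$red_final; ff <- images$fret_final

  ratio_red <- rf / rs
  ratio_fret <- ff / fs
  nf <- (ratio_red - ratio_fret) / (1 - ratio_fret)

  valid <- mask &
    rs > config$min_start_counts & fs > config$min_start_counts &
    is.finite(ratio_red) & is.finite(ratio_fret) &
    ratio_red >= 0 & ratio_fret >= 0 &
    ratio_fret < config$fret_ratio_max &
    is.finite(nf) &
    nf >= config$nf_window[1] & nf <= config$nf_window[2]

  if (!any(valid)) stop("no loaded probes detectable: all pixels invalid")

  ratio_red[!valid] <- NA_real_
  ratio_fret[!valid] <- NA_real_
  nf[!valid] <- NA_real_
  structure(list(ratio_red = ratio_red, ratio_fret = ratio_fret, nf = nf,
                 valid_mask = valid, nf_values = nf[valid]),
            class = "ratio_images")
}

#' Gaussian fit to the NF histogram
#'
#' Histograms the per-pixel NF values over the outlier window and fits a
#' three-parameter Gaussian (amplitude, mean, width) by least squares,
#' initialized from the median and the scaled MAD. The fitted mean is the
#' spot's most likely NF. On non-convergence, on a degenerate (near-delta)
#' histogram, or when the Gaussian explains less than 50% of the histogram
#' variance (e.g. strongly bimodal pixels), `fit_ok` is `FALSE` and the
#' robust fallback (median, MAD) is reported instead.
#'
#' @param nf_values Numeric vector of per-pixel NF values.
#' @param config An [analysis_config()] (bin count, window, minimum pixels).
#' @return A list with `mu`, `sigma`, `fit_ok`, `n` and the fraction of
#'   histogram variance explained (`r_squared`, NA when not fitted).
#' @export
fit_nf_histogram <- function(nf_values, config = analysis_config()) {
  nf_values <- nf_values[is.finite(nf_values)]
  if (length(nf_values) < config$min_pixels) {
    stop("too few valid pixels for histogram fit (", length(nf_values),
         " < ", config$min_pixels, ")")
  }
  win <- config$nf_window
  nf_values <- nf_values[nf_values >= win[1] & nf_values <= win[2]]
  breaks <- seq(win[1], win[2], length.out = config$bins + 1L)
  h <- graphics::hist(nf_values, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  med <- stats::median(nf_values)
  sig0 <- stats::mad(nf_values)          # already scaled to SD for normals
  bw <- diff(breaks[1:2])
  if (sig0 < bw / 2) {                   # near-delta histogram: no stable fit
    return(list(mu = med, sigma = sig0, fit_ok = FALSE,
                n = length(nf_values), r_squared = NA_real_))
  }
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
               start = list(a = max(y), mu = med, s = sig0),
               lower = c(a = 0, mu = win[1], s = bw / 10),
               upper = c(a = Inf, mu = win[2], s = diff(win)),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mu = med, sigma = sig0, fit_ok = FALSE,
                n = length(nf_values), r_squared = NA_real_))
  }
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  ok <- is.finite(r2) && r2 >= 0.5
  list(mu = unname(co[["mu"]]), sigma = unname(co[["s"]]),
       fit_ok = ok, n = length(nf_values), r_squared = r2)
}

#' Quantify one spot
#'
#' The full per-spot readout chain: estimate and subtract the background of
#' each channel, build the per-pixel ratio and NF maps, fit the NF
#' histogram, and summarize. The coupling efficiency is reported as
#' `1 - median(Ratio_FRET)` over valid pixels; a spot with CE below the
#' configured floor was essentially never under load and is flagged invalid
#' (never silently dropped).
#'
#' @param images A `spot_imageset` (raw counts, as simulated or read from
#'   disk).
#' @param config An [analysis_config()].
#' @return An object of class `spot_result`: `nf` (clipped to \[0, 1\] for
#'   reporting), `nf_sigma`, `coupling_efficiency`, `n_pixels`, `fit_ok`,
#'   `valid`, plus `spot_id`/`condition` when present in the metadata.
#' @export
quantify_spot <- function(images, config = analysis_config()) {
  stopifnot(inherits(images, "spot_imageset"))
  corrected <- images
  for (ch in c("red_start", "fret_start", "red_final", "fret_final")) {
    bg <- estimate_background(images[[ch]], images$spot_mask)
    corrected[[ch]] <- images[[ch]] - bg
  }
  ratios <- pixel_nf_map(corrected, config)
  ce <- 1 - stats::median(ratios$ratio_fret[ratios$valid_mask])
  fit <- fit_nf_histogram(ratios$nf_values, config)
  valid <- ce >= config$ce_floor
  structure(list(nf = min(max(fit$mu, 0), 1),
                 nf_raw = fit$mu,
                 nf_sigma = fit$sigma,
                 coupling_efficiency = ce,
                 n_pixels = fit$n,
                 fit_ok = fit$fit_ok,
                 valid = valid,
                 spot_id = images$meta$spot_id %||% NA_character_,
                 condition = images$meta$condition %||% NA_character_),
            class = "spot_result")
}

#' @export
print.spot_result <- function(x, ...) {
  cat(sprintf("<spot_result> %sNF = %.3f +/- %.3f (CE = %.2f, %d px%s%s)\n",
              if (!is.na(x$spot_id)) paste0(x$spot_id, ": ") else "",
              x$nf, x$nf_sigma, x$coupling_efficiency, x$n_pixels,
              if (x$fit_ok) "" else ", fit fallback",
              if (x$valid) "" else ", FLAGGED: not under load"))
  invisible(x)
}

#' Aggregate replicate spots of one condition
#'
#' Mean and sample standard deviation of the per-spot NF values across
#' replicate spots; spots flagged invalid are excluded and counted. With a
#' single valid spot the SD is reported as 0.
#'
#' @param spots List of `spot_result` objects (one condition).
#' @param condition Condition name (default: taken from the first spot).
#' @return An object of class `condition_summary` with `condition`,
#'   `mean_nf`, `sd_nf`, `n_spots`, `n_excluded`.
#' @export
aggregate_condition <- function(spots, condition = NULL) {
  stopifnot(length(spots) >= 1L,
            all(vapply(spots, inherits, logical(1), "spot_result")))
  ok <- vapply(spots, function(s) isTRUE(s$valid), logical(1))
  if (!any(ok)) stop("no valid spots to aggregate")
  nf <- vapply(spots[ok], `[[`, numeric(1), "nf")
  condition <- condition %||% spots[[1]]$condition
  structure(list(condition = condition,
                 mean_nf = mean(nf),
                 sd_nf = if (length(nf) > 1) stats::sd(nf) else 0,
                 n_spots = length(nf),
                 n_excluded = sum(!ok)),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s: NF = %.3f +/- %.3f (n = %d spots%s)\n",
              x$condition, x$mean_nf, x$sd_nf, x$n_spots,
              if (x$n_excluded) paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}

#' Build a condition summary from printed numbers
#'
#' Convenience constructor so published mean +/- SD values can be fed to
#' [compare_conditions()] as worked-example inputs.
#'
#' @param condition Condition name.
#' @param mean_nf,sd_nf Mean and standard deviation of NF.
#' @param n_spots Number of spots behind the summary (default 1).
#' @return A `condition_summary`.
#' @export
condition_summary <- function(condition, mean_nf, sd_nf, n_spots = 1L) {
  stopifnot(is.numeric(mean_nf), is.numeric(sd_nf), sd_nf >= 0, n_spots >= 1)
  structure(list(condition = condition, mean_nf = mean_nf, sd_nf = sd_nf,
                 n_spots = as.integer(n_spots), n_excluded = 0L),
            class = "condition_summary")
}

#' Compare two condition summaries
#'
#' Two conditions are called distinguishable when the difference of their
#' mean NF values exceeds the maximal deviation, defined as the sum of the
#' absolute values of their standard deviations.
#'
#' @param a,b `condition_summary` objects.
#' @return A list with `delta` (`mean_a - mean_b`), `max_deviation`
#'   (`|sd_a| + |sd_b|`) and logical `distinguishable`.
#' @examples
#' a <- condition_summary("sfGFP", 0.353, 0.018)
#' b <- condition_summary("wtGFP", 0.253, 0.018)
#' compare_conditions(a, b)  # delta 0.100 > 0.036: distinguishable
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "condition_summary"), inherits(b, "condition_summary"))
  delta <- a$mean_nf - b$mean_nf
  max_dev <- abs(a$sd_nf) + abs(b$sd_nf)
  list(delta = delta, max_deviation = max_dev,
       distinguishable = abs(delta) > max_dev)
}
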