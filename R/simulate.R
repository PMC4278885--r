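# Synthetic four-channel spot images emulating the assay's optical readout:
# probes at high surface density, Gaussian illumination inhomogeneity,
# incomplete stamp coupling (residual FRET), shot and read noise, with the
# ground-truth rupture fraction supplied by the bond-competition model.

#' Ground truth of one simulated spot
#'
#' @param q_ref_break Fraction of loaded probes whose reference duplex
#'   breaks, in \[0, 1\] — the quantity the assay estimates as NF.
#' @param coupling_efficiency Fraction of probes actually coupled to the
#'   stamp and hence loaded (CE), in \[0, 1\].
#' @param probe_density Mean probes per pixel, > 0. The default of 50 is a
#'   desk-scale stand-in for the assay's ~1e4 probes/um^2 surface density.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(q_ref_break, coupling_efficiency, probe_density = 50) {
  stopifnot(is.numeric(q_ref_break), is.numeric(coupling_efficiency),
            is.numeric(probe_density))
  if (q_ref_break < 0 || q_ref_break > 1) stop("q_ref_break must be in [0, 1]")
  if (coupling_efficiency < 0 || coupling_efficiency > 1) {
    stop("coupling_efficiency must be in [0, 1]")
  }
  if (probe_density <= 0) stop("probe_density must be > 0")
  structure(list(q_ref_break = q_ref_break,
                 coupling_efficiency = coupling_efficiency,
                 probe_density = probe_density),
            class = "ground_truth")
}

#' Optical model of the imaging path
#'
#' Per-channel gains, the relative FRET-channel efficiency (a Cy3-Cy5 FRET
#' pair does not emit like a directly excited Cy5, so the channels are never
#' compared by direct division), an illumination field over the image, and
#' optional per-channel bleaching between the Start and Final exposures.
#'
#' @param gain_red,gain_fret Counts per dye in the RED and FRET channels, > 0.
#' @param fret_factor Relative FRET-channel efficiency in (0, 1\].
#' @param illumination Either `"gaussian"` (2-D Gaussian profile) or
#'   `"uniform"`.
#' @param illum_center Optional c(row, col) center of the Gaussian profile,
#'   0-based pixel coordinates; default image center.
#' @param illum_sigma Gaussian widths c(row, col) in pixels; a scalar is
#'   recycled. Default 0.75 x image size.
#' @param illum_amplitude Peak relative illumination, > 0.
#' @param bleach_red,bleach_fret Multiplicative survival of each channel's
#'   signal between Start and Final images, in (0, 1\]; default 1 (off).
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(gain_red = 120, gain_fret = 100, fret_factor = 0.8,
                          illumination = c("gaussian", "uniform"),
                          illum_center = NULL, illum_sigma = NULL,
                          illum_amplitude = 1,
                          bleach_red = 1, bleach_fret = 1) {
  illumination <- match.arg(illumination)
  if (gain_red <= 0 || gain_fret <= 0) stop("gains must be > 0")
  if (fret_factor <= 0 || fret_factor > 1) stop("fret_factor must be in (0, 1]")
  if (illum_amplitude <= 0) stop("illum_amplitude must be > 0")
  if (bleach_red <= 0 || bleach_red > 1 || bleach_fret <= 0 || bleach_fret > 1) {
    stop("bleach factors must be in (0, 1]")
  }
  structure(list(gain_red = gain_red, gain_fret = gain_fret,
                 fret_factor = fret_factor, illumination = illumination,
                 illum_center = illum_center, illum_sigma = illum_sigma,
                 illum_amplitude = illum_amplitude,
                 bleach_red = bleach_red, bleach_fret = bleach_fret),
            class = "optical_model")
}

#' Camera noise model
#'
#' @param background_offset Constant background level in counts, >= 0.
#' @param read_noise_sd Gaussian read noise SD in counts, >= 0.
#' @param shot_noise Apply Poisson shot noise to the expected counts?
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_offset = 100, read_noise_sd = 2,
                        shot_noise = TRUE) {
  if (background_offset < 0) stop("background_offset must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(background_offset = background_offset,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "noise_model")
}

# Illumination field over an h x w image (matrix of relative intensities).
.illumination_field <- function(optical, shape) {
  h <- shape[1]; w <- shape[2]
  if (optical$illumination == "uniform") {
    return(matrix(optical$illum_amplitude, h, w))
  }
  ctr <- optical$illum_center %||% c((h - 1) / 2, (w - 1) / 2)
  sig <- optical$illum_sigma %||% (0.75 * c(h, w))
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  rows <- (seq_len(h) - 1) - ctr[1]
  cols <- (seq_len(w) - 1) - ctr[2]
  optical$illum_amplitude *
    exp(-outer(rows^2 / (2 * sig[1]^2), cols^2 / (2 * sig[2]^2), `+`))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered circular spot mask (inclusive boundary).
.spot_mask <- function(shape, radius) {
  h <- shape[1]; w <- shape[2]
  rows <- (seq_len(h) - 1) - (h - 1) / 2
  cols <- (seq_len(w) - 1) - (w - 1) / 2
  outer(rows^2, cols^2, `+`) <= radius^2
}

#' Simulate the four fluorescence images of one spot
#'
#' Generates registered RED Start, FRET Start, RED Final and FRET Final
#' images of a single probe spot. Per pixel inside the circular spot mask,
#' the probe count is Poisson with mean `probe_density` and is split
#' multinomially into unloaded probes (fraction `1 - CE`), loaded probes
#' whose reference broke (`CE * q`) and loaded probes whose protein bond
#' broke (`CE * (1 - q)`). The same per-pixel population underlies all four
#' channels, which is what makes the later pixel-by-pixel ratios cancel
#' illumination and density inhomogeneities:
#' * RED Start sees every probe (Cy5 present), FRET Start sees every probe
#'   scaled by the FRET-channel efficiency;
#' * RED Final sees unloaded probes plus reference-broken probes (their Cy5
#'   stayed on the slide);
#' * FRET Final sees only unloaded probes (still fully assembled).
#' Each channel then gains the background offset, optional Poisson shot
#' noise, Gaussian read noise, and is clipped to the 16-bit range and
#' quantized.
#'
#' @param truth A [ground_truth()].
#' @param optical An [optical_model()].
#' @param noise A [noise_model()].
#' @param shape c(height, width) in pixels, each >= 16.
#' @param seed Integer seed; the generator uses a private RNG stream.
#' @param mask_radius Spot radius in pixels (default `0.375 * min(shape)`,
#'   i.e. 48 px at the default 128 x 128 size).
#' @param sampling If `FALSE`, skip all stochastic sampling and return
#'   noise-free expected images (continuous probe fractions, no shot or read
#'   noise, no quantization) — used to assert the expectation identities
#'   exactly.
#' @return An object of class `spot_imageset`: matrices `red_start`,
#'   `fret_start`, `red_final`, `fret_final`, logical `spot_mask`, and
#'   `meta` (seed, mask radius, truth).
#' @export
simulate_spot_imageset <- function(truth, optical, noise,
                                   shape = c(128, 128), seed = 1,
                                   mask_radius = NULL, sampling = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(optical, "optical_model"),
            inherits(noise, "noise_model"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L)) stop("shape must be at least 16 x 16")
  mask_radius <- mask_radius %||% (0.375 * min(shape))
  mask <- .spot_mask(shape, mask_radius)
  if (!any(mask)) stop("spot mask is empty")
  npx <- sum(mask)
  illum <- .illumination_field(optical, shape)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  ce <- truth$coupling_efficiency
  q <- truth$q_ref_break
  if (sampling) {
    n_total <- stats::rpois(npx, truth$probe_density)
    n_unloaded <- stats::rbinom(npx, n_total, 1 - ce)
    n_loaded <- n_total - n_unloaded
    n_refbrk <- stats::rbinom(npx, n_loaded, q)
  } else {
    n_total <- rep(truth$probe_density, npx)
    n_unloaded <- n_total * (1 - ce)
    n_refbrk <- n_total * ce * q
  }

  channel <- function(per_probe_gain, n_probes, bleach = 1) {
    img <- matrix(0, shape[1], shape[2])
    img[mask] <- per_probe_gain * bleach * n_probes
    img <- img * illum + noise$background_offset
    if (sampling) {
      v <- as.vector(img)
      if (noise$shot_noise) v <- stats::rpois(length(v), v)
      if (noise$read_noise_sd > 0) {
        v <- v + stats::rnorm(length(v), 0, noise$read_noise_sd)
      }
      img <- matrix(pmin(pmax(round(v), 0), 65535), shape[1], shape[2])
    }
    img
  }

  red_start <- channel(optical$gain_red, n_total)
  fret_start <- channel(optical$gain_fret * optical$fret_factor, n_total)
  red_final <- channel(optical$gain_red, n_unloaded + n_refbrk,
                       bleach = optical$bleach_red)
  fret_final <- channel(optical$gain_fret * optical$fret_factor, n_unloaded,
                        bleach = optical$bleach_fret)

  structure(list(red_start = red_start, fret_start = fret_start,
                 red_final = red_final, fret_final = fret_final,
                 spot_mask = mask,
                 meta = list(seed = as.integer(seed),
                             mask_radius = mask_radius,
                             shape = shape,
                             truth = truth)),
            class = "spot_imageset")
}

#' @export
print.spot_imageset <- function(x, ...) {
  cat(sprintf("<spot_imageset> %d x %d px, spot radius %.0f px (%d px in mask), seed %d\n",
              nrow(x$red_start), ncol(x$red_start), x$meta$mask_radius,
              sum(x$spot_mask), x$meta$seed))
  invisible(x)
}

# Deterministic per-spot seed expansion from the master seed (kept < 2^31).
.spot_seed <- function(master_seed, spot_index) {
  as.integer((as.numeric(master_seed) * 7919 + spot_index * 104729) %% 2147483647)
}

#' Simulate a full 4 x 4 array experiment
#'
#' Runs the bond-competition model for every condition on the array layout
#' (the true reference-break fraction `q` comes from [first_rupture_prob()]),
#' simulates the four-channel image set of every occupied spot, writes each
#' channel as a 16-bit TIFF, and emits a manifest plus a ground-truth table.
#'
#' @param layout 4 x 4 character matrix of condition names; `NA` or `""`
#'   marks an empty spot. At most 16 occupied spots.
#' @param conditions Named list; each element is a list with fields
#'   `probe` (a [serial_probe()]) and `ce` (coupling efficiency in \[0, 1\]).
#' @param ramp A [force_ramp()].
#' @param optical An [optical_model()].
#' @param noise A [noise_model()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; expanded deterministically into per-spot seeds.
#' @param shape,mask_radius,probe_density Image geometry and density passed
#'   to [simulate_spot_imageset()].
#' @return Invisibly, a list with `manifest` and `truth` data frames (also
#'   written as `manifest.csv` and `ground_truth.csv` in `out_dir`).
#' @export
simulate_array_experiment <- function(layout, conditions, ramp,
                                      optical = optical_model(),
                                      noise = noise_model(),
                                      out_dir, seed = 1,
                                      shape = c(128, 128), mask_radius = NULL,
                                      probe_density = 50) {
  layout <- as.matrix(layout)
  occupied <- which(!is.na(layout) & layout != "", arr.ind = TRUE)
  if (nrow(occupied) == 0L) stop("layout has no occupied spots")
  if (nrow(occupied) > 16L) stop("layout has more than 16 occupied spots")
  used <- unique(layout[occupied])
  missing_cond <- setdiff(used, names(conditions))
  if (length(missing_cond)) {
    bad <- occupied[layout[occupied] %in% missing_cond, , drop = FALSE]
    stop("layout references undefined condition(s) ",
         paste(sQuote(missing_cond), collapse = ", "),
         " at spot(s) ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # q per condition, computed once
  q_by_cond <- vapply(used, function(cn) {
    first_rupture_prob(conditions[[cn]]$probe, ramp)
  }, numeric(1))
  names(q_by_cond) <- used

  channels <- c("red_start", "fret_start", "red_final", "fret_final")
  manifest <- list(); truth_tab <- list()
  ord <- order(occupied[, 1], occupied[, 2])
  occupied <- occupied[ord, , drop = FALSE]
  for (i in seq_len(nrow(occupied))) {
    r <- occupied[i, 1]; cl <- occupied[i, 2]
    cn <- layout[r, cl]
    spot_id <- sprintf("spot_r%dc%d", r, cl)
    spot_index <- (r - 1) * ncol(layout) + cl
    sseed <- .spot_seed(seed, spot_index)
    ce <- conditions[[cn]]$ce %||% 0.8
    truth <- ground_truth(q_ref_break = q_by_cond[[cn]],
                          coupling_efficiency = ce,
                          probe_density = probe_density)
    imgs <- simulate_spot_imageset(truth, optical, noise, shape = shape,
                                   seed = sseed, mask_radius = mask_radius)
    files <- vapply(channels, function(ch) {
      fn <- sprintf("%s_%s.tif", spot_id, ch)
      write_tiff16(imgs[[ch]], file.path(out_dir, fn))
      fn
    }, character(1))
    manifest[[i]] <- data.frame(
      spot_id = spot_id, row = r, col = cl, condition = cn,
      red_start = files[["red_start"]], fret_start = files[["fret_start"]],
      red_final = files[["red_final"]], fret_final = files[["fret_final"]],
      height = shape[1], width = shape[2],
      mask_radius = imgs$meta$mask_radius, seed = sseed,
      stringsAsFactors = FALSE)
    truth_tab[[i]] <- data.frame(
      spot_id = spot_id, condition = cn,
      q_true = q_by_cond[[cn]], coupling_efficiency = ce,
      probe_density = probe_density, seed = sseed,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  truth_tab <- do.call(rbind, truth_tab)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth_tab, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, truth = truth_tab))
}

#' Read one spot's image set back from a manifest row
#'
#' @param manifest_row One row of the manifest data frame written by
#'   [simulate_array_experiment()].
#' @param dir Directory containing the image files.
#' @return A `spot_imageset` reconstructed from disk (mask rebuilt from the
#'   recorded radius).
#' @export
read_spot_imageset <- function(manifest_row, dir) {
  stopifnot(nrow(manifest_row) == 1L)
  imgs <- lapply(c("red_start", "fret_start", "red_final", "fret_final"),
                 function(ch) {
    path <- file.path(dir, manifest_row[[ch]])
    if (!file.exists(path)) {
      stop("missing image file for ", manifest_row$spot_id, ": ", path)
    }
    read_tiff16(path)
  })
  names(imgs) <- c("red_start", "fret_start", "red_final", "fret_final")
  shape <- dim(imgs$red_start)
  mask <- .spot_mask(shape, manifest_row$mask_radius)
  structure(c(imgs,
              list(spot_mask = mask,
                   meta = list(seed = manifest_row$seed,
                               mask_radius = manifest_row$mask_radius,
                               shape = shape,
                               spot_id = manifest_row$spot_id,
                               condition = manifest_row$condition))),
            class = "spot_imageset")
}
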