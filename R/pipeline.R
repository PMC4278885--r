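# Pipeline: JSON experiment config -> simulate -> quantify -> compare, with
# a packaged end-to-end demo. One master seed expands deterministically into
# per-spot seeds so a run is reproducible spot by spot.

#' Read and validate an experiment configuration
#'
#' The configuration is one JSON file describing the whole experiment:
#' ramp parameters, the reference-duplex catalog, per-condition probes
#' (protein characteristic force or explicit Bell parameters, plus the
#' reference name and coupling efficiency), the 4 x 4 spot layout, image
#' geometry, optical and noise models, analysis thresholds, and the master
#' seed. Validation errors name the offending field path.
#'
#' @param path Path to the JSON configuration file.
#' @return A list of class `experiment_config` with constructed model
#'   objects (`ramp`, `conditions` with [serial_probe()]s, `optical`,
#'   `noise`, `analysis`, `layout` matrix, `image`, `seed`, `out_dir`).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fail <- function(field, msg) stop("config$", field, ": ", msg, call. = FALSE)

  seed <- cfg$seed
  if (is.null(seed) || !is.numeric(seed)) fail("seed", "integer master seed required")
  ramp_cfg <- cfg$ramp %||% list()
  ramp <- force_ramp(loading_rate = ramp_cfg$loading_rate,
                     retraction_speed = ramp_cfg$retraction_speed %||% 1,
                     effective_stiffness = ramp_cfg$effective_stiffness %||% 100,
                     kT = ramp_cfg$kT %||% 4.11)
  dx <- cfg$dx %||% 1

  ligands <- default_ligands()
  for (ln in names(cfg$ligands %||% list())) {
    lc <- cfg$ligands[[ln]]
    ligands[[ln]] <- stabilizer_ligand(ln, kd = lc$kd,
                                       concentration = lc$concentration,
                                       delta_force = lc$delta_force)
  }

  refs <- list()
  for (rn in names(cfg$references %||% list())) {
    rc <- cfg$references[[rn]]
    if (is.null(rc$length_bp)) fail(paste0("references$", rn), "length_bp required")
    lig <- NULL
    if (!is.null(rc$ligand)) {
      if (is.null(ligands[[rc$ligand]])) {
        fail(paste0("references$", rn, "$ligand"),
             paste0("unknown ligand '", rc$ligand, "'"))
      }
      lig <- ligands[[rc$ligand]]
    }
    refs[[rn]] <- dna_reference(rn, length_bp = rc$length_bp,
                                geometry = rc$geometry %||% "shear",
                                propynyl_count = rc$propynyl_count %||% 0,
                                ligand = lig)
  }

  if (is.null(cfg$conditions) || !length(cfg$conditions)) {
    fail("conditions", "at least one condition required")
  }
  conditions <- list()
  for (cn in names(cfg$conditions)) {
    cc <- cfg$conditions[[cn]]
    if (is.null(cc$reference)) fail(paste0("conditions$", cn), "reference required")
    if (is.null(refs[[cc$reference]])) {
      fail(paste0("conditions$", cn, "$reference"),
           paste0("unknown reference '", cc$reference, "'"))
    }
    ref_bond <- effective_reference_bond(refs[[cc$reference]], ramp, dx = dx)
    prot <- if (!is.null(cc$protein_force)) {
      bond_from_characteristic_force(cc$protein_force, ramp,
                                     dx = cc$protein_dx %||% dx,
                                     label = paste0(cn, ":protein"))
    } else if (!is.null(cc$protein_k0)) {
      bell_bond(cc$protein_k0, cc$protein_dx %||% dx,
                label = paste0(cn, ":protein"))
    } else {
      fail(paste0("conditions$", cn), "protein_force or protein_k0 required")
    }
    ce <- cc$ce %||% 0.8
    if (ce < 0 || ce > 1) fail(paste0("conditions$", cn, "$ce"), "must be in [0, 1]")
    conditions[[cn]] <- list(probe = serial_probe(prot, ref_bond),
                             ce = ce, reference = cc$reference)
  }

  if (is.null(cfg$layout)) fail("layout", "4 x 4 layout required")
  layout <- if (is.matrix(cfg$layout)) cfg$layout else {
    do.call(rbind, lapply(cfg$layout, as.character))
  }
  layout[layout == ""] <- NA_character_
  if (nrow(layout) != 4L || ncol(layout) != 4L) fail("layout", "must be 4 rows x 4 columns")
  occ <- which(!is.na(layout), arr.ind = TRUE)
  for (i in seq_len(nrow(occ))) {
    cn <- layout[occ[i, 1], occ[i, 2]]
    if (is.null(conditions[[cn]])) {
      fail("layout", sprintf("spot (%d,%d) references undefined condition '%s'",
                             occ[i, 1], occ[i, 2], cn))
    }
  }

  opt_cfg <- cfg$optical %||% list()
  optical <- optical_model(
    gain_red = opt_cfg$gain_red %||% 120,
    gain_fret = opt_cfg$gain_fret %||% 100,
    fret_factor = opt_cfg$fret_factor %||% 0.8,
    illumination = opt_cfg$illumination %||% "gaussian",
    illum_sigma = opt_cfg$illum_sigma,
    illum_amplitude = opt_cfg$illum_amplitude %||% 1,
    bleach_red = opt_cfg$bleach_red %||% 1,
    bleach_fret = opt_cfg$bleach_fret %||% 1)
  noi_cfg <- cfg$noise %||% list()
  noise <- noise_model(background_offset = noi_cfg$background_offset %||% 100,
                       read_noise_sd = noi_cfg$read_noise_sd %||% 2,
                       shot_noise = noi_cfg$shot_noise %||% TRUE)
  ana_cfg <- cfg$analysis %||% list()
  analysis <- analysis_config(
    min_start_counts = ana_cfg$min_start_counts %||% 10,
    fret_ratio_max = ana_cfg$fret_ratio_max %||% 0.995,
    nf_window = ana_cfg$nf_window %||% c(-0.25, 1.25),
    bins = ana_cfg$bins %||% 100,
    min_pixels = ana_cfg$min_pixels %||% 100,
    ce_floor = ana_cfg$ce_floor %||% 0.05)
  img_cfg <- cfg$image %||% list()

  structure(list(seed = as.integer(seed),
                 out_dir = cfg$out_dir %||% "mfa_run",
                 ramp = ramp, dx = dx,
                 references = refs, conditions = conditions,
                 layout = layout,
                 optical = optical, noise = noise, analysis = analysis,
                 image = list(shape = img_cfg$shape %||% c(128L, 128L),
                              mask_radius = img_cfg$mask_radius,
                              probe_density = img_cfg$probe_density %||% 50),
                 raw = cfg),
            class = "experiment_config")
}

.write_provenance <- function(config, out_dir, stage) {
  prov <- list(stage = stage,
               seed = config$seed,
               package_version = as.character(utils::packageVersion("mfassay")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
               config = config$raw)
  jsonlite::write_json(prov, file.path(out_dir, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate an array experiment from a configuration
#'
#' Runs [simulate_array_experiment()] with the configured layout, probes,
#' optics and noise, writes images, manifest, ground truth, a provenance
#' block, and logs each spot's true rupture fraction and coupling
#' efficiency. Idempotent for a fixed seed.
#'
#' @param config An [read_experiment_config()] result (or a path to one).
#' @param out_dir Optional override of the configured output directory.
#' @param quiet Suppress per-spot logging.
#' @return Invisibly, the list returned by [simulate_array_experiment()].
#' @export
run_simulate <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- out_dir %||% config$out_dir
  res <- simulate_array_experiment(
    layout = config$layout, conditions = config$conditions,
    ramp = config$ramp, optical = config$optical, noise = config$noise,
    out_dir = out_dir, seed = config$seed,
    shape = config$image$shape, mask_radius = config$image$mask_radius,
    probe_density = config$image$probe_density)
  .write_provenance(config, out_dir, "simulate")
  if (!quiet) {
    for (i in seq_len(nrow(res$truth))) {
      message(sprintf("simulated %s [%s]: q_true = %.4f, CE = %.2f",
                      res$truth$spot_id[i], res$truth$condition[i],
                      res$truth$q_true[i], res$truth$coupling_efficiency[i]))
    }
  }
  invisible(res)
}

#' Quantify a simulated (or compatible) array experiment
#'
#' Reads the manifest, quantifies every spot, aggregates replicates per
#' condition, and evaluates all pairwise condition comparisons. Writes
#' `results.csv` (spot_id, condition, nf, nf_sigma, ce, n_pixels, fit_ok),
#' `summaries.csv` and `comparisons.csv` next to the manifest.
#'
#' @param manifest Path to `manifest.csv` or the manifest data frame.
#' @param config An `experiment_config` (or path); supplies the analysis
#'   thresholds.
#' @param dir Directory holding the images (default: the manifest's
#'   directory).
#' @return Invisibly, a list with `results`, `summaries`, `comparisons`
#'   data frames and the per-condition `condition_summary` objects. Spots
#'   whose quantification errors are reported in the `error` column; any
#'   errored spot makes the CLI exit nonzero.
#' @export
run_quantify <- function(manifest, config, dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    dir <- dir %||% dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!nrow(manifest)) stop("manifest is empty")
  dir <- dir %||% "."

  rows <- vector("list", nrow(manifest))
  spot_results <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    sr <- tryCatch(quantify_spot(read_spot_imageset(row, dir), config$analysis),
                   error = function(e) e)
    if (inherits(sr, "error")) {
      rows[[i]] <- data.frame(spot_id = row$spot_id, condition = row$condition,
                              nf = NA_real_, nf_sigma = NA_real_, ce = NA_real_,
                              n_pixels = NA_integer_, fit_ok = FALSE,
                              valid = FALSE, error = conditionMessage(sr),
                              stringsAsFactors = FALSE)
    } else {
      spot_results[[i]] <- sr
      rows[[i]] <- data.frame(spot_id = row$spot_id, condition = row$condition,
                              nf = sr$nf, nf_sigma = sr$nf_sigma,
                              ce = sr$coupling_efficiency,
                              n_pixels = sr$n_pixels, fit_ok = sr$fit_ok,
                              valid = sr$valid, error = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)

  conds <- unique(results$condition[results$valid & is.na(results$error)])
  summaries <- lapply(conds, function(cn) {
    idx <- which(results$condition == cn & is.na(results$error))
    aggregate_condition(spot_results[idx], condition = cn)
  })
  names(summaries) <- conds
  summaries_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, mean_nf = s$mean_nf, sd_nf = s$sd_nf,
               n_spots = s$n_spots, n_excluded = s$n_excluded,
               stringsAsFactors = FALSE)
  }))

  comparisons <- .pairwise_comparisons(summaries)

  utils::write.csv(results, file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(summaries_df, file.path(dir, "summaries.csv"), row.names = FALSE)
  utils::write.csv(comparisons, file.path(dir, "comparisons.csv"), row.names = FALSE)
  invisible(list(results = results, summaries = summaries_df,
                 comparisons = comparisons, condition_summaries = summaries,
                 n_errors = sum(!is.na(results$error))))
}

.pairwise_comparisons <- function(summaries) {
  if (length(summaries) < 2L) {
    return(data.frame(condition_a = character(0), condition_b = character(0),
                      delta = numeric(0), max_deviation = numeric(0),
                      distinguishable = logical(0)))
  }
  pairs <- utils::combn(names(summaries), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- summaries[[pairs[1, j]]]; b <- summaries[[pairs[2, j]]]
    cmp <- compare_conditions(a, b)
    data.frame(condition_a = a$condition, condition_b = b$condition,
               delta = cmp$delta, max_deviation = cmp$max_deviation,
               distinguishable = cmp$distinguishable,
               stringsAsFactors = FALSE)
  }))
}

#' Pairwise comparison report from a per-spot results table
#'
#' @param results Path to a `results.csv` written by [run_quantify()], or
#'   the equivalent data frame.
#' @return Data frame of all pairwise condition comparisons.
#' @export
run_compare <- function(results) {
  if (is.character(results)) {
    if (!file.exists(results)) stop("results file not found: ", results)
    results <- utils::read.csv(results, stringsAsFactors = FALSE)
  }
  keep <- results$valid & is.na(results$error)
  results <- results[keep, , drop = FALSE]
  if (!nrow(results)) stop("no valid spots in results")
  summaries <- lapply(split(results, results$condition), function(d) {
    condition_summary(d$condition[1], mean(d$nf),
                      if (nrow(d) > 1) stats::sd(d$nf) else 0, nrow(d))
  })
  .pairwise_comparisons(summaries)
}

#' Path to the packaged demonstration configuration
#' @return File path of the demo JSON config shipped with the package.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.json", package = "mfassay", mustWork = TRUE)
}

#' Run the packaged end-to-end demonstration
#'
#' Simulates the demo array (three nanobody-GFP-like conditions in
#' quadruplicate on a polyamide-stabilized 20 bp reference, plus a
#' four-spot reference-strength sweep for one fixed protein bond),
#' quantifies every spot and reports all pairwise comparisons.
#'
#' @param out_dir Output directory (default a fresh temporary directory).
#' @param seed Optional master-seed override.
#' @param quiet Suppress per-spot logging.
#' @return Invisibly, the [run_quantify()] result plus `truth` and
#'   `out_dir`.
#' @export
run_demo <- function(out_dir = tempfile("mfa_demo_"), seed = NULL, quiet = FALSE) {
  config <- read_experiment_config(demo_config_path())
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- run_simulate(config, out_dir = out_dir, quiet = quiet)
  quant <- run_quantify(file.path(out_dir, "manifest.csv"), config)
  invisible(c(quant, list(truth = sim$truth, out_dir = out_dir)))
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands: `simulate <config.json>`,
#' `quantify <manifest.csv> <config.json>`, `compare <results.csv>`, and
#' `demo [out_dir] [seed]`. Invoked by the packaged script
#' `inst/scripts/mfa.R`:
#' \preformatted{Rscript -e 'mfassay::mfa_cli()' simulate config.json}
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, invisibly (0 on success; nonzero if any spot
#'   errored during quantification).
#' @export
mfa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage:",
    "  mfa simulate <config.json>",
    "  mfa quantify <manifest.csv> <config.json>",
    "  mfa compare <results.csv>",
    "  mfa demo [out_dir] [seed]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  status <- switch(
    cmd,
    simulate = {
      if (length(args) < 2) stop(usage)
      run_simulate(args[2]); 0L
    },
    quantify = {
      if (length(args) < 3) stop(usage)
      res <- run_quantify(args[2], args[3])
      print(res$summaries)
      if (res$n_errors > 0) 1L else 0L
    },
    compare = {
      if (length(args) < 2) stop(usage)
      print(run_compare(args[2])); 0L
    },
    demo = {
      out <- if (length(args) >= 2) args[2] else tempfile("mfa_demo_")
      seed <- if (length(args) >= 3) as.integer(args[3]) else NULL
      res <- run_demo(out_dir = out, seed = seed)
      print(res$summaries); print(res$comparisons)
      if (res$n_errors > 0) 1L else 0L
    },
    { message(usage); 1L })
  invisible(status)
}
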