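# Shared fixtures: all synthetic, built in code.

default_ramp <- function() force_ramp()  # 1e5 pN/s, kT = 4.11

# Probe from two characteristic forces at common dx.
make_probe <- function(f_prot, f_ref, ramp = default_ramp(), dx = 1) {
  serial_probe(
    bond_from_characteristic_force(f_prot, ramp, dx = dx, label = "protein"),
    bond_from_characteristic_force(f_ref, ramp, dx = dx, label = "reference"))
}

# Small, fast image set for unit tests (64 x 64, ~1900 mask pixels).
small_spot <- function(q, ce, seed = 1, optical = optical_model(),
                       noise = noise_model(), density = 50,
                       shape = c(64, 64), sampling = TRUE) {
  simulate_spot_imageset(ground_truth(q, ce, density), optical, noise,
                         shape = shape, seed = seed, sampling = sampling)
}

# Default-size spot (128 x 128, 7232 mask pixels) used where pixel-count
# requirements matter.
full_spot <- function(q, ce, seed = 1, optical = optical_model(),
                      noise = noise_model(), density = 50) {
  simulate_spot_imageset(ground_truth(q, ce, density), optical, noise,
                         shape = c(128, 128), seed = seed)
}

# The five-reference strength sweep used in sensitivity tests: unmodified
# 40 bp shear, propynyl-stabilized 40 bp, and the polyamide-stabilized
# 20 bp duplexes, in the order of decreasing expected NF.
reference_sweep <- function() {
  ligs <- default_ligands()
  list(
    unmod40  = dna_reference("unmod40", 40, "shear"),
    propynyl = dna_reference("propynyl", 40, "shear", propynyl_count = 22),
    p3       = dna_reference("p3", 20, "shear", ligand = ligs$P3),
    p1       = dna_reference("p1", 20, "shear", ligand = ligs$P1),
    p2       = dna_reference("p2", 20, "shear", ligand = ligs$P2))
}

# Minimal in-memory config for pipeline tests (3 conditions, 8 spots).
write_test_config <- function(path, seed = 7, shape = c(64, 64)) {
  cfg <- list(
    seed = seed,
    out_dir = "unused",
    ramp = list(retraction_speed = 1, effective_stiffness = 100, kT = 4.11),
    dx = 1,
    references = list(
      shear40 = list(length_bp = 40, geometry = "shear"),
      shear20_P1 = list(length_bp = 20, geometry = "shear", ligand = "P1")),
    conditions = list(
      weakprot = list(protein_force = 73, reference = "shear20_P1", ce = 0.8),
      strongprot = list(protein_force = 77, reference = "shear20_P1", ce = 0.8),
      vs40 = list(protein_force = 73, reference = "shear40", ce = 0.8)),
    layout = list(
      c("weakprot", "weakprot", "strongprot", "strongprot"),
      c("vs40", "vs40", "weakprot", "strongprot"),
      c("", "", "", ""),
      c("", "", "", "")),
    image = list(shape = shape, probe_density = 50),
    optical = list(gain_red = 120, gain_fret = 100, fret_factor = 0.8,
                   illumination = "gaussian"),
    noise = list(background_offset = 100, read_noise_sd = 2, shot_noise = TRUE),
    analysis = list(min_pixels = 100))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  path
}
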