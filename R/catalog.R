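# DNA reference duplex catalog: geometry, intrinsic (propynyl) and extrinsic
# (hairpin polyamide) stabilization, mapped to characteristic rupture forces.

#' Hairpin polyamide stabilizer ligand
#'
#' A minor-groove-binding hairpin polyamide that stabilizes the reference
#' duplex extrinsically. Occupancy is treated as binary: the ligand
#' contributes its full `delta_force` when present at saturating
#' concentration (>= 1000 x Kd) and nothing otherwise.
#'
#' The default `delta_force` values shipped in [default_ligands()] are NOT
#' physical measurements (no per-ligand force increments are established);
#' they are tunable placeholders chosen once so the catalog reproduces the
#' qualitative reference-strength ordering seen experimentally: every
#' polyamide-stabilized 20 bp duplex outranks the propynyl-stabilized 40 bp
#' duplex, and stabilization follows affinity (P2 > P1 > P3).
#'
#' @param name Ligand name, e.g. "P1".
#' @param kd Dissociation constant in pM, > 0.
#' @param concentration Working concentration in uM, > 0.
#' @param delta_force Force increment added to the duplex characteristic
#'   force when saturated, pN.
#' @return An object of class `stabilizer_ligand`.
#' @export
stabilizer_ligand <- function(name, kd, concentration, delta_force) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(kd), is.numeric(concentration), is.numeric(delta_force))
  if (kd <= 0) stop("kd must be > 0 (pM)")
  if (concentration <= 0) stop("concentration must be > 0 (uM)")
  structure(list(name = name, kd = kd, concentration = concentration,
                 delta_force = delta_force),
            class = "stabilizer_ligand")
}

#' @export
print.stabilizer_ligand <- function(x, ...) {
  cat(sprintf("<stabilizer_ligand> %s: Kd = %.4g pM, c = %.4g uM, dF = %+.3g pN (%s)\n",
              x$name, x$kd, x$concentration, x$delta_force,
              if (is_saturated(x)) "saturated" else "sub-saturating"))
  invisible(x)
}

#' Is a ligand at saturating concentration?
#'
#' Occupancy is treated as binary; a ligand counts as saturated when the
#' working concentration is at least 100 x Kd, i.e. fractional occupancy
#' c/(c + Kd) >= 99% (concentration in uM, Kd in pM; 1 uM = 1e6 pM). All
#' three default polyamides at their 1 uM working concentration pass this
#' comfortably (P3, the weakest binder at Kd 1442 pM, sits at ~693 x Kd).
#'
#' @param ligand A [stabilizer_ligand()].
#' @return Logical.
#' @export
is_saturated <- function(ligand) {
  stopifnot(inherits(ligand, "stabilizer_ligand"))
  ligand$concentration * 1e6 >= 100 * ligand$kd
}

#' Default hairpin polyamide catalog
#'
#' The three sequence-specific hairpin polyamides used with the 20 bp
#' reference, at 1 uM (about 1000 x the saturating concentration):
#' P1 (Kd 105 pM), P2 (Kd 44 pM, chiral amine substituent), P3 (Kd 1442 pM,
#' single binding-site mismatch). The force increments are non-physical
#' defaults; see [stabilizer_ligand()].
#'
#' @return Named list of [stabilizer_ligand()] objects ("P1", "P2", "P3").
#' @export
default_ligands <- function() {
  list(
    P1 = stabilizer_ligand("P1", kd = 105,  concentration = 1, delta_force = 45),
    P2 = stabilizer_ligand("P2", kd = 44,   concentration = 1, delta_force = 55),
    P3 = stabilizer_ligand("P3", kd = 1442, concentration = 1, delta_force = 40)
  )
}

#' DNA reference duplex
#'
#' Describes a reference duplex by its mechanically relevant features:
#' length, pulling geometry (shear: force at opposing 5' termini; zipper:
#' both ends of one strand), number of propynyl-substituted pyrimidines,
#' and an optional bound stabilizer ligand. Sequences, when supplied, are
#' validated only for length and base complementarity.
#'
#' @param name Reference name.
#' @param length_bp Duplex length in base pairs, 1..100.
#' @param geometry `"shear"` or `"zipper"`.
#' @param propynyl_count Number of pyrimidines carrying a 5-propynyl group,
#'   `<= length_bp`. The standard intrinsically stabilized reference replaces
#'   13 cytidines and 9 thymines (22 bases) in a 40 bp duplex.
#' @param ligand Optional [stabilizer_ligand()].
#' @param sequence,complement Optional strand sequences (5'->3' top strand
#'   and its reverse complement); checked for length `length_bp` and
#'   Watson-Crick complementarity.
#' @return An object of class `dna_reference`.
#' @examples
#' dna_reference("ref40", 40, "shear")
#' dna_reference("ref20+P1", 20, "shear", ligand = default_ligands()$P1)
#' @export
dna_reference <- function(name, length_bp, geometry = c("shear", "zipper"),
                          propynyl_count = 0, ligand = NULL,
                          sequence = NULL, complement = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(length_bp), length(length_bp) == 1L,
            is.numeric(propynyl_count), length(propynyl_count) == 1L)
  length_bp <- as.integer(length_bp)
  propynyl_count <- as.integer(propynyl_count)
  if (length_bp < 1L || length_bp > 100L) stop("length_bp must be in 1..100")
  if (propynyl_count < 0L || propynyl_count > length_bp) {
    stop("propynyl_count must be in 0..length_bp")
  }
  if (!is.null(ligand)) stopifnot(inherits(ligand, "stabilizer_ligand"))
  if (!is.null(sequence)) {
    .check_duplex_sequence(sequence, complement, length_bp)
  }
  structure(list(name = name, length_bp = length_bp, geometry = geometry,
                 propynyl_count = propynyl_count, ligand = ligand,
                 sequence = sequence, complement = complement),
            class = "dna_reference")
}

.check_duplex_sequence <- function(sequence, complement, length_bp) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) != length_bp) {
    stop("sequence length does not match length_bp")
  }
  if (!grepl("^[ACGT]+$", sequence)) stop("sequence must contain only A/C/G/T")
  if (!is.null(complement)) {
    complement <- toupper(gsub("\\s", "", complement))
    if (nchar(complement) != length_bp) stop("complement length does not match length_bp")
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(complement, "")[[1]]), collapse = ""))
    if (rc != sequence) stop("strands are not Watson-Crick complementary")
  }
  invisible(TRUE)
}

#' @export
print.dna_reference <- function(x, ...) {
  mods <- character(0)
  if (x$propynyl_count > 0) mods <- c(mods, sprintf("%d propynyl bases", x$propynyl_count))
  if (!is.null(x$ligand)) mods <- c(mods, paste0("+", x$ligand$name))
  cat(sprintf("<dna_reference> %s: %d bp %s%s -> F* = %.3g pN\n",
              x$name, x$length_bp, x$geometry,
              if (length(mods)) paste0(" (", paste(mods, collapse = ", "), ")") else "",
              characteristic_force(x)))
  invisible(x)
}

#' Characteristic rupture force of a reference duplex
#'
#' Maps duplex features to the most probable rupture force under the assay's
#' loading regime. Zipper-mode unzipping proceeds at about 15 pN regardless
#' of length. Shear-mode duplexes anchor at 65 pN for 40 bp — the overstretch
#' (BS-transition) plateau that short oligonucleotides cannot exceed — and
#' intermediate lengths are interpolated linearly in base pairs and capped at
#' the plateau: `65 * min(length_bp, 40) / 40`. Propynyl substitutions add
#' `propynyl_increment` pN per substituted base; a saturated stabilizer
#' ligand adds its `delta_force`. The linear length model and the
#' stabilization increments are deliberately simple, documented defaults —
#' replaceable, not measured.
#'
#' @param reference A [dna_reference()].
#' @param propynyl_increment Force per propynyl base, pN (default 0.3).
#' @return Characteristic force in pN.
#' @examples
#' characteristic_force(dna_reference("r", 40, "shear"))   # 65
#' characteristic_force(dna_reference("r", 12, "zipper"))  # 15
#' @export
characteristic_force <- function(reference, propynyl_increment = 0.3) {
  stopifnot(inherits(reference, "dna_reference"))
  base <- switch(reference$geometry,
                 zipper = 15,
                 shear = 65 * min(reference$length_bp, 40L) / 40,
                 stop("invalid geometry"))
  f <- base + reference$propynyl_count * propynyl_increment
  if (!is.null(reference$ligand) && is_saturated(reference$ligand)) {
    f <- f + reference$ligand$delta_force
  }
  if (f <= 0) stop("characteristic force must be > 0")
  f
}

#' Effective Bell bond of a reference duplex
#'
#' Bridges the catalog to the kinetic model: converts the duplex's
#' characteristic force into the Bell bond whose most probable rupture force
#' under the given ramp reproduces it.
#'
#' @param reference A [dna_reference()].
#' @param ramp A [force_ramp()].
#' @param dx Potential width in nm for the effective bond.
#' @param propynyl_increment Passed to [characteristic_force()].
#' @return A [bell_bond()] labelled after the reference.
#' @export
effective_reference_bond <- function(reference, ramp, dx = 1,
                                     propynyl_increment = 0.3) {
  f <- characteristic_force(reference, propynyl_increment)
  bond_from_characteristic_force(f, ramp, dx = dx, label = reference$name)
}
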