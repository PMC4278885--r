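# Bell-model rupture kinetics for two bonds loaded in series by a linear
# force ramp. Forces in pN, lengths in nm, rates in 1/s, kT in pN*nm.

#' Breakable bond under the Bell model
#'
#' A single-barrier bond whose force-dependent off-rate follows the Bell law
#' \eqn{k(F) = k_0 \exp(F \Delta x / k_B T)}. This is the mechanical identity
#' of either member of a Molecular Force Probe: the protein complex under
#' study or the DNA reference duplex.
#'
#' @param k0 Zero-force off-rate in 1/s. Must be non-negative; `k0 = 0`
#'   describes an unbreakable anchor.
#' @param dx Potential width in nm (distance to the transition state along the
#'   pulling direction). Must be non-negative; `dx = 0` gives a
#'   force-insensitive bond.
#' @param label Free-text label, non-empty.
#' @return An object of class `bell_bond`.
#' @seealso [bell_rate()], [serial_probe()], [bond_from_characteristic_force()]
#' @examples
#' bell_bond(k0 = 1e-4, dx = 1.0, label = "40 bp shear duplex")
#' @export
bell_bond <- function(k0, dx, label = "bond") {
  stopifnot(is.numeric(k0), length(k0) == 1L, is.finite(k0),
            is.numeric(dx), length(dx) == 1L, is.finite(dx))
  if (k0 < 0) stop("k0 must be >= 0 (1/s)")
  if (dx < 0) stop("dx must be >= 0 (nm)")
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("label must be a non-empty string")
  }
  structure(list(k0 = k0, dx = dx, label = label), class = "bell_bond")
}

#' @export
print.bell_bond <- function(x, ...) {
  cat(sprintf("<bell_bond> %s: k0 = %.4g 1/s, dx = %.4g nm\n",
              x$label, x$k0, x$dx))
  invisible(x)
}

#' Linear force ramp
#'
#' The loading protocol of the assay: the stamp retracts at constant speed so
#' the force on every probe grows linearly in time at rate
#' `loading_rate = retraction_speed * effective_stiffness`. The assay's
#' stated regime is a retraction speed of 1 um/s yielding a loading rate of
#' order 1e5 pN/s; the default effective stiffness of 100 pN/nm is the value
#' that makes that pair exact (1 um/s = 1000 nm/s, x 100 pN/nm = 1e5 pN/s).
#'
#' @param loading_rate Loading rate in pN/s. Give either this or both
#'   `retraction_speed` and `effective_stiffness`.
#' @param retraction_speed Stamp retraction speed in um/s.
#' @param effective_stiffness Effective spring constant of the probe/stamp
#'   series in pN/nm.
#' @param kT Thermal energy in pN*nm; default 4.11 (T = 298 K).
#' @return An object of class `force_ramp` with fields `loading_rate` and
#'   `kT` (and the speed/stiffness decomposition when given).
#' @examples
#' force_ramp()                          # 1 um/s x 100 pN/nm = 1e5 pN/s
#' force_ramp(loading_rate = 2e5)
#' @export
force_ramp <- function(loading_rate = NULL, retraction_speed = 1,
                       effective_stiffness = 100, kT = 4.11) {
  stopifnot(is.numeric(kT), length(kT) == 1L, is.finite(kT))
  if (kT <= 0) stop("kT must be > 0 (pN*nm)")
  if (is.null(loading_rate)) {
    stopifnot(is.numeric(retraction_speed), is.numeric(effective_stiffness))
    if (retraction_speed <= 0 || effective_stiffness <= 0) {
      stop("retraction_speed and effective_stiffness must be > 0")
    }
    # um/s * pN/nm = 1000 nm/s * pN/nm = 1000 pN/s
    loading_rate <- retraction_speed * 1000 * effective_stiffness
  } else {
    stopifnot(is.numeric(loading_rate), length(loading_rate) == 1L)
    if (loading_rate <= 0) stop("loading_rate must be > 0 (pN/s)")
    retraction_speed <- NA_real_
    effective_stiffness <- NA_real_
  }
  structure(list(loading_rate = loading_rate,
                 retraction_speed = retraction_speed,
                 effective_stiffness = effective_stiffness,
                 kT = kT),
            class = "force_ramp")
}

#' @export
print.force_ramp <- function(x, ...) {
  cat(sprintf("<force_ramp> r = %.4g pN/s, kT = %.3g pN*nm\n",
              x$loading_rate, x$kT))
  invisible(x)
}

#' Molecular Force Probe: two bonds in series
#'
#' One probe of the assay: the protein complex and the DNA reference duplex
#' share the same force, and exactly one of them ruptures under load. Anchors
#' (biotin-streptavidin, covalent attachments) are treated as unbreakable, so
#' these two bonds are the only admissible failure points.
#'
#' @param protein_bond,reference_bond [bell_bond()] objects.
#' @return An object of class `serial_probe`.
#' @export
serial_probe <- function(protein_bond, reference_bond) {
  stopifnot(inherits(protein_bond, "bell_bond"),
            inherits(reference_bond, "bell_bond"))
  structure(list(protein_bond = protein_bond,
                 reference_bond = reference_bond),
            class = "serial_probe")
}

#' @export
print.serial_probe <- function(x, ...) {
  cat("<serial_probe>\n  protein:   ")
  print(x$protein_bond)
  cat("  reference: ")
  print(x$reference_bond)
  invisible(x)
}

#' Bell off-rate at a given force
#'
#' @param bond A [bell_bond()].
#' @param force Applied force in pN, non-negative (vectorized).
#' @param kT Thermal energy in pN*nm, positive.
#' @return Off-rate(s) in 1/s: `k0 * exp(force * dx / kT)`.
#' @examples
#' bell_rate(bell_bond(1e-4, 1.0), force = 41.1, kT = 4.11)  # 1e-4 * e^10
#' @export
bell_rate <- function(bond, force, kT = 4.11) {
  stopifnot(inherits(bond, "bell_bond"), is.numeric(force), is.numeric(kT))
  if (any(force < 0)) stop("force must be >= 0 (pN)")
  if (kT <= 0) stop("kT must be > 0 (pN*nm)")
  bond$k0 * exp(force * bond$dx / kT)
}

# Integrated Bell hazard dF: int_0^F k(F') dF'
# = k0*kT/dx * (exp(dx*F/kT) - 1) for dx > 0, else k0*F. Vectorized in F.
.bell_hazard_integral <- function(bond, force, kT) {
  if (bond$dx > 0) {
    bond$k0 * kT / bond$dx * expm1(bond$dx * force / kT)
  } else {
    bond$k0 * force
  }
}

# Force at which the joint survival probability of the probe drops to `surv`
# under ramp r: solves (H_ref(F) + H_prot(F)) / r = -log(surv).
.truncation_force <- function(probe, ramp, surv = 1e-12) {
  target <- -log(surv)
  h <- function(f) {
    (.bell_hazard_integral(probe$reference_bond, f, ramp$kT) +
       .bell_hazard_integral(probe$protein_bond, f, ramp$kT)) /
      ramp$loading_rate - target
  }
  upper <- 1
  while (h(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e12) stop("no rupture possible at reachable forces")
  }
  stats::uniroot(h, c(0, upper), tol = 1e-9 * upper)$root
}

#' Probability that the reference bond ruptures first
#'
#' Under a linear ramp the first-rupture identity for two independent Bell
#' bonds sharing the force is
#' \deqn{p_{ref} = \int_0^\infty \frac{k_{ref}(F)}{r}
#'   \exp\left(-\frac{1}{r}\int_0^F [k_{ref}(F') + k_{prot}(F')]\,dF'\right) dF.}
#' This probability equals the expected Normalized Fluorescence of the spot:
#' 0.5 means both bonds are equally strong, values near 1 mean the protein
#' complex outlasts the reference.
#'
#' The inner integral is evaluated in closed form; the outer integral by
#' adaptive quadrature (relative tolerance 1e-6), truncated where the joint
#' survival falls below 1e-12.
#'
#' @param probe A [serial_probe()].
#' @param ramp A [force_ramp()].
#' @return Probability in \[0, 1\] that the reference breaks first.
#' @seealso [simulate_ruptures_kmc()] for the stochastic oracle.
#' @examples
#' b <- bell_bond(1e-3, 1.0)
#' first_rupture_prob(serial_probe(b, b), force_ramp())  # 0.5 by symmetry
#' @export
first_rupture_prob <- function(probe, ramp) {
  stopifnot(inherits(probe, "serial_probe"), inherits(ramp, "force_ramp"))
  kref0 <- probe$reference_bond$k0
  kprot0 <- probe$protein_bond$k0
  if (kref0 == 0 && kprot0 == 0) stop("no rupture possible: both bonds have k0 = 0")
  if (kref0 == 0) return(0)
  if (kprot0 == 0) return(1)
  fmax <- .truncation_force(probe, ramp)
  r <- ramp$loading_rate
  integrand <- function(f) {
    bell_rate(probe$reference_bond, f, ramp$kT) / r *
      exp(-(.bell_hazard_integral(probe$reference_bond, f, ramp$kT) +
              .bell_hazard_integral(probe$protein_bond, f, ramp$kT)) / r)
  }
  p <- stats::integrate(integrand, 0, fmax, rel.tol = 1e-6, abs.tol = 0,
                        subdivisions = 1000L)$value
  min(max(p, 0), 1)
}

#' Kinetic Monte Carlo rupture sampling
#'
#' Statistically exact sampling of which bond breaks first under the ramp:
#' the rupture force is drawn by inverse transform on the joint cumulative
#' hazard (monotone Newton iteration seeded from a tabulated inverse), and
#' the broken bond is then chosen by a Bernoulli split on the instantaneous
#' hazard ratio at that force. Serves as the independent oracle for
#' [first_rupture_prob()].
#'
#' @param probe A [serial_probe()].
#' @param ramp A [force_ramp()].
#' @param n Number of probes to simulate, >= 1.
#' @param seed Integer seed; the call uses its own RNG stream and restores
#'   the caller's.
#' @return An object of class `rupture_stats`: counts of reference/protein
#'   ruptures, mean rupture force (pN), and the seed.
#' @examples
#' b <- bell_bond(1e-3, 1.0)
#' simulate_ruptures_kmc(serial_probe(b, b), force_ramp(), n = 1000, seed = 7)
#' @export
simulate_ruptures_kmc <- function(probe, ramp, n, seed) {
  stopifnot(inherits(probe, "serial_probe"), inherits(ramp, "force_ramp"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (probe$reference_bond$k0 == 0 && probe$protein_bond$k0 == 0) {
    stop("no rupture possible: both bonds have k0 = 0")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  r <- ramp$loading_rate
  kT <- ramp$kT
  lam <- function(f) {   # cumulative hazard of the joint first-rupture time
    (.bell_hazard_integral(probe$reference_bond, f, kT) +
       .bell_hazard_integral(probe$protein_bond, f, kT)) / r
  }
  lam_d <- function(f) { # its derivative dLambda/dF = k_tot(F)/r
    (bell_rate(probe$reference_bond, f, kT) +
       bell_rate(probe$protein_bond, f, kT)) / r
  }
  target <- stats::rexp(n)   # -log(U), exponential(1) quantiles of the hazard
  fmax <- .truncation_force(probe, ramp, surv = exp(-max(target)) * 0.5)
  grid <- seq(0, fmax, length.out = 4096L)
  f <- stats::approx(lam(grid), grid, xout = target, rule = 2)$y
  for (i in 1:30) {   # Newton polish; Lambda is smooth, convex, increasing
    step <- (lam(f) - target) / lam_d(f)
    f <- pmax(f - step, 0)
    if (max(abs(step)) < 1e-10 * max(f, 1)) break
  }
  p_ref <- bell_rate(probe$reference_bond, f, kT) /
    (bell_rate(probe$reference_bond, f, kT) + bell_rate(probe$protein_bond, f, kT))
  ref_broken <- stats::runif(n) < p_ref
  structure(list(n_trials = n,
                 n_reference_broken = sum(ref_broken),
                 n_protein_broken = n - sum(ref_broken),
                 mean_rupture_force = mean(f),
                 seed = as.integer(seed)),
            class = "rupture_stats")
}

#' @export
print.rupture_stats <- function(x, ...) {
  cat(sprintf(
    "<rupture_stats> n = %d: reference broke %d (%.3f), protein broke %d; <F*> = %.2f pN\n",
    x$n_trials, x$n_reference_broken, x$n_reference_broken / x$n_trials,
    x$n_protein_broken, x$mean_rupture_force))
  invisible(x)
}

#' Most probable rupture force of a single Bell bond
#'
#' The mode of the rupture-force distribution under a linear ramp,
#' \eqn{F^* = (k_B T/\Delta x)\,\ln(r \Delta x / (k_0 k_B T))}, floored at 0.
#' Used to calibrate catalog reference duplexes.
#'
#' @param bond A [bell_bond()] with `k0 > 0` and `dx > 0`.
#' @param ramp A [force_ramp()].
#' @return Most probable rupture force in pN.
#' @seealso [bond_from_characteristic_force()] for the inverse.
#' @export
most_probable_rupture_force <- function(bond, ramp) {
  stopifnot(inherits(bond, "bell_bond"), inherits(ramp, "force_ramp"))
  if (bond$k0 <= 0 || bond$dx <= 0) stop("requires k0 > 0 and dx > 0")
  f <- ramp$kT / bond$dx *
    log(ramp$loading_rate * bond$dx / (bond$k0 * ramp$kT))
  max(f, 0)
}

#' Build a Bell bond from its characteristic rupture force
#'
#' Inverse of [most_probable_rupture_force()]: given the force a bond should
#' most probably rupture at under the ramp, returns the Bell bond with
#' \eqn{k_0 = (r \Delta x / k_B T) \exp(-F \Delta x / k_B T)} at the chosen
#' potential width.
#'
#' @param force Target most-probable rupture force in pN, > 0.
#' @param ramp A [force_ramp()].
#' @param dx Potential width in nm, > 0 (default 1).
#' @param label Bond label.
#' @return A [bell_bond()] whose [most_probable_rupture_force()] equals `force`.
#' @examples
#' b <- bond_from_characteristic_force(65, force_ramp())
#' most_probable_rupture_force(b, force_ramp())  # 65
#' @export
bond_from_characteristic_force <- function(force, ramp, dx = 1, label = "bond") {
  stopifnot(is.numeric(force), length(force) == 1L, inherits(ramp, "force_ramp"))
  if (force <= 0) stop("force must be > 0 (pN)")
  if (!is.numeric(dx) || dx <= 0) stop("dx must be > 0 (nm)")
  k0 <- ramp$loading_rate * dx / ramp$kT * exp(-force * dx / ramp$kT)
  bell_bond(k0 = k0, dx = dx, label = label)
}

#' Sensitivity curve of the assay around a reference bond
#'
#' Sweeps the protein bond strength across a grid of characteristic forces
#' (at fixed potential width) against one reference bond and reports the
#' expected Normalized Fluorescence and its local slope with respect to
#' protein force. Like a balance scale, the assay discriminates best where
#' it is balanced: the absolute slope is maximal where NF is nearest 0.5.
#'
#' @param reference A [bell_bond()] for the reference duplex.
#' @param protein_force_grid Sorted, non-empty vector of protein
#'   characteristic forces in pN.
#' @param ramp A [force_ramp()].
#' @param dx Potential width used for the swept protein bonds, nm.
#' @return A data frame with columns `protein_force`, `nf`, `slope`
#'   (central-difference d NF / d F, 1/pN).
#' @export
sensitivity_curve <- function(reference, protein_force_grid, ramp, dx = 1) {
  stopifnot(inherits(reference, "bell_bond"), inherits(ramp, "force_ramp"))
  g <- protein_force_grid
  if (length(g) == 0L) stop("protein_force_grid must be non-empty")
  if (is.unsorted(g, strictly = TRUE)) stop("protein_force_grid must be sorted, strictly increasing")
  nf <- vapply(g, function(f) {
    prot <- bond_from_characteristic_force(f, ramp, dx = dx, label = "protein")
    first_rupture_prob(serial_probe(prot, reference), ramp)
  }, numeric(1))
  n <- length(g)
  slope <- rep(NA_real_, n)
  if (n >= 2) {
    slope[1] <- (nf[2] - nf[1]) / (g[2] - g[1])
    slope[n] <- (nf[n] - nf[n - 1]) / (g[n] - g[n - 1])
    if (n >= 3) {
      idx <- 2:(n - 1)
      slope[idx] <- (nf[idx + 1] - nf[idx - 1]) / (g[idx + 1] - g[idx - 1])
    }
  }
  data.frame(protein_force = g, nf = nf, slope = slope)
}
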