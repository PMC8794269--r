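# Effective-viscosity model for plasma and nanoparticle-laden plasma.
#
# Blood in embryos lacking red blood cells is treated as plasma alone; when a
# lipid nanoemulsion is injected to restore viscous load, the suspension is
# modeled with the Corcione empirical correlation, which expresses the
# effective dynamic viscosity of a dilute nanofluid relative to its base
# fluid through the particle diameter d_p, an equivalent base-fluid molecule
# diameter d_f, and the particle volume fraction phi.

AVOGADRO <- 6.022e23 # mol^-1

# Correlation validity ranges reported with the fit.
CORCIONE_PHI_RANGE <- c(1e-4, 0.071)
CORCIONE_DP_RANGE <- c(25e-9, 200e-9) # m

#' Base-fluid physical parameters
#'
#' Bundles the physical constants of the base fluid needed by the
#' effective-viscosity model.  Defaults describe zebrafish blood plasma:
#' dynamic viscosity 1.5 mPa s (approximately constant over rearing
#' temperatures), mean molecular weight 100 kDa (weight-averaged over the
#' plasma protein profile), and density 997 kg/m3 at the reference
#' temperature 293 K.  Temperature is carried for provenance only; the
#' correlation itself is temperature-free in this formulation.
#'
#' @param mu_f dynamic viscosity of the base fluid (mPa s).
#' @param M molecular weight of the base fluid (kg/mol).
#' @param rho_f0 mass density at the reference temperature (kg/m3).
#' @param T0 reference temperature (K).
#' @return object of class `fluid_spec`.
#' @export
fluid_spec <- function(mu_f = 1.5, M = 100, rho_f0 = 997, T0 = 293) {
  stopifnot(is.numeric(mu_f), is.numeric(M), is.numeric(rho_f0))
  if (mu_f <= 0 || M <= 0 || rho_f0 <= 0) {
    stop("mu_f, M and rho_f0 must all be positive")
  }
  structure(list(mu_f = mu_f, M = M, rho_f0 = rho_f0, T0 = T0),
            class = "fluid_spec")
}

#' Nanofluid parameters
#'
#' @param fluid a [fluid_spec()].
#' @param d_p nanoparticle diameter (m).
#' @param phi nanoparticle volume fraction (dimensionless, in `[0, 1)`).
#' @return object of class `nanofluid_spec`; `$in_validity` records whether
#'   `phi` and `d_p` lie in the ranges over which the correlation was fitted
#'   (volume fractions 1e-4 to 0.071, particle sizes 25 to 200 nm).
#' @export
nanofluid_spec <- function(fluid, d_p, phi) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (d_p <= 0) stop("d_p must be > 0")
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  in_validity <- (phi == 0 ||
    (phi >= CORCIONE_PHI_RANGE[1] && phi <= CORCIONE_PHI_RANGE[2])) &&
    d_p >= CORCIONE_DP_RANGE[1] && d_p <= CORCIONE_DP_RANGE[2]
  structure(list(fluid = fluid, d_p = d_p, phi = phi,
                 in_validity = in_validity),
            class = "nanofluid_spec")
}

#' Equivalent diameter of a base-fluid molecule
#'
#' `d_f = 0.1 * (6 M / (N pi rho_f0))^(1/3)` with N Avogadro's number: the
#' diameter a base-fluid molecule would have if the fluid were a simple
#' packing of spheres, rescaled by the empirical 0.1 prefactor of the
#' correlation.  For the plasma defaults (M = 100 kg/mol, rho = 997 kg/m3)
#' this is about 6.83e-10 m.
#'
#' @param fluid a [fluid_spec()].
#' @return equivalent molecule diameter (m).
#' @export
equivalent_molecule_diameter <- function(fluid) {
  stopifnot(inherits(fluid, "fluid_spec"))
  0.1 * (6 * fluid$M / (AVOGADRO * pi * fluid$rho_f0))^(1 / 3)
}

#' Effective dynamic viscosity of a nanofluid
#'
#' Corcione correlation:
#' `mu_eff / mu_f = 1 / (1 - 34.87 (d_p / d_f)^(-0.3) phi^1.03)`.
#' The ratio is dimensionless and independent of `mu_f`; `phi = 0` returns
#' the base-fluid viscosity exactly.  An error is raised when the correlation
#' diverges (`34.87 (d_p/d_f)^(-0.3) phi^1.03 >= 1`); parameters outside the
#' fitted validity ranges produce a warning, not an error, because the plasma
#' `d_p/d_f` ratio itself sits at the edge of the tested regime.
#'
#' @param spec a [nanofluid_spec()].
#' @return object of class `effective_viscosity`: a list with `mu_eff`
#'   (mPa s), `ratio` (`mu_eff / mu_f`), `phi`, `d_p`, `d_f`, and
#'   `in_validity`.
#' @examples
#' plasma <- fluid_spec()
#' effective_viscosity(nanofluid_spec(plasma, d_p = 95e-9, phi = 0.01))
#' @export
effective_viscosity <- function(spec) {
  stopifnot(inherits(spec, "nanofluid_spec"))
  d_f <- equivalent_molecule_diameter(spec$fluid)
  term <- if (spec$phi == 0) 0 else {
    34.87 * (spec$d_p / d_f)^(-0.3) * spec$phi^1.03
  }
  if (term >= 1) {
    stop("Corcione correlation diverges for these parameters (34.87 (d_p/d_f)^-0.3 phi^1.03 >= 1)")
  }
  if (!spec$in_validity) {
    warning("phi or d_p outside the correlation's fitted validity range; result is an extrapolation")
  }
  ratio <- 1 / (1 - term)
  structure(list(mu_eff = spec$fluid$mu_f * ratio, ratio = ratio,
                 mu_f = spec$fluid$mu_f, phi = spec$phi, d_p = spec$d_p,
                 d_f = d_f, in_validity = spec$in_validity),
            class = "effective_viscosity")
}

#' @export
print.effective_viscosity <- function(x, ...) {
  cat("Effective viscosity (Corcione correlation)\n")
  cat(sprintf("  mu_f   = %.4g mPa s, phi = %.4g, d_p = %.3g m, d_f = %.3g m\n",
              x$mu_f, x$phi, x$d_p, x$d_f))
  cat(sprintf("  mu_eff = %.6g mPa s (ratio %.6g)\n", x$mu_eff, x$ratio))
  if (!x$in_validity) cat("  note: parameters outside the fitted validity range\n")
  invisible(x)
}

#' Nanoparticle volume fraction after intravascular injection
#'
#' Computes the circulating volume fraction after injecting a stock
#' suspension into the bloodstream, assuming complete mixing:
#' `phi = stock_fraction * injected / (injected + blood)`.  Also returns the
#' simple dilution factor `blood / injected` for comparison against the
#' bench convention of matching concentration by diluting the stock 1:13 in
#' buffer (4.6 nl injected into an assumed 60 nl total blood volume).
#'
#' @param stock_fraction droplet volume fraction of the injected stock
#'   (dimensionless, in `[0, 1]`).
#' @param injected_volume injected volume (nl); default 4.6.
#' @param blood_volume total blood volume (nl); default 60.
#' @return list with `phi` and `dilution_factor`.
#' @examples
#' injection_volume_fraction(1, 4.6, 60)$dilution_factor # ~13
#' @export
injection_volume_fraction <- function(stock_fraction, injected_volume = 4.6,
                                      blood_volume = 60) {
  if (stock_fraction < 0 || stock_fraction > 1) {
    stop("stock_fraction must be in [0, 1]")
  }
  if (injected_volume <= 0 || blood_volume <= 0) stop("volumes must be > 0")
  list(
    phi = stock_fraction * injected_volume / (injected_volume + blood_volume),
    dilution_factor = blood_volume / injected_volume
  )
}
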