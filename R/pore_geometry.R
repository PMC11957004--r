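#' @include utils.R
NULL

#' Glass-nanopipette pore geometry
#'
#' An S4 container for the geometry of a conical glass nanopipette pore and
#' the electrolyte it is filled with. The pore is modelled as a truncated
#' cone: the tip diameter `tipDiameter` (nm) widens along the taper either at
#' a fixed half-cone angle `halfConeAngle` (degrees) or over an explicit
#' `taperLength` (um) to the base diameter. Exactly one of the angle or the
#' taper length drives the cone model; the other is derived from it together
#' with the base diameter.
#'
#' @slot tipDiameter numeric(1), tip (sensing) diameter in nm.
#' @slot halfConeAngle numeric(1), half-cone angle in degrees, in (0, 90).
#' @slot taperLength numeric(1), taper length in um (NA when the angle drives
#'   the cone).
#' @slot baseDiameter numeric(1), base diameter in nm; defaults to a wide
#'   capillary bore so that the cone resistance is dominated by the tip.
#' @slot bufferConductivity numeric(1), electrolyte conductivity in S/m.
#'   No default is shipped: the measurement buffer (e.g. 4 M LiCl) must be
#'   characterised by the user and supplied in the run configuration.
#' @slot biasVoltage numeric(1), applied bias in mV (metadata; the conductance
#'   model is ohmic).
#'
#' @seealso [poreGeometry()], [conductanceFromGeometry()],
#'   [diameterFromConductance()], [amplitudeScale()]
#' @export
setClass("PoreGeometry",
  representation(
    tipDiameter = "numeric",
    halfConeAngle = "numeric",
    taperLength = "numeric",
    baseDiameter = "numeric",
    bufferConductivity = "numeric",
    biasVoltage = "numeric"
  )
)

setValidity("PoreGeometry", function(object) {
  msg <- character()
  if (length(object@tipDiameter) != 1L || !is.finite(object@tipDiameter) ||
      object@tipDiameter <= 0) {
    msg <- c(msg, "tipDiameter must be a single positive number (nm)")
  }
  angle_set <- length(object@halfConeAngle) == 1L && is.finite(object@halfConeAngle)
  taper_set <- length(object@taperLength) == 1L && is.finite(object@taperLength)
  if (angle_set && taper_set) {
    msg <- c(msg, "exactly one of halfConeAngle or taperLength may be set; the other is derived")
  }
  if (!angle_set && !taper_set) {
    msg <- c(msg, "one of halfConeAngle or taperLength must be set")
  }
  if (angle_set && (object@halfConeAngle <= 0 || object@halfConeAngle >= 90)) {
    msg <- c(msg, "halfConeAngle must lie in (0, 90) degrees")
  }
  if (taper_set && object@taperLength <= 0) {
    msg <- c(msg, "taperLength must be positive (um)")
  }
  if (length(object@baseDiameter) == 1L && is.finite(object@baseDiameter) &&
      object@baseDiameter <= object@tipDiameter) {
    msg <- c(msg, "baseDiameter must exceed tipDiameter")
  }
  if (length(object@bufferConductivity) != 1L || !is.finite(object@bufferConductivity) ||
      object@bufferConductivity <= 0) {
    msg <- c(msg, "bufferConductivity must be a single positive number (S/m)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PoreGeometry
#'
#' @param tipDiameter tip diameter, nm.
#' @param bufferConductivity electrolyte conductivity, S/m (required; the
#'   package ships no default for any buffer).
#' @param halfConeAngle half-cone angle, degrees. Supply either this or
#'   `taperLength`, not both.
#' @param taperLength taper length, um.
#' @param baseDiameter base diameter, nm. Defaults to 5e5 nm (0.5 mm bore),
#'   effectively a semi-infinite cone.
#' @param biasVoltage applied bias, mV (metadata only).
#'
#' @return A [PoreGeometry-class] object.
#' @examples
#' pg <- poreGeometry(tipDiameter = 10, halfConeAngle = 5, bufferConductivity = 20)
#' conductanceFromGeometry(pg)
#' @export
poreGeometry <- function(tipDiameter, bufferConductivity,
                         halfConeAngle = NA_real_, taperLength = NA_real_,
                         baseDiameter = 5e5, biasVoltage = 400) {
  new("PoreGeometry",
      tipDiameter = as.numeric(tipDiameter),
      halfConeAngle = as.numeric(halfConeAngle),
      taperLength = as.numeric(taperLength),
      baseDiameter = as.numeric(baseDiameter),
      bufferConductivity = as.numeric(bufferConductivity),
      biasVoltage = as.numeric(biasVoltage))
}

#' @rdname poreGeometry
#' @param object,x a `PoreGeometry`.
#' @export
setMethod("show", "PoreGeometry", function(object) {
  cat("PoreGeometry: tip", format(object@tipDiameter), "nm")
  if (is.finite(object@halfConeAngle)) {
    cat(", half-cone angle", format(object@halfConeAngle), "deg")
  } else {
    cat(", taper length", format(object@taperLength), "um")
  }
  cat(", sigma", format(object@bufferConductivity), "S/m\n")
  cat("  open-pore conductance:",
      format(conductanceFromGeometry(object), digits = 4), "nS\n")
  invisible(NULL)
})

#' @rdname poreGeometry
#' @export
tipDiameter <- function(x) {
  stopifnot(is(x, "PoreGeometry"))
  x@tipDiameter
}

## Taper length in m for a geometry (derived from the angle when needed).
.taper_length_m <- function(geom) {
  d_tip <- geom@tipDiameter * 1e-9
  d_base <- geom@baseDiameter * 1e-9
  if (is.finite(geom@taperLength)) {
    geom@taperLength * 1e-6
  } else {
    # base reached after L = (d_base - d_tip) / (2 tan theta)
    (d_base - d_tip) / (2 * tan(geom@halfConeAngle * pi / 180))
  }
}

#' Open-pore conductance of a conical nanopore
#'
#' The standard glass-nanopipette model: bulk resistance of a truncated cone,
#' `R_cone = 4 L / (sigma * pi * d_tip * d_base)`, in series with single-side
#' access resistance `R_access = 1 / (sigma * d_tip)`. The conductance is
#' `G = 1 / (R_cone + R_access)`, strictly increasing in the tip diameter and
#' linear in the conductivity.
#'
#' @param geom a [PoreGeometry-class].
#' @return Open-pore conductance in nS.
#' @export
conductanceFromGeometry <- function(geom) {
  stopifnot(is(geom, "PoreGeometry"))
  validObject(geom)
  sigma <- geom@bufferConductivity
  d_tip <- geom@tipDiameter * 1e-9
  d_base <- geom@baseDiameter * 1e-9
  L <- .taper_length_m(geom)
  r_cone <- 4 * L / (sigma * pi * d_tip * d_base)
  r_access <- 1 / (sigma * d_tip)
  1 / (r_cone + r_access) * 1e9
}

#' Estimate pore diameter from open-pore conductance
#'
#' Inverts [conductanceFromGeometry()] for the tip diameter by bracketed root
#' search over `[0.1 nm, 10 um]`, given the cone angle (or taper length) and
#' the buffer conductivity. This mirrors the experimental practice of sizing
#' a pore from the open-pore conductance measured in an IV sweep.
#'
#' @param G measured open-pore conductance, nS.
#' @param geomPrior a [PoreGeometry-class] carrying the angle/taper and
#'   conductivity; its `tipDiameter` is ignored (but must be valid).
#' @return Estimated tip diameter in nm. The round trip through
#'   [conductanceFromGeometry()] reproduces `G` to relative tolerance 1e-9.
#' @export
diameterFromConductance <- function(G, geomPrior) {
  stopifnot(is(geomPrior, "PoreGeometry"))
  if (!is.finite(G) || G <= 0) {
    stop("conductance must be a positive number (nS)")
  }
  f <- function(d_nm) {
    g <- geomPrior
    g@tipDiameter <- d_nm
    conductanceFromGeometry(g) - G
  }
  lo <- 0.1
  hi <- 1e4  # 10 um in nm
  if (f(lo) > 0 || f(hi) < 0) {
    stop("no pore diameter in [0.1 nm, 10 um] matches conductance ", G, " nS")
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Pore-size scaling of blockage amplitudes
#'
#' Relative current blockades shrink as the pore widens: a molecule excludes
#' a fixed cross-section, so the blockade scales as the inverse square of the
#' tip diameter. Returns `(dRef / dTip)^2`, the factor by which the simulator
#' multiplies species blockage amplitudes quoted at the reference diameter.
#'
#' @param dTip pore tip diameter, nm.
#' @param dRef reference diameter at which species amplitudes are quoted, nm.
#' @param exponent scaling exponent; 2 (cross-sectional exclusion) by default.
#' @return Dimensionless scale factor, strictly decreasing in `dTip`.
#' @export
amplitudeScale <- function(dTip, dRef, exponent = 2) {
  if (any(!is.finite(c(dTip, dRef))) || any(c(dTip, dRef) <= 0)) {
    stop("diameters must be positive")
  }
  (dRef / dTip)^exponent
}
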