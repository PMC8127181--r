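#' @include AllClasses.R
NULL

#' Allometric ODBA-to-oxygen calibration constants
#'
#' Intercept and slope of the linear relation between ODBA and the rate of
#' oxygen consumption Vo (ml O2 min^-1), scaled allometrically with mean
#' adult body mass: intercept = 2.75 BM^0.73, slope = 3.52 BM^0.94. For a
#' 5.2 kg gentoo this yields Vo = 9.16 + ODBA * 16.58; for a 3.7 kg
#' chinstrap, Vo = 7.15 + ODBA * 12.04.
#'
#' @param BM mean adult body mass, kg (> 0).
#' @return named numeric `c(intercept, slope)`.
#' @export
voParams <- function(BM) {
  if (!is.numeric(BM) || any(BM <= 0)) stop("BM must be > 0", call. = FALSE)
  c(intercept = 2.75 * BM^0.73, slope = 3.52 * BM^0.94)
}

#' Energy content of oxygen as a power conversion factor
#'
#' The uptake of 1 l O2 corresponds to roughly 20 kJ, so 1 ml O2 min^-1
#' equals 20 J / 60 s = 0.333 J s^-1.
#'
#' @param kJPerL energy equivalent of oxygen, kJ per litre.
#' @return J s^-1 per (ml O2 min^-1).
#' @export
o2ToPowerFactor <- function(kJPerL = 20) kJPerL / 60

#' Construct species-level energetic parameters
#'
#' Defaults describe a gentoo penguin: 5.2 kg mean adult mass, 2.3 m s^-1
#' commuting swim speed, 16.1 W kg^-1 minimum mass-specific cost of
#' transport (swim-canal and at-sea estimates), and the rounded oxygen
#' conversion 0.333 J s^-1 per ml O2 min^-1. The Vo calibration constants
#' are derived from [voParams()] unless explicitly overridden.
#'
#' @param BM body mass, kg.
#' @param swimSpeed m s^-1.
#' @param transportCost W kg^-1.
#' @param o2ToPower J s^-1 per (ml O2 min^-1).
#' @param voIntercept,voSlope optional overrides, ml O2 min^-1.
#' @return a [SpeciesParams-class].
#' @export
speciesParams <- function(BM = 5.2, swimSpeed = 2.3, transportCost = 16.1,
                          o2ToPower = 0.333, voIntercept = NULL,
                          voSlope = NULL) {
  vp <- voParams(BM)
  new("SpeciesParams", BM = BM, swimSpeed = swimSpeed,
      transportCost = transportCost,
      voIntercept = voIntercept %||% unname(vp["intercept"]),
      voSlope = voSlope %||% unname(vp["slope"]),
      o2ToPower = o2ToPower)
}

#' Rate of oxygen consumption from an ODBA value
#'
#' Vo = intercept + slope * ODBA (ml O2 min^-1). The ODBA argument must be
#' on the same unit convention (per-dive g-sample sums at the recorded
#' sampling rate) used when the calibration regressions were fitted.
#'
#' @param odba ODBA value(s), >= 0.
#' @param species a [SpeciesParams-class].
#' @return Vo in ml O2 min^-1.
#' @export
voFromOdba <- function(odba, species) {
  if (any(odba < 0)) stop("ODBA must be >= 0", call. = FALSE)
  species@voIntercept + species@voSlope * odba
}

#' Mass-specific power from oxygen consumption
#'
#' MP = Vo * o2ToPower / BM, in J kg^-1 s^-1.
#'
#' @param vo ml O2 min^-1, >= 0.
#' @param species a [SpeciesParams-class].
#' @return J kg^-1 s^-1.
#' @export
massSpecificPower <- function(vo, species)
  vo * species@o2ToPower / species@BM

#' One-way cost of travelling to a location
#'
#' Travel time TT = distance / swim speed; CT = TT * transport cost
#' (J kg^-1, one way — the landscape doubles it for the return leg).
#'
#' @param distance metres, >= 0.
#' @param species a [SpeciesParams-class].
#' @return J kg^-1.
#' @export
costOfTravel <- function(distance, species) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  (distance / species@swimSpeed) * species@transportCost
}

#' Class-wise diving cost over a trip (trapezoidal depth gradient)
#'
#' Cost of all dives of one class during a trip, assuming dives span a
#' gradient of bottom depths from 3 m (the minimum depth counted as a
#' dive) out to the target depth, so the power per dive is the
#' trapezoidal mean of MP at 3 m and MP at the target depth:
#' `DD * (mpAt3m + mpAtDepth) * MND / 2 * proportion` (J kg^-1).
#'
#' @param DD dive duration of the class, s.
#' @param mpAt3m,mpAtDepth mass-specific power at 3 m and at the target
#'   depth, J kg^-1 s^-1.
#' @param MND number of dives per trip.
#' @param proportion class proportion in `[0, 1]`.
#' @return J kg^-1.
#' @export
mpMnd <- function(DD, mpAt3m, mpAtDepth, MND, proportion) {
  stopifnot(all(DD >= 0), all(mpAt3m >= 0), all(mpAtDepth >= 0),
            all(MND >= 0), all(proportion >= 0 & proportion <= 1))
  DD * (mpAt3m + mpAtDepth) * MND / 2 * proportion
}

#' Total cost of foraging
#'
#' TCF = MP_MND_benthic + MP_MND_pelagic + 2 * CT; the travel cost is
#' doubled for the return to the colony.
#'
#' @param mpMndBenthic,mpMndPelagic J kg^-1, from [mpMnd()].
#' @param CT one-way travel cost, J kg^-1.
#' @return J kg^-1.
#' @export
totalCostForaging <- function(mpMndBenthic, mpMndPelagic, CT)
  mpMndBenthic + mpMndPelagic + 2 * CT

#' Total bottom time over a trip
#'
#' Birds start diving close to the colony and deepen their dives with
#' distance, so the benthic bottom time per dive is averaged between the
#' minimum observed benthic bottom time and the bottom time predicted at
#' the cell's depth: `TBT = (mBBT + BBT)/2 * MND * pBD + PBT * MND * pPD`.
#'
#' @param mBBT minimum observed benthic bottom time, s.
#' @param BBT benthic bottom time at the target depth, s.
#' @param PBT pelagic bottom time (at the median pelagic depth), s.
#' @param MND dives per trip.
#' @param pBD,pPD class proportions (must sum to 1).
#' @return s. Zero values should be flagged by the caller before forming
#'   the TRC ratio.
#' @export
totalBottomTime <- function(mBBT, BBT, PBT, MND, pBD, pPD) {
  stopifnot(all(abs(pBD + pPD - 1) < 1e-9))
  (mBBT + BBT) / 2 * MND * pBD + PBT * MND * pPD
}

#' Total relative cost of foraging
#'
#' TRC = TCF / TBT, in J kg^-1 s^-1 — the energy-landscape value: the
#' mass-specific total cost of foraging (diving plus commuting) per unit
#' bottom time (the proxy for energy gain).
#'
#' @param TCF J kg^-1.
#' @param TBT s, must be > 0 (non-positive cells are flagged upstream and
#'   excluded from the landscape).
#' @return J kg^-1 s^-1.
#' @export
totalRelativeCost <- function(TCF, TBT) {
  if (any(TBT <= 0))
    stop("TBT must be > 0; flag and exclude such cells", call. = FALSE)
  TCF / TBT
}
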