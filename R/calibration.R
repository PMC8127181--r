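#' @include AllClasses.R
NULL

# family registry shared by the calibration fits and the synthetic
# generator's true laws; order here is the deterministic tie-break order
.regressionFamilies <- function() list(
  linear = list(
    npar = 2L,
    fn = function(x, coef) coef[1] + coef[2] * x,
    fit = function(x, y) {
      fit <- stats::lm(y ~ x)
      stats::setNames(as.numeric(stats::coef(fit)), c("a", "b"))
    }),
  power = list(
    npar = 2L,
    fn = function(x, coef) coef[1] * x^coef[2],
    fit = function(x, y) {
      ok <- x > 0 & y > 0
      if (sum(ok) < 3L) stop("power family needs positive data")
      st <- stats::coef(stats::lm(log(y[ok]) ~ log(x[ok])))
      fit <- minpack.lm::nlsLM(y ~ a * x^b,
                               start = list(a = exp(st[1]), b = st[2]),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
      stats::setNames(as.numeric(stats::coef(fit)), c("a", "b"))
    }),
  exprise = list(
    npar = 2L,
    fn = function(x, coef) coef[1] * (1 - exp(-coef[2] * x)),
    fit = function(x, y) {
      st <- list(a = max(y) * 1.05 + 1e-9,
                 b = 1 / max(stats::median(x), 1e-9))
      fit <- minpack.lm::nlsLM(y ~ a * (1 - exp(-b * x)), start = st,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
      stats::setNames(as.numeric(stats::coef(fit)), c("a", "b"))
    }),
  quadratic = list(
    npar = 3L,
    fn = function(x, coef) coef[1] + coef[2] * x + coef[3] * x^2,
    fit = function(x, y) {
      fit <- stats::lm(y ~ x + I(x^2))
      stats::setNames(as.numeric(stats::coef(fit)), c("a", "b", "c"))
    }))

.evalLaw <- function(law, x)
  .regressionFamilies()[[law$family]]$fn(x, law$coef)

.rsquared <- function(y, yhat) {
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) return(0)
  max(0, min(1, 1 - sum((y - yhat)^2) / sstot))
}

#' Fit one response-vs-predictor relationship, selecting the best family
#'
#' Every requested family is fitted by least squares on the untransformed
#' response (nonlinear families via Levenberg-Marquardt), and the family
#' with the highest R^2 on the original scale is selected; ties (within
#' 1e-9) go to the family with fewer parameters, then to registry order
#' (linear, power, exprise, quadratic), so selection is deterministic.
#' All candidate fits are attached as the `"fitLog"` attribute.
#'
#' @param x,y numeric vectors (n >= 3).
#' @param families character subset of the family registry.
#' @param response,predictor,diveClass metadata stored on the model.
#' @return a [RegressionModel-class] with attribute `fitLog`.
#' @export
fitBestModel <- function(x, y,
                         families = c("linear", "power", "exprise",
                                      "quadratic"),
                         response = "y", predictor = "x",
                         diveClass = "all") {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L)
    stop("need >= 3 observations to fit '", diveClass, "' (have ",
         length(x), ")", call. = FALSE)
  reg <- .regressionFamilies()
  families <- intersect(names(reg), families)
  if (!length(families)) stop("no known family requested", call. = FALSE)
  cand <- lapply(families, function(fam) {
    f <- reg[[fam]]
    coef <- tryCatch(f$fit(x, y), error = function(e) NULL)
    if (is.null(coef) || anyNA(coef)) return(NULL)
    list(family = fam, coef = coef, npar = f$npar,
         r2 = .rsquared(y, f$fn(x, coef)))
  })
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand))
    stop("no family could be fitted for '", diveClass, "'", call. = FALSE)
  r2 <- vapply(cand, `[[`, numeric(1), "r2")
  npar <- vapply(cand, `[[`, numeric(1), "npar")
  best <- order(-round(r2 / 1e-9) * 1e-9, npar, seq_along(cand))[1L]
  sel <- cand[[best]]
  m <- new("RegressionModel", response = response, predictor = predictor,
           diveClass = diveClass, family = sel$family, coef = sel$coef,
           r2 = sel$r2, n = length(x), trainRange = range(x))
  attr(m, "fitLog") <- cand
  m
}

.fitPerClass <- function(dives, response, families, predictor = "maxDepth") {
  out <- list()
  for (cls in c("benthic", "pelagic")) {
    sub <- dives[dives$class == cls, , drop = FALSE]
    if (nrow(sub) < 3L)
      stop("class '", cls, "' has ", nrow(sub),
           " dives; >= 3 required", call. = FALSE)
    out[[cls]] <- fitBestModel(sub[[predictor]], sub[[response]],
                               families = families, response = response,
                               predictor = predictor, diveClass = cls)
  }
  out
}

#' Fit per-dive ODBA sum vs. maximum dive depth, per dive class
#'
#' The depth-dependence of dive cost differs between benthic and pelagic
#' dives, so each class is fitted separately over the candidate families.
#'
#' @param dives labelled dive table (`class`, `maxDepth`, `odbaSum`).
#' @param families candidate family names, see [fitBestModel()].
#' @return list with elements `benthic` and `pelagic`
#'   ([RegressionModel-class]).
#' @export
fitOdbaDepth <- function(dives,
                         families = c("linear", "power", "exprise",
                                      "quadratic"))
  .fitPerClass(dives, "odbaSum", families)

#' Fit bottom time vs. maximum dive depth, per dive class
#' @inheritParams fitOdbaDepth
#' @return list with elements `benthic` and `pelagic`.
#' @export
fitBottomtimeDepth <- function(dives,
                               families = c("linear", "power", "exprise",
                                            "quadratic"))
  .fitPerClass(dives, "bottomTime", families)

#' Fit dives-per-trip vs. maximum trip distance
#'
#' Used in the variable-MND (distance-dependent) landscape mode, where the
#' number of dives per trip grows with the maximum distance from the
#' colony.
#'
#' @param trips list of [ForagingTrip-class] objects.
#' @param families candidate family names.
#' @return a [RegressionModel-class] (response `nDives`, predictor
#'   `maxDistanceKm`).
#' @export
fitDivesVsDistance <- function(trips,
                               families = c("linear", "power", "exprise",
                                            "quadratic")) {
  if (length(trips) < 3L) stop("need >= 3 trips", call. = FALSE)
  x <- vapply(trips, function(tr) tr@maxDistanceKm, numeric(1))
  y <- vapply(trips, function(tr) nrow(tr@dives), numeric(1))
  fitBestModel(x, y, families = families, response = "nDives",
               predictor = "maxDistanceKm", diveClass = "all")
}

#' Predict from a fitted regression model
#'
#' Predictions beyond `[min, 1.25 * max]` of the training predictor range
#' emit a warning but are still returned — landscape cells routinely lie
#' beyond the deepest observed dive, and the extrapolation is deliberate
#' but loud. Physically impossible values are floored: at 1 for dive
#' counts (`nDives` response), at 0 otherwise.
#'
#' @param object a [RegressionModel-class].
#' @param newdata numeric vector of predictor values.
#' @param warnExtrapolation logical.
#' @return numeric predictions.
#' @export
setMethod("predict", "RegressionModel",
  function(object, newdata, warnExtrapolation = TRUE) {
    lo <- object@trainRange[1]; hi <- 1.25 * object@trainRange[2]
    out <- newdata < lo | newdata > hi
    if (warnExtrapolation && any(out))
      warning(sum(out), " prediction(s) of ", object@response,
              " outside training range [", signif(lo, 4), ", ",
              signif(hi, 4), "] (extrapolation)", call. = FALSE)
    p <- unname(.regressionFamilies()[[object@family]]$fn(newdata,
                                                          object@coef))
    pmax(p, if (object@response == "nDives") 1 else 0)
  })
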