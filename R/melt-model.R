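#' Soluble protein fraction at a temperature
#'
#' Evaluates the sigmoid melting model
#' \eqn{f(T) = (1 - plateau)/(1 + e^{-(a/T - b)}) + plateau}
#' at one or more temperatures (degrees Celsius). This is the quantity an
#' isothermal shift assay samples at its single assay temperature.
#'
#' @param object a [MeltCurve-class].
#' @param temperature numeric vector of temperatures in degrees Celsius,
#'   all \code{> 0}. Recycled against the curves in \code{object} by the
#'   usual rules (use a length-1 \code{object} to evaluate one curve on a
#'   temperature grid, or equal lengths for elementwise evaluation).
#' @return numeric vector of soluble fractions in \code{(plateau, 1)}.
#' @examples
#' fractionSoluble(MeltCurve(520, 10, 0), 52)   # 0.5: T = a/b is the midpoint
#' @export
setGeneric("fractionSoluble",
    function(object, temperature) standardGeneric("fractionSoluble"))

#' @rdname fractionSoluble
#' @export
setMethod("fractionSoluble", "MeltCurve", function(object, temperature) {
    if (any(!is.finite(temperature)) || any(temperature <= 0))
        stop("'temperature' must be finite and positive (degrees Celsius)")
    .fractionSoluble(object@a, object@b, object@plateau, temperature)
})

# vectorized core, shared with the curve fitter
.fractionSoluble <- function(a, b, plateau, temperature) {
    (1 - plateau) / (1 + exp(-(a / temperature - b))) + plateau
}

#' Melting temperature of a curve
#'
#' The temperature at which the fitted soluble fraction equals 0.5,
#' in closed form: \eqn{T_m = a / (b + \log(1 - 2\,plateau))}. Defined
#' only for curves with \code{plateau < 0.5}; curves that never drop to
#' 0.5 have no melting point and raise an error.
#'
#' @param object a [MeltCurve-class] with all \code{plateau < 0.5}.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' meltingTemperature(MeltCurve(550, 10, 0))    # 55
#' @export
setGeneric("meltingTemperature",
    function(object) standardGeneric("meltingTemperature"))

#' @rdname meltingTemperature
#' @export
setMethod("meltingTemperature", "MeltCurve", function(object) {
    if (any(object@plateau >= 0.5))
        stop("no melting point: 'plateau' must be < 0.5 for Tm to exist")
    .meltingTemperature(object@a, object@b, object@plateau)
})

.meltingTemperature <- function(a, b, plateau) {
    ifelse(plateau < 0.5, a / (b + log(1 - 2 * plateau)), NA_real_)
}

#' Curve slope at the melting temperature
#'
#' Analytic derivative of the soluble fraction with respect to temperature,
#' evaluated at Tm (per degree Celsius; negative for any valid curve).
#' This is the "curve slope" quantity used by the gradient-design quality
#' filter (slope < -0.06). At \code{plateau = 0} it reduces to
#' \eqn{-a / (4 T_m^2)}, the slope at the inflection point.
#'
#' @inheritParams meltingTemperature
#' @return numeric vector of slopes (negative).
#' @export
setGeneric("slopeAtTm", function(object) standardGeneric("slopeAtTm"))

#' @rdname slopeAtTm
#' @export
setMethod("slopeAtTm", "MeltCurve", function(object) {
    if (any(object@plateau >= 0.5))
        stop("no melting point: 'plateau' must be < 0.5 for Tm to exist")
    .slopeAtTm(object@a, object@b, object@plateau)
})

# f(T) = (1-p) s(u) + p with u = a/T - b, s the logistic function.
# f'(T) = (1-p) s(u)(1-s(u)) (-a/T^2); at Tm, s(u) = (0.5-p)/(1-p).
.slopeAtTm <- function(a, b, plateau) {
    tm <- .meltingTemperature(a, b, plateau)
    s <- (0.5 - plateau) / (1 - plateau)
    (1 - plateau) * s * (1 - s) * (-a / tm^2)
}

#' Differential solubility at one temperature (delta Y)
#'
#' The drug-minus-vehicle difference in soluble fraction at a single assay
#' temperature: the effect size an isothermal shift assay measures.
#' Positive values indicate ligand-induced stabilization.
#'
#' @param vehicle,drug [MeltCurve-class] objects for the two conditions.
#' @param temperature assay temperature(s) in degrees Celsius, \code{> 0}.
#' @return numeric vector of signed solubility differences.
#' @export
deltaY <- function(vehicle, drug, temperature) {
    fractionSoluble(drug, temperature) -
        fractionSoluble(vehicle, temperature)
}

#' Melting-temperature shift (delta Tm)
#'
#' The drug-minus-vehicle difference in melting temperature: the effect
#' size a thermal-gradient (TPP-style) analysis estimates. Positive values
#' indicate stabilization.
#'
#' @inheritParams deltaY
#' @return numeric vector of Tm shifts in degrees Celsius.
#' @export
deltaTm <- function(vehicle, drug) {
    meltingTemperature(drug) - meltingTemperature(vehicle)
}
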