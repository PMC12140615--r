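#' Number of parcels (state dimension) of an object
#'
#' @param x A \linkS4class{MindyModel}, \linkS4class{CombinedDynamics},
#'   \linkS4class{ToySnic}, \linkS4class{ParcelTimeseries} or
#'   \linkS4class{DerivativeSamples} object.
#' @return Integer scalar.
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' One-step change of a dynamical system
#'
#' Evaluates the discrete-time vector field \eqn{\Delta x = f(x)} of a model at
#' one or many states. For a \linkS4class{MindyModel} this is
#' \eqn{W\psi_\alpha(x) - D \odot x}; for a \linkS4class{CombinedDynamics} it is
#' the convex combination \eqn{\gamma f_1(x) + (1-\gamma) f_2(x)}; for a
#' \linkS4class{ToySnic} it is the planar SNIC normal form scaled by its
#' integration step.
#'
#' @param dynamics A dynamics object.
#' @param x Numeric state vector of length \code{nParcels(dynamics)}, or a
#'   matrix with one state per row.
#' @return Same shape as \code{x}: the one-step change at each state.
#' @export
setGeneric("deltaState", function(dynamics, x) standardGeneric("deltaState"))

#' Advance a dynamical system by one step
#'
#' @inheritParams deltaState
#' @return \code{x + deltaState(dynamics, x)}.
#' @export
setGeneric("stepState", function(dynamics, x) standardGeneric("stepState"))
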