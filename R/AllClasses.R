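#' @import methods
#' @importFrom stats rbinom runif median quantile rnbinom rlnorm rpois sd var
#'   setNames complete.cases shapiro.test ks.test dist coef lm qnorm
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics hist
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib nevusdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameters of the cell-autonomous (stage-model) arrest simulator
#'
#' A clone grows from a single founder by synchronous cell cycles. In the
#' \code{"founder_divides"} variant every proliferating cell divides each
#' cycle and each daughter then advances one stage with probability \code{s}
#' (advancing out of the last stage is permanent arrest); in
#' \code{"founder_may_arrest"} the stage-advance test is applied to every
#' cell (including the founder) \emph{before} it divides, and an arrested
#' cell never divides. \code{stages = 1} is the classical one-hit model in
#' which \code{s} is simply the per-cycle arrest probability.
#'
#' @slot variant character, \code{"founder_divides"} (default) or
#'   \code{"founder_may_arrest"}.
#' @slot s numeric in \[0, 1\]; per-cycle per-daughter stage-transition
#'   (arrest) probability.
#' @slot stages integer >= 1; number of sequential stages.
#' @slot horizon integer >= 1; cell-cycle cap (30 cycles is a generous upper
#'   bound for mouse nevi, which stop growing within 2-3 weeks).
#'
#' @export
setClass("StageModelParams",
  representation(variant = "character", s = "numeric",
                 stages = "integer", horizon = "integer"),
  prototype(variant = "founder_divides", s = 0.5, stages = 1L, horizon = 30L))

setValidity("StageModelParams", function(object) {
  msg <- character()
  if (!object@variant %in% c("founder_divides", "founder_may_arrest"))
    msg <- c(msg, "variant must be 'founder_divides' or 'founder_may_arrest'")
  if (length(object@s) != 1L || is.na(object@s) || object@s < 0 || object@s > 1)
    msg <- c(msg, "s must be a single probability in [0, 1]")
  if (length(object@stages) != 1L || is.na(object@stages) || object@stages < 1L)
    msg <- c(msg, "stages must be a positive integer")
  if (length(object@horizon) != 1L || is.na(object@horizon) || object@horizon < 1L)
    msg <- c(msg, "horizon must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct stage-model parameters
#'
#' @param s per-cycle stage-transition (arrest) probability.
#' @param stages number of sequential stages (1 = single-stage).
#' @param variant update-order variant; see \linkS4class{StageModelParams}.
#' @param horizon cell-cycle cap.
#' @return A \linkS4class{StageModelParams} object.
#' @examples
#' StageModelParams(s = 0.56)
#' @export
StageModelParams <- function(s = 0.5, stages = 1L,
                             variant = c("founder_divides", "founder_may_arrest"),
                             horizon = 30L) {
  variant <- match.arg(variant)
  new("StageModelParams", variant = variant, s = as.numeric(s),
      stages = as.integer(stages), horizon = as.integer(horizon))
}

#' Parameters of the renewal-control (collective arrest) model
#'
#' Renewal probability \eqn{p} -- the probability that each offspring of a
#' cell division remains dividing -- falls with the number of arrested cells
#' \eqn{A} through a Hill function,
#' \deqn{p(A) = p_{max} \frac{K^h}{K^h + A^h},}
#' with half-max \eqn{K} (default 50 arrested cells) and Hill coefficient
#' \eqn{h} (default 1). This is an integral negative feedback: the arrested
#' pool integrates past divisions and throttles renewal.
#'
#' The default \code{p_max = 0.9} is strictly below 1 so that the arrest
#' flux \eqn{1 - p} is nonzero before any cell has arrested; at
#' \code{p_max = 1} exactly, a clone started with zero arrested cells would
#' never seed the feedback and would grow without bound.
#'
#' @slot p_max maximal renewal probability (0, 1].
#' @slot half_max arrested-cell count at half-maximal effect (> 0).
#' @slot hill_coeff Hill coefficient (>= 1).
#' @slot initial_dividing starting number of dividing cells.
#' @slot cycle_time cell-cycle duration in arbitrary time units (mean-field
#'   ODE form only; the stochastic form is synchronous in cycles).
#' @slot horizon_cycles cycle cap for the stochastic form.
#' @export
setClass("FeedbackParams",
  representation(p_max = "numeric", half_max = "numeric", hill_coeff = "numeric",
                 initial_dividing = "integer", cycle_time = "numeric",
                 horizon_cycles = "integer"),
  prototype(p_max = 0.9, half_max = 50, hill_coeff = 1, initial_dividing = 1L,
            cycle_time = 1, horizon_cycles = 1000L))

setValidity("FeedbackParams", function(object) {
  msg <- character()
  if (object@p_max <= 0 || object@p_max > 1)
    msg <- c(msg, "p_max must be in (0, 1]")
  if (object@half_max <= 0) msg <- c(msg, "half_max must be > 0")
  if (object@hill_coeff < 1) msg <- c(msg, "hill_coeff must be >= 1")
  if (object@initial_dividing < 1L)
    msg <- c(msg, "initial_dividing must be >= 1")
  if (object@cycle_time <= 0) msg <- c(msg, "cycle_time must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct renewal-control parameters
#'
#' @param p_max maximal renewal probability.
#' @param half_max arrested-cell count at half-maximal feedback.
#' @param hill_coeff Hill coefficient.
#' @param initial_dividing starting number of dividing cells.
#' @param cycle_time cell-cycle duration (ODE form).
#' @param horizon_cycles cycle cap for stochastic runs.
#' @return A \linkS4class{FeedbackParams} object.
#' @examples
#' FeedbackParams()                    # the default model
#' FeedbackParams(half_max = 500)      # weaker feedback, larger clones
#' @export
FeedbackParams <- function(p_max = 0.9, half_max = 50, hill_coeff = 1,
                           initial_dividing = 1L, cycle_time = 1,
                           horizon_cycles = 1000L) {
  new("FeedbackParams", p_max = as.numeric(p_max), half_max = as.numeric(half_max),
      hill_coeff = as.numeric(hill_coeff),
      initial_dividing = as.integer(initial_dividing),
      cycle_time = as.numeric(cycle_time),
      horizon_cycles = as.integer(horizon_cycles))
}

#' A clone-size distribution
#'
#' Sparse size -> count map over an ensemble of simulated (or analytically
#' sampled) clones, with any truncation threshold that has been applied.
#'
#' @slot sizes integer vector of distinct clone sizes (ascending).
#' @slot counts integer vector of clone counts per size.
#' @slot n_clones total clones after truncation.
#' @slot truncation_threshold threshold below which clones were removed
#'   (0 = none).
#' @export
setClass("SizeDistribution",
  representation(sizes = "integer", counts = "integer",
                 n_clones = "integer", truncation_threshold = "numeric"),
  prototype(sizes = integer(), counts = integer(), n_clones = 0L,
            truncation_threshold = 0))

setValidity("SizeDistribution", function(object) {
  msg <- character()
  if (length(object@sizes) != length(object@counts))
    msg <- c(msg, "sizes and counts must have equal length")
  if (is.unsorted(object@sizes, strictly = TRUE) && length(object@sizes) > 1L)
    msg <- c(msg, "sizes must be strictly ascending")
  if (sum(object@counts) != object@n_clones)
    msg <- c(msg, "counts must sum to n_clones")
  if (length(object@sizes) && any(object@sizes < object@truncation_threshold))
    msg <- c(msg, "all sizes must be >= truncation_threshold")
  if (length(msg)) msg else TRUE
})

#' Build a SizeDistribution from raw clone sizes
#'
#' @param x integer vector of clone sizes.
#' @param truncation_threshold threshold already applied to \code{x}
#'   (bookkeeping only; use \code{\link{truncateDistribution}} to truncate).
#' @return A \linkS4class{SizeDistribution}.
#' @export
SizeDistribution <- function(x, truncation_threshold = 0) {
  tab <- table(x)
  new("SizeDistribution", sizes = as.integer(names(tab)),
      counts = as.integer(tab), n_clones = length(x),
      truncation_threshold = as.numeric(truncation_threshold))
}

#' @describeIn SizeDistribution-class raw sizes expanded back to one entry
#'   per clone.
#' @param object,x a \code{SizeDistribution}.
#' @export
setGeneric("cloneSizes", function(object) standardGeneric("cloneSizes"))

#' @rdname SizeDistribution-class
#' @export
setMethod("cloneSizes", "SizeDistribution", function(object)
  rep(object@sizes, object@counts))

#' @rdname SizeDistribution-class
#' @export
setMethod("length", "SizeDistribution", function(x) x@n_clones)

setMethod("show", "StageModelParams", function(object) {
  cat("StageModelParams:", object@variant,
      sprintf("| s = %g, stages = %d, horizon = %d cycles\n",
              object@s, object@stages, object@horizon))
})

setMethod("show", "FeedbackParams", function(object) {
  cat(sprintf(
    "FeedbackParams: p(A) = %g * %g^%g / (%g^%g + A^%g); start %d dividing\n",
    object@p_max, object@half_max, object@hill_coeff, object@half_max,
    object@hill_coeff, object@hill_coeff, object@initial_dividing))
})

setMethod("show", "SizeDistribution", function(object) {
  cat(sprintf("SizeDistribution: %d clones, %d distinct sizes",
              object@n_clones, length(object@sizes)))
  if (object@truncation_threshold > 0)
    cat(sprintf(" (truncated at %g)", object@truncation_threshold))
  cat("\n")
  if (length(object@sizes))
    cat(sprintf("  size range [%d, %d], median %g\n", min(object@sizes),
                max(object@sizes), stats::median(cloneSizes(object))))
})
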