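#' Colonization scenario
#'
#' Parameters of one generative model of aquifer assembly.
#'
#' Under the *repeated* model an aquifer is colonized in 2 or 3 distinct
#' events: at event j every still-empty niche is filled with probability
#' `event_probs[j]` by a species drawn uniformly, without replacement within
#' the event, from a pool of `pool_size` ancestral surface species. Sympatric
#' sister species arise when the same ancestral species colonizes the aquifer
#' in different events. Under the *single* model there is one colonization
#' event with per-niche probability `event_probs[1]`; each niche left empty is
#' then filled with probability `diversification_prob` by in-situ speciation
#' of a resident, so sisters arise within the aquifer.
#'
#' By convention the last event probability is 1 (all niches present today are
#' filled in the final event); pass a different value to explore departures.
#'
#' @param model `"repeated"` or `"single"`.
#' @param event_probs Numeric vector of per-niche colonization probabilities,
#'   one per event: length 2 or 3 for the repeated model, length 1 for the
#'   single model.
#' @param diversification_prob Probability q that an empty niche is filled by
#'   within-aquifer speciation (single model only).
#' @param pool_size Number n of ancestral surface species (repeated model
#'   only); must be at least the largest niche count simulated.
#' @return An object of class `colonization_scenario`.
#' @examples
#' colonization_scenario("repeated", c(0.5, 1), pool_size = 10)
#' colonization_scenario("single", 0.78, diversification_prob = 1)
#' @export
colonization_scenario <- function(model = c("repeated", "single"),
                                  event_probs,
                                  diversification_prob = NULL,
                                  pool_size = NULL) {
  model <- match.arg(model)
  check_prob(event_probs, "event_probs")
  if (model == "repeated") {
    if (!length(event_probs) %in% 2:3)
      stop("repeated model takes 2 or 3 colonization events", call. = FALSE)
    if (is.null(pool_size) || length(pool_size) != 1L || pool_size < 1 ||
        pool_size != round(pool_size))
      stop("repeated model needs an integer pool_size >= 1", call. = FALSE)
    pool_size <- as.integer(pool_size)
    diversification_prob <- NULL
  } else {
    if (length(event_probs) != 1L)
      stop("single model has exactly one colonization event", call. = FALSE)
    if (is.null(diversification_prob))
      stop("single model needs diversification_prob (q)", call. = FALSE)
    check_prob(diversification_prob, "diversification_prob")
    pool_size <- NULL
  }
  structure(
    list(model = model, event_probs = as.numeric(event_probs),
         diversification_prob = diversification_prob, pool_size = pool_size),
    class = "colonization_scenario"
  )
}

#' @export
print.colonization_scenario <- function(x, ...) {
  cat("Colonization scenario:", x$model, "model\n")
  cat("  event probabilities:", paste(signif(x$event_probs, 4), collapse = ", "), "\n")
  if (!is.null(x$pool_size)) cat("  ancestral pool size n:", x$pool_size, "\n")
  if (!is.null(x$diversification_prob))
    cat("  diversification probability q:", x$diversification_prob, "\n")
  invisible(x)
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop(sprintf("%s must be probabilities in [0, 1]", what), call. = FALSE)
  invisible(p)
}

as_scenario <- function(x) {
  if (inherits(x, "colonization_scenario")) return(x)
  stop("expected a 'colonization_scenario' object", call. = FALSE)
}
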