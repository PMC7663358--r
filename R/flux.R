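# Metabolic flux analysis (MFA) integration: convert fluxes reported relative
# to a reference reaction (citrate synthase fixed at 100 is the field
# convention) into absolute units, and impose them, together with literature
# exchange rates, as LP bounds on the network.

#' Convert relative flux estimates to absolute values
#'
#' Fluxes estimated relative to a reference (anchor) reaction are rescaled so
#' the anchor takes a known absolute value, e.g. one derived from a tracer
#' infusion rate and body weight. Standard deviations scale identically.
#'
#' @param estimates data.frame with columns \code{reaction},
#'   \code{relative_value}, \code{sd_relative} (>= 0).
#' @param anchor_reaction id of the anchor reaction within \code{estimates}.
#' @param anchor_absolute its known absolute flux (> 0), in the target units
#'   (conventionally umol/kg/min).
#' @return the input with added columns \code{absolute_value},
#'   \code{sd_absolute}; attribute \code{scale} records the factor.
#' @export
relative_to_absolute <- function(estimates, anchor_reaction, anchor_absolute) {
  stopifnot(is.data.frame(estimates),
            all(c("reaction", "relative_value", "sd_relative") %in%
                  names(estimates)))
  if (any(estimates$sd_relative < 0)) stop("sd_relative must be >= 0")
  i <- match(anchor_reaction, estimates$reaction)
  if (is.na(i)) stop("anchor reaction '", anchor_reaction, "' not found")
  if (estimates$relative_value[i] == 0)
    stop("anchor reaction has zero relative flux")
  if (anchor_absolute <= 0) stop("anchor_absolute must be > 0")
  scale <- anchor_absolute / estimates$relative_value[i]
  out <- estimates
  out$absolute_value <- out$relative_value * scale
  out$sd_absolute <- out$sd_relative * scale
  attr(out, "scale") <- scale
  out
}

#' Build LP bounds from converted MFA estimates
#'
#' Each estimate becomes the interval (v - k sd, v + k sd), clipped to the
#' reaction's structural range (so the lower bound of an irreversible
#' reaction stays at 0 and a constraint can only restrict, never widen, the
#' network). A lower bound above the structural upper bound is an error, as
#' the measurement then contradicts the network.
#'
#' @param estimates data.frame from [relative_to_absolute()]; an optional
#'   \code{model_reaction_id} column maps estimate ids onto network reaction
#'   ids (defaults to \code{reaction}).
#' @param network the target \code{metabolic_network}.
#' @param k half-width of the bound interval in standard deviations.
#' @return data.frame of class \code{constraint_set} with columns
#'   \code{reaction}, \code{lower}, \code{upper}.
#' @export
constraints_from_mfa <- function(estimates, network, k = 2) {
  if (!"absolute_value" %in% names(estimates))
    stop("estimates must be converted first; see relative_to_absolute()")
  ids <- if ("model_reaction_id" %in% names(estimates))
    estimates$model_reaction_id else estimates$reaction
  unmapped <- setdiff(ids, network$reactions$id)
  if (length(unmapped))
    stop("flux estimates reference unmapped reaction id(s): ",
         paste(unmapped, collapse = ", "))
  ri <- match(ids, network$reactions$id)
  lower <- estimates$absolute_value - k * estimates$sd_absolute
  upper <- estimates$absolute_value + k * estimates$sd_absolute
  lower <- pmax(lower, network$reactions$lower_bound[ri])
  too_high <- lower > network$reactions$upper_bound[ri]
  upper <- pmin(upper, network$reactions$upper_bound[ri])
  if (any(too_high))
    stop("MFA lower bound exceeds structural upper bound for: ",
         paste(ids[too_high], collapse = ", "))
  structure(data.frame(reaction = ids, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("constraint_set", "data.frame"))
}

#' Bounds from literature uptake/secretion rates
#'
#' Uses the standard constraint-based sign convention for exchange reactions:
#' uptake is negative exchange flux, so a measured uptake rate r gives bounds
#' (-r, 0); a secretion rate r gives (0, r).
#'
#' @param exchanges data.frame with columns \code{reaction},
#'   \code{direction} ("uptake" or "secretion"), \code{rate} (>= 0).
#' @return a \code{constraint_set}.
#' @export
constraints_from_exchanges <- function(exchanges) {
  stopifnot(all(c("reaction", "direction", "rate") %in% names(exchanges)))
  if (any(exchanges$rate < 0)) stop("exchange rates must be >= 0")
  if (!all(exchanges$direction %in% c("uptake", "secretion")))
    stop("direction must be 'uptake' or 'secretion'")
  up <- exchanges$direction == "uptake"
  structure(data.frame(reaction = exchanges$reaction,
                       lower = ifelse(up, -exchanges$rate, 0),
                       upper = ifelse(up, 0, exchanges$rate),
                       stringsAsFactors = FALSE),
            class = c("constraint_set", "data.frame"))
}

#' Apply a constraint set to a network
#'
#' Returns a copy of the network with the listed reaction bounds replaced.
#' The original bounds are kept in the attribute \code{replaced_bounds} so
#' [remove_constraints()] can restore them exactly.
#'
#' @param network a \code{metabolic_network}.
#' @param constraints a \code{constraint_set}.
#' @return the constrained network copy.
#' @export
apply_constraints <- function(network, constraints) {
  if (any(constraints$lower > constraints$upper))
    stop("constraint with lower > upper for: ",
         paste(constraints$reaction[constraints$lower > constraints$upper],
               collapse = ", "))
  ri <- match(constraints$reaction, network$reactions$id)
  if (anyNA(ri))
    stop("constraint references unknown reaction id(s): ",
         paste(constraints$reaction[is.na(ri)], collapse = ", "))
  out <- network
  saved <- data.frame(reaction = constraints$reaction,
                      lower = network$reactions$lower_bound[ri],
                      upper = network$reactions$upper_bound[ri],
                      stringsAsFactors = FALSE)
  out$reactions$lower_bound[ri] <- constraints$lower
  out$reactions$upper_bound[ri] <- constraints$upper
  validate_network(out)
  attr(out, "replaced_bounds") <- saved
  out
}

#' Restore bounds replaced by [apply_constraints()]
#'
#' @param network a network previously returned by [apply_constraints()].
#' @return the network with its original bounds.
#' @export
remove_constraints <- function(network) {
  saved <- attr(network, "replaced_bounds")
  if (is.null(saved)) stop("network carries no replaced bounds to restore")
  ri <- match(saved$reaction, network$reactions$id)
  out <- network
  out$reactions$lower_bound[ri] <- saved$lower
  out$reactions$upper_bound[ri] <- saved$upper
  attr(out, "replaced_bounds") <- NULL
  out
}

#' Read MFA flux estimates from TSV
#'
#' Expected columns: \code{reaction}, \code{relative_value},
#' \code{sd_relative}, optionally \code{model_reaction_id}.
#'
#' @param path TSV file path.
#' @return data.frame of flux estimates.
#' @export
read_flux_estimates <- function(path) {
  if (!file.exists(path)) stop("flux file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction", "relative_value", "sd_relative")
  if (!all(need %in% names(d)))
    stop("flux TSV must have columns: ", paste(need, collapse = ", "))
  d
}
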