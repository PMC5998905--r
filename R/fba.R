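#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its flux subject to steady
#' state (`S v = 0`) and the flux bounds — two linear programs per reaction.
#' No objective-optimality constraint is imposed: variability is purely
#' feasibility-based, matching a workflow in which model extraction needs no
#' predefined biomass objective. The ranges normalize the flux-change ratio
#' of [flux_change()], so by default they are computed on the shared
#' (generic) network rather than per-tissue models.
#'
#' @param network a [metabolic_network].
#' @param reactions reaction ids to analyze (default all).
#' @param fixed_constraints optional named list `reaction_id -> c(lb, ub)`
#'   overriding bounds (e.g. to pin an uptake or fix a context).
#' @return data frame of class `fva_range`: `reaction_id`, `minflux`,
#'   `maxflux`.
#' @export
fva <- function(network, reactions = NULL, fixed_constraints = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  ids <- reaction_ids(network)
  reactions <- reactions %||% ids
  if (!all(reactions %in% ids)) {
    stop("unknown reaction id(s): ",
         paste(setdiff(reactions, ids), collapse = ", "), call. = FALSE)
  }
  b <- apply_bound_overrides(network, fixed_constraints)
  S <- network$S
  zero <- rep(0, nrow(S))
  if (!lp_feasible(S, zero, b$lb, b$ub)) {
    stop("network has no steady-state solution under these constraints",
         call. = FALSE)
  }
  n <- ncol(S)
  minf <- maxf <- numeric(length(reactions))
  for (i in seq_along(reactions)) {
    j <- match(reactions[i], ids)
    obj <- numeric(n)
    obj[j] <- 1
    lo <- lp_solve(obj, S, zero, b$lb, b$ub, maximize = FALSE)
    hi <- lp_solve(obj, S, zero, b$lb, b$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA failed for reaction ", reactions[i], " (status ",
           lo$status, "/", hi$status, ")", call. = FALSE)
    }
    minf[i] <- lo$objective
    maxf[i] <- hi$objective
  }
  structure(data.frame(reaction_id = reactions, minflux = minf,
                       maxflux = maxf, stringsAsFactors = FALSE),
            class = c("fva_range", "data.frame"))
}

apply_bound_overrides <- function(network, fixed_constraints) {
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  if (!is.null(fixed_constraints)) {
    ids <- reaction_ids(network)
    for (nm in names(fixed_constraints)) {
      j <- match(nm, ids)
      if (is.na(j)) stop("unknown reaction id in constraints: ", nm,
                         call. = FALSE)
      lb[j] <- fixed_constraints[[nm]][1L]
      ub[j] <- fixed_constraints[[nm]][2L]
    }
  }
  list(lb = lb, ub = ub)
}

#' Rate-limiting reactions of a tissue model
#'
#' A reaction is rate-limiting when its simulated flux attains its upper
#' bound (within `tol`). With `reverse = TRUE`, reversible reactions
#' saturating their lower bound are also reported.
#'
#' @param model a [tissue model][extract_tissue_model] or a named flux
#'   vector.
#' @param network the [metabolic_network] supplying the bounds.
#' @param tol saturation tolerance (flux units).
#' @param reverse also detect reverse-direction saturation.
#' @return sorted character vector of reaction ids.
#' @export
rate_limiting <- function(model, network, tol = 1e-6, reverse = FALSE) {
  v <- if (inherits(model, "tissue_model")) model$fluxes else model
  ids <- reaction_ids(network)
  v <- v[ids]
  v[is.na(v)] <- 0
  ub <- network$reactions$upper_bound
  lb <- network$reactions$lower_bound
  hit <- v >= ub - tol
  if (reverse) hit <- hit | (lb < 0 & v <= lb + tol)
  sort(ids[hit])
}
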