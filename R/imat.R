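#' Map gene expression states onto reactions through GPR rules
#'
#' Evaluates every reaction's gene-protein-reaction rule over a sample's
#' trilean gene states: `and` takes the minimum (a complex is only as
#' available as its scarcest subunit), `or` the maximum (any isozyme
#' suffices). Reactions with an empty rule — exchange reactions in
#' particular — are moderate (0), i.e. unconstrained in the model
#' extraction.
#'
#' @param network a [metabolic_network].
#' @param gene_states an [expression_states][discretize] object, a gene x
#'   sample integer matrix, or a named vector of states for one sample.
#' @param sample sample id (required when `gene_states` has several).
#' @return named integer vector over all reactions with values in
#'   `{-1, 0, 1}`: the reaction state map (+1 = expected active, R_H;
#'   -1 = expected inactive, R_L).
#' @export
reaction_states <- function(network, gene_states, sample = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  if (inherits(gene_states, "expression_states")) {
    gene_states <- gene_states$states
  }
  if (is.matrix(gene_states)) {
    if (is.null(sample)) {
      if (ncol(gene_states) != 1L) {
        stop("several samples present; supply `sample`", call. = FALSE)
      }
      sample <- colnames(gene_states)[1L]
    }
    if (!sample %in% colnames(gene_states)) {
      stop("sample '", sample, "' not found in gene states", call. = FALSE)
    }
    gene_states <- gene_states[, sample]
  }
  out <- vapply(network$gpr_trees, evaluate_gpr, 0L,
                gene_states = gene_states)
  stats::setNames(as.integer(out), reaction_ids(network))
}

# Assemble the MILP: continuous fluxes v, binaries y, one slack per
# implication row. Rows are equalities; inequalities are closed with
# non-negative slacks. Linearization:
#   r in R_H (forward):  v_r - (eps - lb_r) y+ >= lb_r
#   r in R_H reversible: v_r + (ub_r + eps) y- <= ub_r,  y+ + y- <= 1
#   r in R_L:            v_r + ub_r y <= ub_r,  v_r + lb_r y >= lb_r
build_imat_milp <- function(network, states, epsilon) {
  ids <- reaction_ids(network)
  n <- length(ids)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  rh <- names(states)[states == 1L]
  rl <- names(states)[states == -1L]
  y_info <- data.frame(reaction = character(), kind = character(),
                       stringsAsFactors = FALSE)
  for (r in rh) {
    y_info <- rbind(y_info, data.frame(reaction = r, kind = "plus"))
    if (lb[match(r, ids)] < 0) {
      y_info <- rbind(y_info, data.frame(reaction = r, kind = "minus"))
    }
  }
  for (r in rl) {
    y_info <- rbind(y_info, data.frame(reaction = r, kind = "low"))
  }
  p <- nrow(y_info)
  yi <- function(r, kind) {
    n + which(y_info$reaction == r & y_info$kind == kind)
  }

  rows <- list()
  rhs <- numeric(0)
  slack_sign <- numeric(0)
  add_row <- function(cols, vals, b, sgn) {
    a <- numeric(n + p)
    a[cols] <- vals
    rows[[length(rows) + 1L]] <<- a
    rhs <<- c(rhs, b)
    slack_sign <<- c(slack_sign, sgn)
  }
  for (r in rh) {
    j <- match(r, ids)
    add_row(c(j, yi(r, "plus")), c(1, -(epsilon - lb[j])), lb[j], -1)
    if (lb[j] < 0) {
      add_row(c(j, yi(r, "minus")), c(1, ub[j] + epsilon), ub[j], +1)
      add_row(c(yi(r, "plus"), yi(r, "minus")), c(1, 1), 1, +1)
    }
  }
  for (r in rl) {
    j <- match(r, ids)
    add_row(c(j, yi(r, "low")), c(1, ub[j]), ub[j], +1)
    add_row(c(j, yi(r, "low")), c(1, lb[j]), lb[j], -1)
  }
  q <- length(rows)
  m <- nrow(network$S)
  A <- matrix(0, m + q, n + p + q)
  A[seq_len(m), seq_len(n)] <- network$S
  for (i in seq_len(q)) {
    A[m + i, seq_len(n + p)] <- rows[[i]]
    A[m + i, n + p + i] <- slack_sign[i]
  }
  obj <- c(numeric(n), rep(1, p), numeric(q))
  lbx <- c(lb, rep(0, p), rep(0, q))
  ubx <- c(ub, rep(1, p), rep(Inf, q))
  list(A = A, rhs = c(rep(0, m), rhs), lb = lbx, ub = ubx, obj = obj,
       n = n, y_cols = if (p) n + seq_len(p) else integer(0),
       y_info = y_info)
}

# Depth-first branch and bound over the binaries. The LP relaxation gives
# the bound; the objective is integral so a node is pruned when
# floor(bound) cannot beat the incumbent. Branching: most fractional
# binary, ties to the lowest index, one-branch first — fully deterministic.
solve_imat_milp <- function(P, time_limit = 60) {
  p <- length(P$y_cols)
  best <- list(obj = -1L, y = numeric(0), x = NULL)
  timed_out <- FALSE
  t0 <- proc.time()[[3L]]
  recurse <- function(ylb, yub) {
    if (timed_out) return(invisible())
    if (proc.time()[[3L]] - t0 > time_limit) {
      timed_out <<- TRUE
      return(invisible())
    }
    lb2 <- P$lb
    ub2 <- P$ub
    lb2[P$y_cols] <- ylb
    ub2[P$y_cols] <- yub
    r <- lp_solve(P$obj, P$A, P$rhs, lb2, ub2, maximize = TRUE)
    if (r$status != "optimal") return(invisible())
    if (floor(r$objective + 1e-6) <= best$obj) return(invisible())
    yv <- r$x[P$y_cols]
    frac <- abs(yv - round(yv))
    if (all(frac < 1e-6)) {
      obj <- as.integer(round(r$objective))
      if (obj > best$obj) best <<- list(obj = obj, y = round(yv), x = r$x)
      return(invisible())
    }
    jb <- which.max(pmin(yv, 1 - yv))
    ylb1 <- ylb
    ylb1[jb] <- 1
    recurse(ylb1, yub)
    yub0 <- yub
    yub0[jb] <- 0
    recurse(ylb, yub0)
  }
  if (p == 0L) {
    feas <- lp_solve(P$obj, P$A, P$rhs, P$lb, P$ub, maximize = TRUE)
    if (feas$status == "optimal") best <- list(obj = 0L, y = numeric(0),
                                               x = feas$x)
  } else {
    recurse(rep(0, p), rep(1, p))
  }
  list(best = best, timed_out = timed_out)
}

#' Fit a context-specific flux distribution (iMAT)
#'
#' Solves the iMAT mixed-integer linear program: over steady-state flux
#' vectors (`S v = 0`, bounds respected), maximize the number of reactions
#' whose flux activity agrees with their expression-derived state. A
#' reaction expected active (state +1, set R_H) is satisfied when it
#' carries `|v| >= epsilon` (either direction if reversible); a reaction
#' expected inactive (state -1, set R_L) is satisfied when `v = 0`. The
#' integer objective is the number of satisfied reactions.
#'
#' MILP solvers can return different flux vectors of equal objective; for
#' reproducible downstream statistics the returned vector is canonicalized
#' by a secondary linear program that, with the binary assignment fixed,
#' minimizes total absolute flux. The whole solve is deterministic.
#'
#' @param network a [metabolic_network].
#' @param states reaction state map from [reaction_states()] (named vector
#'   in `{-1, 0, 1}`; omitted reactions count as 0).
#' @param epsilon activation threshold in flux units (default 1; the flux
#'   scale is the conventional `[-1000, 1000]`).
#' @param time_limit branch-and-bound wall-clock limit in seconds; on
#'   timeout the best feasible solution found is returned with status
#'   `"time-limit"`.
#' @param canonicalize run the secondary minimum-`sum(|v|)` program.
#' @param activity_tol numeric zero threshold separating round-off from
#'   genuine flux (distinct from `epsilon` by design).
#' @return an object of class `imat_fit` with components `fluxes` (named
#'   vector), `objective`, `satisfied_high`, `satisfied_low`, `status`,
#'   `binaries`, plus the inputs. Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals` (0/1 per flagged reaction, 1 = unsatisfied),
#'   `plot`.
#' @seealso [extract_tissue_model()], [reaction_states()]
#' @export
imat <- function(network, states, epsilon = 1, time_limit = 60,
                 canonicalize = TRUE, activity_tol = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  ids <- reaction_ids(network)
  if (is.null(names(states))) {
    stop("states must be a named vector of reaction states", call. = FALSE)
  }
  if (!all(names(states) %in% ids)) {
    stop("unknown reaction id(s) in states: ",
         paste(setdiff(names(states), ids), collapse = ", "), call. = FALSE)
  }
  if (!all(states %in% c(-1L, 0L, 1L))) {
    stop("reaction states must be in {-1, 0, 1}", call. = FALSE)
  }
  full_states <- stats::setNames(integer(length(ids)), ids)
  full_states[names(states)] <- as.integer(states)

  rh <- ids[full_states == 1L]
  if (length(rh)) {
    lbv <- network$reactions$lower_bound[match(rh, ids)]
    ubv <- network$reactions$upper_bound[match(rh, ids)]
    dead <- ubv < epsilon & lbv > -epsilon
    if (any(dead)) {
      warning("epsilon = ", epsilon, " exceeds the attainable flux ",
              "magnitude of highly-expressed reaction(s): ",
              paste(rh[dead], collapse = ", "))
    }
  }

  P <- build_imat_milp(network, full_states, epsilon)
  sol <- solve_imat_milp(P, time_limit = time_limit)
  if (sol$best$obj < 0L) {
    return(structure(list(fluxes = NULL, objective = NA_integer_,
                          satisfied_high = character(),
                          satisfied_low = character(),
                          status = if (sol$timed_out) "time-limit"
                                   else "infeasible",
                          epsilon = epsilon, activity_tol = activity_tol,
                          states = full_states, binaries = NULL,
                          network = network, call = match.call()),
                     class = "imat_fit"))
  }
  yv <- sol$best$y
  binaries <- P$y_info
  binaries$value <- if (nrow(binaries)) as.integer(yv) else integer(0)
  v <- sol$best$x[seq_along(ids)]
  if (canonicalize) {
    v <- canonical_flux(network, binaries, epsilon)
  }
  v <- stats::setNames(v, ids)
  v[abs(v) < activity_tol] <- 0

  sat_by <- function(kind) {
    unique(binaries$reaction[binaries$kind %in% kind & binaries$value == 1L])
  }
  satisfied_high <- sort(sat_by(c("plus", "minus")))
  satisfied_low <- sort(sat_by("low"))
  structure(list(fluxes = v, objective = sol$best$obj,
                 satisfied_high = satisfied_high,
                 satisfied_low = satisfied_low,
                 status = if (sol$timed_out) "time-limit" else "optimal",
                 epsilon = epsilon, activity_tol = activity_tol,
                 states = full_states, binaries = binaries,
                 network = network, call = match.call()),
            class = "imat_fit")
}

# Secondary LP: binaries fixed, minimize sum |v|. Satisfied implications
# become bound overrides; |v| is linearized with one t >= |v_j| per
# reaction.
canonical_flux <- function(network, binaries, epsilon) {
  ids <- reaction_ids(network)
  n <- length(ids)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  if (nrow(binaries)) {
    for (i in seq_len(nrow(binaries))) {
      if (binaries$value[i] != 1L) next
      j <- match(binaries$reaction[i], ids)
      switch(binaries$kind[i],
        plus = lb[j] <- max(lb[j], epsilon),
        minus = ub[j] <- min(ub[j], -epsilon),
        low = { lb[j] <- max(lb[j], 0); ub[j] <- min(ub[j], 0) })
    }
  }
  S <- network$S
  m <- nrow(S)
  tmax <- pmax(abs(lb), abs(ub))
  # columns: v (n), t (n), slacks (2n)
  A <- matrix(0, m + 2L * n, 4L * n)
  A[seq_len(m), seq_len(n)] <- S
  for (j in seq_len(n)) {
    A[m + j, j] <- -1            #  t_j - v_j - s  = 0
    A[m + j, n + j] <- 1
    A[m + j, 2L * n + j] <- -1
    A[m + n + j, j] <- 1         #  t_j + v_j - s' = 0
    A[m + n + j, n + j] <- 1
    A[m + n + j, 3L * n + j] <- -1
  }
  obj <- c(numeric(n), rep(1, n), numeric(2L * n))
  lbx <- c(lb, numeric(n), numeric(2L * n))
  ubx <- c(ub, tmax, rep(Inf, 2L * n))
  r <- lp_solve(obj, A, rep(0, m + 2L * n), lbx, ubx)
  if (r$status != "optimal") {
    stop("canonicalization LP failed (status ", r$status, ")",
         call. = FALSE)
  }
  r$x[seq_len(n)]
}

#' @export
print.imat_fit <- function(x, ...) {
  st <- x$states
  cat("iMAT fit (", x$status, ")\n", sep = "")
  cat("  reactions: ", length(st), "  R_H: ", sum(st == 1L),
      "  R_L: ", sum(st == -1L), "  epsilon: ", x$epsilon, "\n", sep = "")
  if (!is.null(x$fluxes)) {
    cat("  objective (satisfied reactions): ", x$objective, " = ",
        length(x$satisfied_high), " high + ", length(x$satisfied_low),
        " low\n", sep = "")
    cat("  active reactions (|v| > ", x$activity_tol, "): ",
        sum(abs(x$fluxes) > x$activity_tol), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.imat_fit <- function(object, ...) {
  st <- object$states
  flagged <- names(st)[st != 0L]
  sat <- c(object$satisfied_high, object$satisfied_low)
  subsys <- object$network$reactions$subsystem
  active <- if (is.null(object$fluxes)) character() else
    names(object$fluxes)[abs(object$fluxes) > object$activity_tol]
  per_sub <- table(subsys[match(active, reaction_ids(object$network))])
  out <- list(status = object$status, objective = object$objective,
              n_high = sum(st == 1L), n_low = sum(st == -1L),
              n_satisfied = length(sat),
              unsatisfied = sort(setdiff(flagged, sat)),
              n_active = length(active),
              active_by_subsystem = per_sub,
              epsilon = object$epsilon)
  class(out) <- "summary.imat_fit"
  out
}

#' @export
print.summary.imat_fit <- function(x, ...) {
  cat("iMAT fit summary (", x$status, ")\n", sep = "")
  cat("  flagged: ", x$n_high, " high, ", x$n_low, " low; satisfied: ",
      x$n_satisfied, "\n", sep = "")
  if (length(x$unsatisfied)) {
    cat("  unsatisfied: ", paste(x$unsatisfied, collapse = ", "), "\n",
        sep = "")
  }
  cat("  active reactions: ", x$n_active, "\n", sep = "")
  if (length(x$active_by_subsystem)) {
    cat("  active by subsystem:\n")
    print(x$active_by_subsystem)
  }
  invisible(x)
}

#' @export
coef.imat_fit <- function(object, ...) object$fluxes

#' @export
fitted.imat_fit <- function(object, ...) object$fluxes

#' @export
residuals.imat_fit <- function(object, ...) {
  st <- object$states
  flagged <- names(st)[st != 0L]
  sat <- c(object$satisfied_high, object$satisfied_low)
  stats::setNames(as.integer(!flagged %in% sat), flagged)
}

#' @export
plot.imat_fit <- function(x, ...) {
  if (is.null(x$fluxes)) {
    stop("no flux distribution to plot (status ", x$status, ")",
         call. = FALSE)
  }
  st <- x$states[names(x$fluxes)]
  cols <- c("steelblue", "grey70", "indianred")[st + 2L]
  graphics::barplot(x$fluxes, col = cols, border = NA, las = 2L,
                    cex.names = 0.6, ylab = "flux",
                    main = "iMAT flux distribution", ...)
  graphics::legend("topright", fill = c("indianred", "grey70", "steelblue"),
                   legend = c("R_H", "moderate", "R_L"), bty = "n")
  invisible(x)
}

#' Extract the tissue-specific model from an iMAT fit
#'
#' The tissue model keeps only the active reactions: those carrying flux
#' above the numerical activity tolerance in the (canonicalized) optimum.
#'
#' @param network the [metabolic_network] the fit was made on.
#' @param solution an [imat_fit][imat] with status `"optimal"`.
#' @param tissue sample/tissue label.
#' @param activity_tol zero threshold on `|v|`.
#' @return object of class `tissue_model`: `tissue`, `active_reactions`,
#'   `fluxes`, `epsilon`, `source_states`.
#' @export
extract_tissue_model <- function(network, solution, tissue,
                                 activity_tol = 1e-6) {
  stopifnot(inherits(solution, "imat_fit"))
  if (!identical(solution$status, "optimal")) {
    stop("cannot extract a tissue model from a non-optimal solution ",
         "(status ", solution$status, ")", call. = FALSE)
  }
  v <- solution$fluxes
  active <- names(v)[abs(v) > activity_tol]
  if (!length(active)) {
    warning("tissue model '", tissue, "' has no active reactions")
  }
  structure(list(tissue = tissue, active_reactions = active, fluxes = v,
                 epsilon = solution$epsilon,
                 source_states = solution$states,
                 network_fingerprint = network_fingerprint(network)),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("Tissue model '", x$tissue, "': ", length(x$active_reactions),
      " active of ", length(x$fluxes), " reactions (epsilon ", x$epsilon,
      ")\n", sep = "")
  invisible(x)
}

#' Intersection-region counts of active-reaction sets
#'
#' Counts every region of the Venn diagram of the models'
#' active-reaction sets (all `2^k - 1` non-empty membership patterns,
#' exclusive counts), plus the full intersection under the label
#' `"shared"`.
#'
#' @param models list of [tissue models][extract_tissue_model] over the
#'   same network (at least two).
#' @return named integer vector; names are `&`-joined tissue labels for the
#'   exclusive regions, plus `"shared"`.
#' @export
active_set_overlap <- function(models) {
  if (length(models) < 2L) stop("need at least two models", call. = FALSE)
  stopifnot(all(vapply(models, inherits, TRUE, "tissue_model")))
  fps <- vapply(models, `[[`, "", "network_fingerprint")
  if (length(unique(fps)) != 1L) {
    stop("models come from different networks", call. = FALSE)
  }
  labels <- vapply(models, `[[`, "", "tissue")
  if (anyDuplicated(labels)) stop("duplicate tissue labels", call. = FALSE)
  sets <- lapply(models, `[[`, "active_reactions")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L) {
    member <- matrix(FALSE, 0L, length(models))
  }
  k <- length(models)
  out <- integer(0)
  for (code in seq_len(2L^k - 1L)) {
    pattern <- as.logical(bitwAnd(code, 2L^(seq_len(k) - 1L)))
    cnt <- if (length(universe)) {
      sum(apply(member, 1L, function(row) all(row == pattern)))
    } else {
      0L
    }
    out[paste(labels[pattern], collapse = "&")] <- cnt
  }
  out["shared"] <- if (length(universe)) {
    sum(apply(member, 1L, all))
  } else {
    0L
  }
  out
}
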