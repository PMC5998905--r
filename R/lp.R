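#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to equality constraints
#' `A %*% x == rhs` and box bounds `lb <= x <= ub`, using a dense
#' bounded-variable two-phase simplex with Bland's rule. The method is
#' deterministic: identical inputs always return the identical vertex.
#'
#' All linear and mixed-integer programs in the package (flux feasibility,
#' flux variability analysis, the iMAT relaxations) are solved through this
#' routine. Lower bounds must be finite; upper bounds may be `Inf`.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A numeric constraint matrix, `m x n` (a single constraint may be
#'   given as a vector).
#' @param rhs numeric right-hand side, length `m`.
#' @param lb,ub numeric bounds, length `n` (scalars are recycled).
#' @param maximize logical; maximize instead of minimize.
#' @param max_iter simplex iteration cap; `0` selects a size-based default.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"iteration_limit"`), and for optimal solutions `x` and
#'   `objective` (on the original, non-negated scale).
#' @examples
#' # max x1 + x2 s.t. x1 + x2 <= 1 written with a slack variable
#' lp_solve(c(1, 1, 0), matrix(c(1, 1, 1), 1), 1,
#'          lb = c(0, 0, 0), ub = c(Inf, Inf, Inf), maximize = TRUE)
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, maximize = FALSE, max_iter = 0L) {
  if (is.vector(A)) A <- matrix(A, nrow = 1L)
  A <- as.matrix(A)
  n <- ncol(A)
  obj <- rep_len(as.numeric(obj), n)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  rhs <- as.numeric(rhs)
  stopifnot(length(rhs) == nrow(A), all(is.finite(lb)), all(ub >= lb - 1e-12))
  cc <- if (maximize) -obj else obj
  res <- .simplex_cpp(A, rhs, cc, lb, ub, as.integer(max_iter))
  status <- c("optimal", "infeasible", "unbounded",
              "iteration_limit")[res$status + 1L]
  out <- list(status = status)
  if (status == "optimal") {
    out$x <- as.numeric(res$x)
    out$objective <- if (maximize) -res$objective else res$objective
  }
  out
}

# Feasibility of A x = rhs, lb <= x <= ub (phase 1 only in effect).
lp_feasible <- function(A, rhs, lb, ub) {
  res <- lp_solve(numeric(ncol(as.matrix(A))), A, rhs, lb, ub)
  identical(res$status, "optimal")
}
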