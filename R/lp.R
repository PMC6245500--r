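#' Solve a bounded linear program
#'
#' Dense bounded-variable two-phase primal simplex (compiled). Solves
#' \code{max c'x} subject to \code{A x = b} and \code{lb <= x <= ub}; bounds
#' may be infinite. This is the workhorse behind \code{\link{bilevelFBA}};
#' it is exported so that solver behaviour can be inspected directly.
#'
#' @param objective numeric coefficient vector c.
#' @param constMat constraint matrix A (rows are equality constraints).
#' @param rhs right-hand side b.
#' @param lower,upper variable bounds.
#' @param maximize if \code{FALSE}, minimise instead.
#' @param tol pivot/feasibility tolerance.
#' @param maxit iteration cap (0 = automatic).
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"maxit"}), \code{solution}, \code{objective}
#'   and \code{residual} (max abs equality violation).
#' @examples
#' # max x1 + x2 s.t. x1 - x2 = 0, 0 <= x <= 2  ->  x = (2, 2)
#' solveLinearProgram(c(1, 1), matrix(c(1, -1), 1), 0, c(0, 0), c(2, 2))
#' @export
solveLinearProgram <- function(objective, constMat, rhs, lower, upper,
                               maximize = TRUE, tol = 1e-9, maxit = 0L) {
  constMat <- as.matrix(constMat)
  storage.mode(constMat) <- "double"
  n <- ncol(constMat)
  stopifnot(length(objective) == n, length(lower) == n, length(upper) == n,
            length(rhs) == nrow(constMat))
  obj <- if (maximize) as.numeric(objective) else -as.numeric(objective)
  res <- .cpp_simplex(obj, constMat, as.numeric(rhs), as.numeric(lower),
                      as.numeric(upper), tol, as.integer(maxit))
  status <- c("optimal", "infeasible", "unbounded", "maxit")[res$status + 1L]
  if (status != "optimal")
    return(list(status = status, solution = NULL, objective = NA_real_,
                residual = NA_real_))
  list(status = status,
       solution = as.numeric(res$x),
       objective = if (maximize) res$objective else -res$objective,
       residual = res$residual)
}
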