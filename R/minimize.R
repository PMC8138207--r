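# Powell direction-set minimization over Cartesian coordinates. Derivative
# free: each cycle line-minimizes along a set of directions (initially the
# coordinate axes), then replaces the direction of largest single gain with
# the cycle's net displacement. The line search brackets the minimum by
# doubling an initial step and hands the bracket to stats::optimize.

line_minimize <- function(f, x, d, step = 0.25, max_expand = 12) {
  g <- function(t) f(x + t * d)
  lo <- -step; hi <- step
  f0 <- g(0)
  for (k in seq_len(max_expand)) {
    if (g(lo) > f0 || g(hi) > f0) break
    lo <- 2 * lo; hi <- 2 * hi
  }
  opt <- stats::optimize(g, lower = lo, upper = hi)
  if (opt$objective >= f0) list(t = 0, value = f0)
  else list(t = opt$minimum, value = opt$objective)
}

#' Minimize a structure with the Powell direction-set method
#'
#' Derivative-free energy minimization of all Cartesian coordinates under the
#' internal force field. The energy trace over accepted cycles is
#' non-increasing; iteration stops when a full cycle lowers the energy by less
#' than \code{tol} or after \code{max_iter} cycles.
#'
#' @param m a \code{qmol} with types and charges assigned.
#' @param tol convergence threshold on the per-cycle energy decrease
#'   (kcal/mol).
#' @param max_iter maximum number of Powell cycles.
#' @return list with \code{molecule} (minimized), \code{energy} (final
#'   [energy_report()]), \code{trace} (energy after each cycle, kcal/mol) and
#'   \code{converged}.
#' @examples
#' m <- make_fixture("methanol")
#' fit <- minimize_powell(m, tol = 1e-3, max_iter = 5)
#' fit$converged
#' @export
minimize_powell <- function(m, tol = 1e-4, max_iter = 200) {
  ctx <- ff_context(m)
  n3 <- 3 * n_atoms(m)
  f <- function(x) {
    e <- sum(eval_ff(ctx, matrix(x, ncol = 3)))
    if (!is.finite(e)) stop("energy evaluation failed during minimization")
    e
  }
  x <- as.vector(coords(m))
  dirs <- diag(n3)
  e <- f(x)
  trace <- e
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    e_start <- e
    x_start <- x
    biggest <- 0; ibig <- 1
    for (d in seq_len(n3)) {
      ls <- line_minimize(f, x, dirs[, d])
      gain <- e - ls$value
      if (gain > biggest) { biggest <- gain; ibig <- d }
      if (ls$t != 0) { x <- x + ls$t * dirs[, d]; e <- ls$value }
    }
    net <- x - x_start
    if (sqrt(sum(net^2)) > 1e-12) {
      dirs[, ibig] <- dirs[, n3]
      dirs[, n3] <- net / sqrt(sum(net^2))
      ls <- line_minimize(f, x, dirs[, n3])
      if (ls$t != 0) { x <- x + ls$t * dirs[, n3]; e <- ls$value }
    }
    trace <- c(trace, e)
    if (e_start - e < tol) { converged <- TRUE; break }
  }
  coords(m) <- matrix(x, ncol = 3)
  terms <- eval_ff(ctx, coords(m))
  list(molecule = m, energy = energy_report(sum(terms), terms = terms),
       trace = trace, converged = converged)
}
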