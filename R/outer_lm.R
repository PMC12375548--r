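#' Outer Levenberg-Marquardt loop for bi-level personalization
#'
#' Damped (trust-region-like) nonlinear least squares with forward-difference
#' Jacobians and box bounds, written for residual functions that carry
#' optimizer state: `fn(x, q_init)` must return `list(resid =, q =)` where
#' `q` is the per-frame inner-solution matrix used to warm-start subsequent
#' evaluations.  The warm-start basis is updated only when a step is
#' accepted, so every candidate within one iteration sees the same basis and
#' the objective is deterministic.  Acceptance is monotone: the cost never
#' increases.
#'
#' @param fn residual function `(x, q_init) -> list(resid, q)`.
#' @param x0 numeric start vector.
#' @param lower,upper box bounds (steps are clamped).
#' @param fd_step per-variable forward-difference steps.
#' @param maxiter iteration cap.
#' @param ftol relative cost-improvement stopping tolerance.
#' @param ptol relative step-size stopping tolerance.
#' @param q_seed optional warm-start basis for the first evaluation.
#' @return list with `par`, `cost`, `initial_cost`, `niter`,
#'   `cost_history`, and `q` (inner solutions at the final iterate).
#' @keywords internal
outer_lm <- function(fn, x0, lower, upper, fd_step, maxiter = 30,
                     ftol = 1e-10, ptol = 1e-10, q_seed = NULL) {
  clamp <- function(x) pmin(pmax(x, lower), upper)
  x <- clamp(x0)
  n <- length(x)
  base <- fn(x, q_seed)
  r <- base$resid
  q_base <- base$q
  cost <- sum(r^2)
  initial_cost <- cost
  hist <- cost
  lambda <- 1e-3
  iter <- 0L
  stall <- 0L
  while (iter < maxiter) {
    iter <- iter + 1L
    if (cost < 1e-20) break
    J <- vapply(seq_len(n), function(i) {
      xp <- x
      xp[i] <- xp[i] + fd_step[i]
      (fn(xp, q_base)$resid - r) / fd_step[i]
    }, numeric(length(r)))
    J <- matrix(J, nrow = length(r))
    g <- as.numeric(crossprod(J, r))
    H <- crossprod(J)
    dH <- pmax(diag(H), 1e-12)
    accepted <- FALSE
    improved <- 0
    step_rel <- Inf
    for (try in 1:12) {
      A <- H + diag(lambda * dH, n)
      d <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(d)) { lambda <- lambda * 4; next }
      xt <- clamp(x + d)
      if (max(abs(xt - x)) == 0) break
      trial <- fn(xt, q_base)
      cost_t <- sum(trial$resid^2)
      if (cost_t <= cost) {
        improved <- cost - cost_t
        step_rel <- max(abs(xt - x) / pmax(abs(x), fd_step))
        x <- xt
        r <- trial$resid
        q_base <- trial$q
        cost <- cost_t
        hist <- c(hist, cost)
        lambda <- max(lambda * 0.1, 1e-12)
        accepted <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
    # stop after two consecutive iterations with negligible progress (a
    # single small accepted step can just reflect a high damping phase)
    tiny <- improved <= ftol * max(cost, 1e-12) || step_rel <= ptol
    stall <- if (tiny) stall + 1L else 0L
    if (stall >= 2L) break
  }
  list(par = x, cost = cost, initial_cost = initial_cost, niter = iter,
       cost_history = hist, q = q_base)
}
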