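#' Inverse-kinematics solver settings
#'
#' Loop closure is handled as a heavily weighted soft constraint: the
#' closure residual components enter the least-squares objective scaled by
#' `closure_weight`.  A frame whose closure residual exceeds
#' `closure_tolerance` at the solution is flagged as failed assembly and all
#' its per-marker errors are replaced by `failure_penalty`, so that an outer
#' optimization steers away from regions of design-variable space where the
#' loop cannot be closed.
#'
#' @param closure_weight dimensionless weight on closure residuals.
#' @param closure_tolerance assembly tolerance (mm).
#' @param failure_penalty error value reported for unassembled frames (mm).
#' @param max_iterations inner solver iteration cap per frame.
#' @param ftol,xtol,gtol relative cost / step / gradient convergence
#'   tolerances.
#' @return An object of class `ik_settings`.
#' @export
ik_settings <- function(closure_weight = 1000, closure_tolerance = 1,
                        failure_penalty = 1000, max_iterations = 100,
                        ftol = 1e-12, xtol = 1e-12, gtol = 1e-12) {
  vals <- list(closure_weight = closure_weight,
               closure_tolerance = closure_tolerance,
               failure_penalty = failure_penalty,
               max_iterations = as.integer(max_iterations),
               ftol = ftol, xtol = xtol, gtol = gtol)
  if (any(unlist(vals) <= 0)) stop("all IK settings must be positive")
  structure(vals, class = "ik_settings")
}

model_marker_names <- function(model) {
  unlist(lapply(model$bodies, function(b) colnames(b$landmarks))) %||%
    character(0)
}

#' Solve inverse kinematics for a single frame
#'
#' Nonlinear least squares over the model coordinates minimizing the sum of
#' squared marker distances plus `closure_weight^2` times the sum of squared
#' closure residuals, solved by a damped (Levenberg-Marquardt) trust-region
#' iteration with monotone acceptance.
#'
#' @param model a `kinematic_model`.
#' @param markers named list of length-3 vectors or a 3 x n matrix with
#'   marker names as columns (mm, ground frame); `NA` positions are treated
#'   as missing.
#' @param q_init initial coordinate vector (defaults to the model's stored
#'   neutral values).
#' @param settings an [ik_settings()] object.
#' @param free optional integer/character vector of coordinates to solve
#'   for; all others are held at `q_init` (all free by default).
#' @return list with `q`, `per_marker_error` (mm, named), `closure_residual`
#'   (mm), `assembled`, `iterations` and `cost_history`.
#' @export
solve_ik_frame <- function(model, markers, q_init = model_q(model),
                           settings = ik_settings(), free = NULL) {
  if (is.list(markers))
    markers <- vapply(markers, as.numeric, numeric(3))
  markers <- as.matrix(markers)
  use <- intersect(colnames(markers), model_marker_names(model))
  if (length(use) == 0 && length(model$constraints) == 0)
    stop("no markers in common between model and data")
  cm <- compile_model(model, marker_names = use)
  target <- if (length(use)) matrix(markers[, use], 3, length(use)) else
    matrix(numeric(0), 3, 0)
  if (any(!is.finite(q_init))) stop("q_init must be finite")
  free_idx <- resolve_free(cm, free)
  out <- ik_frame_cpp(cm, target, as.numeric(q_init), free_idx,
                      settings$closure_weight, settings$max_iterations,
                      settings$ftol, settings$xtol, settings$gtol)
  closure <- if (length(out$closure)) max(out$closure) else 0
  assembled <- closure <= settings$closure_tolerance
  err <- stats::setNames(as.numeric(out$distances), use)
  if (!assembled) err[] <- settings$failure_penalty
  list(q = stats::setNames(as.numeric(out$q), cm$q_names),
       per_marker_error = err, closure_residual = closure,
       assembled = assembled, iterations = out$iterations,
       cost_history = as.numeric(out$cost_history))
}

resolve_free <- function(cm, free) {
  if (is.null(free)) return(seq_len(cm$nq) - 1L)
  if (is.character(free)) free <- match(free, cm$q_names)
  if (anyNA(free) || any(free < 1) || any(free > cm$nq))
    stop("unknown coordinate in 'free'")
  as.integer(free) - 1L
}

#' Solve inverse kinematics over a marker trajectory
#'
#' Solves frame by frame; frame 1 starts from the model's neutral pose (or
#' `q_init`) and each later frame is warm-started from the previous
#' solution.  Alternatively a full `frames x nq` matrix of initial guesses
#' can be supplied (used to warm-start repeated solves inside the outer
#' personalization).
#'
#' @param model a `kinematic_model`.
#' @param markers a [marker_set()].
#' @param settings an [ik_settings()].
#' @param q_init `NULL`, a length-nq vector, or a `frames x nq` matrix.
#' @param free optional coordinates to solve for (see [solve_ik_frame()]).
#' @return An object of class `ik_result`: list with `q` (frames x nq),
#'   `distances` (frames x markers, mm; `failure_penalty` on unassembled
#'   frames), `closure` (mm), `assembled` (logical), `marker_residuals`
#'   (frames x 3 nmarkers signed components), `marker_names`, `times`,
#'   `rate`, `iterations`.
#' @export
solve_ik_trajectory <- function(model, markers, settings = ik_settings(),
                                q_init = NULL, free = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  nf <- n_frames(markers)
  use <- intersect(markers$names, model_marker_names(model))
  if (length(use) == 0) stop("no markers in common between model and data")
  cm <- compile_model(model, marker_names = use)
  sel <- match(use, markers$names)
  targets <- aperm(markers$positions[, sel, , drop = FALSE], c(3, 2, 1))
  all_missing <- apply(targets, 3, function(m) all(!is.finite(m)))
  if (any(all_missing))
    warning(sum(all_missing), " frame(s) have no finite marker data")
  if (is.null(q_init)) q_init <- model_q(model)
  q_init <- if (is.matrix(q_init)) {
    if (nrow(q_init) != nf || ncol(q_init) != cm$nq)
      stop("q_init matrix must be frames x nq")
    q_init
  } else matrix(as.numeric(q_init), 1, cm$nq)
  free_idx <- resolve_free(cm, free)
  out <- ik_traj_cpp(cm, targets, q_init, free_idx,
                     settings$closure_weight, settings$max_iterations,
                     settings$ftol, settings$xtol, settings$gtol)
  closure <- if (length(model$constraints)) {
    apply(out$closure, 1, max)
  } else rep(0, nf)
  assembled <- closure <= settings$closure_tolerance
  distances <- out$distances
  resid <- out$marker_residuals
  if (any(!assembled)) {
    distances[!assembled, ] <- settings$failure_penalty
    resid[!assembled, ] <- settings$failure_penalty
  }
  colnames(distances) <- use
  colnames(out$q) <- cm$q_names
  structure(list(q = out$q, distances = distances, closure = closure,
                 assembled = assembled, marker_residuals = resid,
                 marker_names = use, times = markers$times,
                 rate = markers$rate,
                 iterations = as.integer(out$iterations),
                 settings = settings),
            class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  st <- error_stats(x)
  cat("ik_result:", nrow(x$q), "frames,", length(x$marker_names),
      "markers\n  assembled:", sum(x$assembled), "/", length(x$assembled),
      "\n  avg error:", format(st$avg, digits = 4), "mm, max error:",
      format(st$max, digits = 4), "mm\n")
  invisible(x)
}

#' Marker distance error statistics
#'
#' @param results an `ik_result` or list of them.
#' @param markers optional character vector restricting the statistics to a
#'   marker subset (e.g. scapula markers only).
#' @return list with `avg` (mean of all per-marker distances over frames
#'   and markers, mm), `max` (largest single distance, mm), and `rmse`
#'   (named per-marker root-mean-square error over frames, mm).
#' @export
error_stats <- function(results, markers = NULL) {
  if (inherits(results, "ik_result")) results <- list(results)
  dmat <- do.call(rbind, lapply(results, function(r) {
    d <- r$distances
    if (!is.null(markers)) {
      keep <- intersect(markers, colnames(d))
      if (length(keep) == 0) stop("empty marker subset")
      d <- d[, keep, drop = FALSE]
    }
    d
  }))
  vals <- dmat[is.finite(dmat)]
  if (length(vals) == 0) stop("no finite marker distances")
  rmse <- sqrt(colMeans(dmat^2, na.rm = TRUE))
  list(avg = mean(vals), max = max(vals), rmse = rmse)
}
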