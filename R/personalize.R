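#' Design-variable selectors
#'
#' A selector names one scalar design variable of the outer personalization:
#' one of the 12 joint parameters of a joint (`select_joint_parameter`), a
#' body scale factor along one axis (`select_body_scale`), one coordinate of
#' a marker's position in its body frame (`select_marker_position`), or one
#' coordinate of a point-constraint attachment (`select_constraint_point`).
#'
#' Default optimization bounds (relative to the initial value) are +/-50 mm
#' for translations, +/-45 degrees for rotations, and absolute `[0.5, 2]`
#' for scale factors; they guard against non-anatomical minima and can be
#' overridden per selector.
#'
#' @param joint joint name.
#' @param frame `"parent"` or `"child"`.
#' @param component one of `"tx"`, `"ty"`, `"tz"` (mm), `"rx"`, `"ry"`,
#'   `"rz"` (rad).
#' @param bounds optional length-2 absolute bounds.
#' @return a `design_selector` object.
#' @rdname design-selectors
#' @export
select_joint_parameter <- function(joint, frame = c("parent", "child"),
                                   component, bounds = NULL) {
  frame <- match.arg(frame)
  component <- match.arg(component, c("tx", "ty", "tz", "rx", "ry", "rz"))
  new_selector("joint_parameter", bounds,
               joint = joint, frame = frame, component = component)
}

#' @param axis `"x"`, `"y"` or `"z"`.
#' @param body body name.
#' @rdname design-selectors
#' @export
select_body_scale <- function(body, axis = c("x", "y", "z"),
                              bounds = c(0.5, 2)) {
  axis <- match.arg(axis)
  new_selector("body_scale", bounds, body = body, axis = axis)
}

#' @param marker landmark name on `body`.
#' @rdname design-selectors
#' @export
select_marker_position <- function(body, marker, axis = c("x", "y", "z"),
                                   bounds = NULL) {
  axis <- match.arg(axis)
  new_selector("marker_position", bounds, body = body, marker = marker,
               axis = axis)
}

#' @param constraint point-constraint index in the model.
#' @param side `"a"` or `"b"` (which attachment of the constraint).
#' @rdname design-selectors
#' @export
select_constraint_point <- function(constraint = 1L, side = c("a", "b"),
                                    axis = c("x", "y", "z"), bounds = NULL) {
  side <- match.arg(side)
  axis <- match.arg(axis)
  new_selector("constraint_point", bounds,
               constraint = as.integer(constraint), side = side, axis = axis)
}

new_selector <- function(kind, bounds, ...) {
  structure(list(kind = kind, bounds = bounds, ...),
            class = "design_selector")
}

selector_key <- function(s) {
  paste(unlist(s[setdiff(names(s), "bounds")]), collapse = "/")
}

axis_num <- function(axis) match(axis, c("x", "y", "z"))

selector_get <- function(model, s) {
  switch(s$kind,
    joint_parameter = {
      j <- model$joints[[s$joint]]
      if (is.null(j)) stop("unknown joint '", s$joint, "'")
      block <- paste0(s$frame, "_",
                      if (substr(s$component, 1, 1) == "t") "translation"
                      else "rotation")
      j$params[[block]][axis_num(substr(s$component, 2, 2))]
    },
    body_scale = {
      b <- model$bodies[[s$body]]
      if (is.null(b)) stop("unknown body '", s$body, "'")
      b$scale_factors[axis_num(s$axis)]
    },
    marker_position = {
      lm <- model$bodies[[s$body]]$landmarks
      if (is.null(lm) || !s$marker %in% colnames(lm))
        stop("unknown marker '", s$marker, "' on body '", s$body, "'")
      lm[axis_num(s$axis), s$marker]
    },
    constraint_point = {
      if (s$constraint > length(model$constraints))
        stop("constraint index out of range")
      model$constraints[[s$constraint]][[paste0("point_", s$side)]][
        axis_num(s$axis)]
    },
    stop("unknown selector kind '", s$kind, "'"))
}

selector_set <- function(model, s, value) {
  value <- as.numeric(value)
  switch(s$kind,
    joint_parameter = {
      block <- paste0(s$frame, "_",
                      if (substr(s$component, 1, 1) == "t") "translation"
                      else "rotation")
      model$joints[[s$joint]]$params[[block]][
        axis_num(substr(s$component, 2, 2))] <- value
    },
    body_scale = {
      model$bodies[[s$body]]$scale_factors[axis_num(s$axis)] <- value
    },
    marker_position = {
      model$bodies[[s$body]]$landmarks[axis_num(s$axis), s$marker] <- value
    },
    constraint_point = {
      model$constraints[[s$constraint]][[paste0("point_", s$side)]][
        axis_num(s$axis)] <- value
    })
  model
}

#' Get / set the design vector named by a list of selectors
#' @param model a `kinematic_model`.
#' @param selectors list of `design_selector` objects.
#' @return `get_design`: named numeric vector of current values.
#' @export
get_design <- function(model, selectors) {
  stats::setNames(vapply(selectors, function(s) selector_get(model, s),
                         numeric(1)),
                  vapply(selectors, selector_key, character(1)))
}

#' @param x numeric vector of design values (selector order).
#' @rdname get_design
#' @export
set_design <- function(model, selectors, x) {
  for (i in seq_along(selectors)) model <- selector_set(model, selectors[[i]], x[i])
  model
}

selector_bounds <- function(s, x0) {
  if (!is.null(s$bounds)) return(as.numeric(s$bounds))
  if (s$kind == "body_scale") return(c(0.5, 2))
  rotational <- s$kind == "joint_parameter" &&
    substr(s$component, 1, 1) == "r"
  if (rotational) x0 + c(-pi / 4, pi / 4) else x0 + c(-50, 50)
}

#' Personalization task
#'
#' One stage of the outer optimization: a marker data set (optionally
#' referenced by file path and/or decimated to a stage rate) plus the set of
#' scalar design variables optimized during the stage.
#'
#' @param markers a [marker_set()] or a TRC file path, or `NULL` to use the
#'   marker set supplied to [run_sequence()].
#' @param selectors list of design selectors; duplicate scalars are
#'   rejected.
#' @param rate optional stage rate (Hz); the marker data are decimated to
#'   this rate before the stage runs.
#' @param name task label used in histories.
#' @param maxiter outer least-squares iteration cap.
#' @param ik an [ik_settings()] for the inner solves.
#' @return a `personalization_task`.
#' @export
personalization_task <- function(markers = NULL, selectors, rate = NULL,
                                 name = "task", maxiter = 30,
                                 ik = ik_settings()) {
  if (length(selectors) < 1) stop("a task needs at least one selector")
  keys <- vapply(selectors, selector_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate design variable in task: ", keys[duplicated(keys)][1])
  structure(list(markers = markers, selectors = selectors, rate = rate,
                 name = name, maxiter = as.integer(maxiter), ik = ik),
            class = "personalization_task")
}

map_basis <- function(q, from_times, to_times) {
  idx <- vapply(to_times, function(t) which.min(abs(from_times - t)),
                integer(1))
  q[idx, , drop = FALSE]
}

resolve_task_markers <- function(task, markers = NULL) {
  m <- task$markers %||% markers
  if (is.null(m)) stop("task '", task$name, "' has no marker data")
  if (is.character(m)) m <- read_trc(m)
  if (!is.null(task$rate) && task$rate != m$rate)
    m <- downsample_markers(m, task$rate)
  m
}

#' Run one personalization task
#'
#' Outer trust-region nonlinear least squares (Levenberg-Marquardt with
#' finite-difference Jacobians) over the selected design variables.  The
#' residual vector stacks the per-marker per-frame 3-D component errors
#' after an inner inverse-kinematics re-solve at the current design
#' variables; frames that fail to assemble contribute `failure_penalty`
#' residuals.  Inner solves are warm-started from the per-frame solutions
#' found at the task's starting design, which keeps the outer residual a
#' deterministic, smooth function of the design variables.
#'
#' @param model a `kinematic_model`.
#' @param task a [personalization_task()].
#' @param markers fallback marker set when the task carries none.
#' @param q_seed,seed_times optional per-frame coordinate matrix (and its
#'   frame times) used to warm-start the task's first inner solve, e.g. the
#'   `basis` of a preceding task; frames are matched by nearest time.
#' @return a `personalization_result`: list with the updated `model`,
#'   `final_cost` (mm^2 sum of squared marker distance errors),
#'   `initial_cost`, `stats` (from [error_stats()] on the final IK pass),
#'   `design` (final values), `ik` (the final `ik_result`), `basis` /
#'   `basis_times` (per-frame solutions for chaining) and `history`.
#' @export
run_task <- function(model, task, markers = NULL, q_seed = NULL,
                     seed_times = NULL) {
  ms <- resolve_task_markers(task, markers)
  sel <- task$selectors
  x0 <- get_design(model, sel)
  bounds <- vapply(seq_along(sel),
                   function(i) selector_bounds(sel[[i]], x0[i]), numeric(2))
  # forward-difference steps sized per variable kind: well above the inner
  # solver tolerance, well below the objective's curvature scale
  fd_step <- vapply(sel, function(s) {
    if (s$kind == "body_scale") return(1e-5)
    if (s$kind == "joint_parameter" && substr(s$component, 1, 1) == "r")
      return(1e-5)
    1e-3
  }, numeric(1))
  seed0 <- if (!is.null(q_seed)) {
    map_basis(q_seed, seed_times, ms$times)
  }
  fn <- function(x, q_init) {
    m2 <- set_design(model, sel, x)
    ik <- solve_ik_trajectory(m2, ms, settings = task$ik, q_init = q_init)
    list(resid = as.numeric(ik$marker_residuals), q = ik$q)
  }
  fit <- outer_lm(fn, x0, lower = bounds[1, ], upper = bounds[2, ],
                  fd_step = fd_step, maxiter = task$maxiter,
                  q_seed = seed0)
  x_fin <- fit$par
  model_out <- set_design(model, sel, x_fin)
  # evaluate with the optimizer's final per-frame basis: a cold chained
  # pass can land on worse per-frame local minima than the basis tracked
  # during the optimization
  ik_fin <- solve_ik_trajectory(model_out, ms, settings = task$ik,
                                q_init = fit$q)
  final_cost <- sum(ik_fin$marker_residuals^2)
  initial_cost <- fit$initial_cost
  if (final_cost > initial_cost + 1e-8 * (1 + initial_cost)) {
    warning("final cost exceeds initial cost; outer optimization made no ",
            "progress")
  }
  structure(list(model = model_out, final_cost = final_cost,
                 initial_cost = initial_cost,
                 stats = error_stats(ik_fin), design = x_fin, ik = ik_fin,
                 basis = ik_fin$q, basis_times = ms$times,
                 history = list(list(name = task$name,
                                     initial_cost = initial_cost,
                                     final_cost = final_cost,
                                     niter = fit$niter,
                                     cost_history = fit$cost_history,
                                     stats = error_stats(ik_fin)))),
            class = "personalization_result")
}

#' @export
print.personalization_result <- function(x, ...) {
  cat("personalization_result:", length(x$history), "task(s)\n")
  for (h in x$history)
    cat(sprintf("  %-18s cost %.4g -> %.4g (avg err %.3g mm)\n", h$name,
                h$initial_cost, h$final_cost, h$stats$avg))
  cat(sprintf("  final cost: %.6g mm^2, avg error: %.4g mm, max: %.4g mm\n",
              x$final_cost, x$stats$avg, x$stats$max))
  invisible(x)
}

#' Run a sequence of personalization tasks
#'
#' Tasks are executed in order, each starting from the previous task's
#' output model; per-task histories are retained.
#'
#' @param model a `kinematic_model`.
#' @param tasks list of [personalization_task()] objects.
#' @param markers fallback marker set for tasks that carry none.
#' @return a `personalization_result` for the final model with the combined
#'   history.
#' @export
run_sequence <- function(model, tasks, markers = NULL) {
  if (length(tasks) < 1) stop("at least one task is required")
  history <- list()
  res <- NULL
  basis <- NULL
  basis_times <- NULL
  for (task in tasks) {
    res <- run_task(model, task, markers = markers, q_seed = basis,
                    seed_times = basis_times)
    model <- res$model
    basis <- res$basis
    basis_times <- res$basis_times
    history <- c(history, res$history)
  }
  res$history <- history
  res
}

#' Staged personalization protocol for the closed-chain shoulder model
#'
#' Builds the six-task protocol: five single-joint stages on stage-rate
#' (default 20 Hz) data — (1) glenohumeral center location in scapula and
#' humerus, (2) clavicle scale along its long axis plus the constraint-point
#' location in the clavicle, (3) sternoclavicular parent-frame orientation
#' in the torso, (4) scapulothoracic parent-frame location in the torso,
#' (5) scapulothoracic child-frame location and orientation in the scapula —
#' followed by a combined task over all of these design variables at the
#' native (100 Hz) rate.  The staged order personalizes one anatomical joint
#' at a time to reduce the risk of local minima.
#'
#' @param markers concatenated full-rate [marker_set()] (or TRC path).
#' @param stage_rate rate of the five staged tasks (Hz).
#' @param stage_maxiter,combined_maxiter outer iteration caps.
#' @param ik an [ik_settings()].
#' @return list of [personalization_task()] objects.
#' @export
shoulder_protocol <- function(markers = NULL, stage_rate = 20,
                              stage_maxiter = 30, combined_maxiter = 15,
                              ik = ik_settings()) {
  jp <- function(joint, frame, comps) {
    lapply(comps, function(co) select_joint_parameter(joint, frame, co))
  }
  t_loc <- c("tx", "ty", "tz")
  t_rot <- c("rx", "ry", "rz")
  sel1 <- c(jp("glenohumeral", "parent", t_loc),
            jp("glenohumeral", "child", t_loc))
  sel2 <- c(list(select_body_scale("clavicle", "x")),
            lapply(c("x", "y", "z"), function(a)
              select_constraint_point(1L, "b", a)))
  sel3 <- jp("sternoclavicular", "parent", t_rot)
  sel4 <- jp("scapulothoracic", "parent", t_loc)
  sel5 <- c(jp("scapulothoracic", "child", t_loc),
            jp("scapulothoracic", "child", t_rot))
  stage <- function(name, sel) {
    personalization_task(markers, sel, rate = stage_rate, name = name,
                         maxiter = stage_maxiter, ik = ik)
  }
  c(list(stage("glenohumeral", sel1),
         stage("acromioclavicular", sel2),
         stage("sternoclavicular", sel3),
         stage("scapulothoracic_parent", sel4),
         stage("scapulothoracic_child", sel5)),
    list(personalization_task(markers, c(sel1, sel2, sel3, sel4, sel5),
                              rate = NULL, name = "combined",
                              maxiter = combined_maxiter, ik = ik)))
}

#' Personalization protocol for the open-chain scapula-only models
#'
#' A single selector set — scapulothoracic parent-frame orientation and
#' location in the torso plus child-frame location and orientation in the
#' scapula (12 parameters) — run first on stage-rate data and then refined
#' on the full-rate data.
#'
#' @inheritParams shoulder_protocol
#' @return list of [personalization_task()] objects.
#' @export
scapula_protocol <- function(markers = NULL, stage_rate = 20,
                             stage_maxiter = 40, combined_maxiter = 15,
                             ik = ik_settings()) {
  sel <- c(lapply(c("rx", "ry", "rz"), function(co)
             select_joint_parameter("scapulothoracic", "parent", co)),
           lapply(c("tx", "ty", "tz"), function(co)
             select_joint_parameter("scapulothoracic", "parent", co)),
           lapply(c("tx", "ty", "tz", "rx", "ry", "rz"), function(co)
             select_joint_parameter("scapulothoracic", "child", co)))
  list(personalization_task(markers, sel, rate = stage_rate,
                            name = "scapulothoracic_stage",
                            maxiter = stage_maxiter, ik = ik),
       personalization_task(markers, sel, rate = NULL,
                            name = "scapulothoracic_full",
                            maxiter = combined_maxiter, ik = ik))
}
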