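with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

jitter3 <- function(mag) stats::runif(3, -mag, mag)

#' Ground-truth synthetic subject
#'
#' Generates a reproducible synthetic subject: anatomically plausible
#' right-shoulder landmark tables (torso frame per ISB: origin at IJ,
#' X anterior, Y superior, Z lateral), ground-truth joint parameters for the
#' scapulothoracic, glenohumeral and sternoclavicular joints, and a
#' ground-truth 5-DOF-scapula closed-chain model.  The model's stored
#' neutral pose places the scapula at its spherical-coordinate radius
#' (`scap_q3` about 90 mm from the thorax-centered origin); the
#' sternoclavicular parent orientation and the clavicle scale are
#' constructed so that the acromioclavicular point constraint closes
#' exactly at that neutral pose.
#' All randomness is drawn from R's default Mersenne-Twister stream seeded
#' with `seed`; the caller's RNG state is preserved.
#'
#' @param seed integer seed.
#' @return An object of class `synthetic_subject`: list with `model` (the
#'   closed-chain ground truth), `landmarks` (scapula / humerus / torso
#'   tables), `st_params`, `gh_params`, `sc_params`, `clavicle_scale`,
#'   `clavicle_length` and `seed`.
#' @export
make_subject <- function(seed = 1L) {
  with_seed(seed, {
    scap <- cbind(GC = c(-10, -15, -5) + jitter3(4),
                  IA = c(-90, -120, -40) + jitter3(8),
                  TS = c(-100, -5, -70) + jitter3(8),
                  PLA = c(-35, 5, 10) + jitter3(4),
                  AC = c(-20, 10, -5) + jitter3(4))
    hum <- cbind(HHC = c(0, 0, 0),
                 LE = c(5, -270, -20) + jitter3(6),
                 ME = c(8, -272, 25) + jitter3(6))
    tors <- cbind(IJ = c(0, 0, 0),
                  C7 = c(-110, 25, 0) + jitter3(6),
                  T8 = c(-140, -180, 0) + jitter3(8))
    # the child frame sits at the scapula (near the landmark centroid), so
    # the radial coordinate q3 carries the full thorax-to-scapula distance
    # and the chart stays well-conditioned over the whole operating range
    st <- joint_parameters(
      parent_translation = (tors[, "IJ"] + tors[, "T8"]) / 2 + jitter3(8),
      parent_rotation = stats::runif(3, -0.1, 0.1),
      child_translation = c(-50, -25, -20) + jitter3(5),
      child_rotation = stats::runif(3, -0.1, 0.1))
    q3_neutral <- 90 + stats::runif(1, -10, 10)
    gh <- joint_parameters(
      parent_translation = scap[, "GC"] + jitter3(3),
      parent_rotation = stats::runif(3, -0.05, 0.05),
      child_translation = hum[, "HHC"] + jitter3(3),
      child_rotation = stats::runif(3, -0.05, 0.05))
    sc_loc <- tors[, "IJ"] + c(-5, -5, 20) + jitter3(3)
    landmarks <- list(scapula = scap, humerus = hum, torso = tors)
    # orient the clavicle long axis toward the neutral-pose AC position and
    # scale its length so the loop closes exactly at q = 0
    pre <- build_closed_chain_model(
      5, landmarks, st_params = st, gh_params = gh,
      sc_params = joint_parameters(parent_translation = sc_loc))
    q_ref <- stats::setNames(rep(0, 10), coordinate_names(pre))
    q_ref["scap_q3"] <- q3_neutral
    ac_w <- landmark_positions(pre, q_ref, "scapula")[, "AC"]
    d <- ac_w - sc_loc
    len <- sqrt(sum(d^2))
    u <- d / len
    helper <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
    w <- helper - sum(helper * u) * u
    w <- w / sqrt(sum(w^2))
    R <- cbind(u, w, c(u[2] * w[3] - u[3] * w[2],
                       u[3] * w[1] - u[1] * w[3],
                       u[1] * w[2] - u[2] * w[1]))
    sc <- joint_parameters(parent_translation = sc_loc,
                           parent_rotation = rotation_to_euler(R))
    clav_scale <- c(len / 150, 1, 1)
    model <- build_closed_chain_model(5, landmarks, st_params = st,
                                      gh_params = gh, sc_params = sc,
                                      clavicle_scale = clav_scale)
    model <- set_model_q(model, q_ref)  # stored neutral pose closes the loop
    structure(list(model = model, landmarks = landmarks, st_params = st,
                   gh_params = gh, sc_params = sc,
                   clavicle_scale = clav_scale, clavicle_length = 150,
                   seed = as.integer(seed)),
              class = "synthetic_subject")
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("synthetic_subject (seed ", x$seed, ")\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Ground-truth open-chain scapula model of a synthetic subject
#' @param subject a [make_subject()] result.
#' @param dofs 3, 4 or 5 scapular DOFs.
#' @return a `kinematic_model` sharing the subject's true scapulothoracic
#'   joint parameters.
#' @export
subject_scapula_model <- function(subject, dofs = 5) {
  m <- build_scapula_model(dofs, subject$landmarks$scapula,
                           subject$landmarks$torso,
                           st_params = subject$st_params)
  q <- model_q(m)
  q["scap_q3"] <- model_q(subject$model)[["scap_q3"]]
  set_model_q(m, q)
}

quintic_ease <- function(u) u^3 * (6 * u^2 - 15 * u + 10)

wave_profile <- function(u, wave) {
  switch(wave,
         updown = ifelse(u < 0.5, quintic_ease(2 * u),
                         quintic_ease(2 - 2 * u)),
         sweep = quintic_ease(u),
         stop("unknown wave type '", wave, "'"))
}

script_coord <- function(start, end, wave = "updown") {
  list(start = start, end = end, wave = wave)
}

#' Default eight-task motion script catalog
#'
#' Smooth (piecewise-quintic, zero endpoint velocity and acceleration)
#' driver trajectories for the eight shoulder tasks: forward elevation (FE,
#' WFE), scapular plane abduction (SA, WSA), coronal plane abduction (CA,
#' WCA) and internal/external humeral rotation at 90 degrees abduction
#' (ERa90) and at rest (ERaR).  Elevation tasks sweep 2.1 rad (120 degrees)
#' of glenohumeral elevation up and back down, with scapular drivers
#' following a scapulohumeral-rhythm-like fraction of the humeral range;
#' weighted variants ('W' prefix) use slightly larger scapular and slightly
#' smaller humeral ranges.  Driver coordinates are the four independent
#' scapular DOFs (`scap_q1`, `scap_q2`, `scap_q4`, `scap_q5`) and the three
#' glenohumeral rotations; scapular translation and the two clavicle
#' rotations are solved from loop closure.
#'
#' @param duration task duration (s).
#' @return named list of motion scripts.
#' @export
default_motion_scripts <- function(duration = 2) {
  # the q1:q2 mix differs by elevation plane (different planes recruit
  # upward rotation vs posterior tilt differently), so the pooled scapular
  # rotations span a proper 2-D range across the catalog
  elev <- function(plane, q1, q2, w = 1, scap = 1) list(
    gh_plane = script_coord(plane, plane),
    gh_elev = script_coord(0.2, 0.2 + 2.1 * w),
    gh_axial = script_coord(0.05, 0.05),
    scap_q1 = script_coord(0, q1 * scap),
    scap_q2 = script_coord(0, q2 * scap),
    scap_q4 = script_coord(0, 0.30 * scap),
    scap_q5 = script_coord(0, 0.15 * scap))
  er <- function(elev_angle, a0, a1, q1, q2, scap) list(
    gh_plane = script_coord(0.5, 0.5),
    gh_elev = script_coord(elev_angle, elev_angle),
    gh_axial = script_coord(a0, a1, wave = "sweep"),
    scap_q1 = script_coord(0, q1 * scap),
    scap_q2 = script_coord(0, q2 * scap),
    scap_q4 = script_coord(0, 0.08 * scap),
    scap_q5 = script_coord(0, 0.05 * scap))
  scripts <- list(
    FE = elev(1.3, 0.45, 0.12),
    WFE = elev(1.3, 0.45, 0.12, w = 0.95, scap = 1.15),
    SA = elev(0.6, 0.40, 0.25),
    WSA = elev(0.6, 0.40, 0.25, w = 0.95, scap = 1.15),
    CA = elev(0.05, 0.32, 0.36),
    WCA = elev(0.05, 0.32, 0.36, w = 0.95, scap = 1.15),
    ERa90 = er(1.5, -0.7, 0.7, 0.10, 0.04, scap = 1),
    ERaR = er(0.25, -0.5, 0.9, 0.05, 0.06, scap = 0.6))
  lapply(scripts, function(s) structure(list(coords = s,
                                             duration = duration),
                                        class = "motion_script"))
}

script_values <- function(script, times) {
  u <- times / max(times)
  vals <- vapply(script$coords, function(co)
    co$start + (co$end - co$start) * wave_profile(u, co$wave),
    numeric(length(times)))
  colnames(vals) <- names(script$coords)
  vals
}

#' Generate a gold-standard motion catalog from a synthetic subject
#'
#' Runs the ground-truth closed-chain model along each motion script:
#' per frame, the seven independent drivers are set from the script and the
#' scapular translation plus the two sternoclavicular rotations are solved
#' so the acromioclavicular loop closes exactly; the resulting scapula and
#' humerus 6-DOF poses (torso frame) are converted to quaternion pose
#' trajectories and passed through [synthesize_markers()] to produce the
#' 11-marker gold-standard set.  The generating coordinates are recorded
#' for oracle use.
#'
#' @param subject a [make_subject()] result.
#' @param scripts named list of motion scripts
#'   (default [default_motion_scripts()]).
#' @param rate sampling rate (Hz).
#' @return An object of class `motion_catalog`: list with `motions` (named
#'   list of [marker_set()]), `q_true` (named list of frames x nq
#'   generating-coordinate matrices), `rate`.
#' @export
make_catalog <- function(subject, scripts = default_motion_scripts(),
                         rate = 100) {
  model <- subject$model
  qn <- coordinate_names(model)
  closure_coords <- c("scap_q3", "sc_q1", "sc_q2")
  driver_coords <- setdiff(qn, closure_coords)
  no_markers <- matrix(numeric(0), 3, 0)
  asm_settings <- ik_settings(closure_weight = 1, closure_tolerance = 1,
                              max_iterations = 200)
  motions <- list()
  q_true <- list()
  for (mn in names(scripts)) {
    script <- scripts[[mn]]
    times <- seq(0, script$duration, by = 1 / rate)
    vals <- script_values(script, times)
    if (!all(colnames(vals) %in% driver_coords))
      stop("script '", mn, "' drives unknown or closure-solved coordinates")
    nf <- length(times)
    Q <- matrix(0, nf, length(qn), dimnames = list(NULL, qn))
    Q[, colnames(vals)] <- vals
    q_prev <- model_q(model)
    for (f in seq_len(nf)) {
      qf <- Q[f, ]
      qf[closure_coords] <- q_prev[closure_coords]
      sol <- solve_ik_frame(model, no_markers, q_init = qf,
                            settings = asm_settings, free = closure_coords)
      if (sol$closure_residual > 1e-6)
        stop("script '", mn, "' frame ", f,
             " cannot close the kinematic loop (residual ",
             format(sol$closure_residual), " mm)")
      Q[f, ] <- sol$q
      q_prev <- sol$q
    }
    poses <- body_pose_trajectories(model, Q, times, rate,
                                    c("scapula", "humerus"))
    motions[[mn]] <- synthesize_markers(
      poses, subject$landmarks[c("scapula", "humerus")],
      subject$landmarks$torso)
    q_true[[mn]] <- Q
  }
  structure(list(motions = motions, q_true = q_true, rate = rate),
            class = "motion_catalog")
}

body_pose_trajectories <- function(model, Q, times, rate, bodies) {
  cm <- compile_model(model)
  idx <- match(bodies, cm$body_order)
  nf <- nrow(Q)
  quats <- lapply(bodies, function(b) matrix(NA_real_, nf, 4))
  trans <- lapply(bodies, function(b) matrix(NA_real_, nf, 3))
  for (f in seq_len(nf)) {
    fkout <- fk_cpp(cm, Q[f, ])
    for (k in seq_along(bodies)) {
      quats[[k]][f, ] <- rotation_to_quat(fkout$rotations[, , idx[k]])
      trans[[k]][f, ] <- fkout$translations[, idx[k]]
    }
  }
  lapply(seq_along(bodies), function(k)
    pose_trajectory(bodies[k], quats[[k]], trans[[k]], rate, times = times))
}

#' Perturb a subject's model into a degraded starting point
#'
#' Uniformly perturbs the personalizable parameters of the ground-truth
#' model — glenohumeral center in scapula and humerus, clavicle long-axis
#' scale, constraint-point location in the clavicle, sternoclavicular
#' parent orientation, scapulothoracic parent location and child location /
#' orientation (for open-chain scapula models: the full 12 scapulothoracic
#' parameters) — and records the applied perturbation for recovery scoring.
#'
#' @param subject a [make_subject()] result.
#' @param magnitudes list with `translation` (mm), `rotation` (rad), `scale`
#'   (fractional) perturbation half-ranges.
#' @param seed integer seed.
#' @param model model to perturb; defaults to the subject's closed-chain
#'   ground truth.  Open-chain scapula models (no glenohumeral joint) get
#'   the scapula-only parameter set perturbed.
#' @return list with `model` (the degraded `kinematic_model`),
#'   `perturbation` (named vector of applied offsets) and `selectors`.
#' @export
perturb_subject <- function(subject,
                            magnitudes = list(translation = 10,
                                              rotation = 0.087,
                                              scale = 0.1),
                            seed = 1L, model = NULL) {
  model <- model %||% subject$model
  closed <- "glenohumeral" %in% names(model$joints)
  jp <- function(joint, frame, comps) {
    lapply(comps, function(co) select_joint_parameter(joint, frame, co))
  }
  t_loc <- c("tx", "ty", "tz"); t_rot <- c("rx", "ry", "rz")
  if (closed) {
    sel <- c(jp("glenohumeral", "parent", t_loc),
             jp("glenohumeral", "child", t_loc),
             list(select_body_scale("clavicle", "x")),
             lapply(c("x", "y", "z"), function(a)
               select_constraint_point(1L, "b", a)),
             jp("sternoclavicular", "parent", t_rot),
             jp("scapulothoracic", "parent", t_loc),
             jp("scapulothoracic", "child", t_loc),
             jp("scapulothoracic", "child", t_rot))
  } else {
    sel <- c(jp("scapulothoracic", "parent", t_rot),
             jp("scapulothoracic", "parent", t_loc),
             jp("scapulothoracic", "child", t_loc),
             jp("scapulothoracic", "child", t_rot))
  }
  mag_of <- function(s) {
    if (s$kind == "body_scale") return(magnitudes$scale)
    if (s$kind == "joint_parameter" && substr(s$component, 1, 1) == "r")
      return(magnitudes$rotation)
    magnitudes$translation
  }
  x0 <- get_design(model, sel)
  delta <- with_seed(seed, {
    vapply(sel, function(s) stats::runif(1, -mag_of(s), mag_of(s)),
           numeric(1))
  })
  names(delta) <- names(x0)
  list(model = set_design(model, sel, x0 + delta), perturbation = delta,
       selectors = sel)
}
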