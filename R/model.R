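#' Body segment
#'
#' A rigid body segment carrying named anatomical landmarks expressed in the
#' body's local frame (mm) and per-axis scale factors.  Landmark positions are
#' scaled elementwise by `scale_factors` whenever they are mapped to the
#' ground frame.
#'
#' @param name body name.
#' @param landmarks a 3 x n numeric matrix with landmark names as column
#'   names, or a named list of length-3 vectors, or `NULL`.
#' @param scale_factors length-3 strictly positive numeric (dimensionless).
#' @return An object of class `skin_body`.
#' @export
body_segment <- function(name, landmarks = NULL, scale_factors = c(1, 1, 1)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.list(landmarks)) {
    if (is.null(names(landmarks)) || anyDuplicated(names(landmarks)))
      stop("landmark names must be present and unique")
    landmarks <- vapply(landmarks, function(p) as.numeric(p), numeric(3))
  }
  if (!is.null(landmarks)) {
    landmarks <- as.matrix(landmarks)
    if (nrow(landmarks) != 3L) stop("landmarks must be 3 x n")
    if (is.null(colnames(landmarks)) || anyDuplicated(colnames(landmarks)))
      stop("landmark names must be present and unique")
  }
  scale_factors <- as.numeric(scale_factors)
  if (length(scale_factors) != 3L || any(scale_factors <= 0))
    stop("scale_factors must be 3 strictly positive numbers")
  structure(list(name = name, landmarks = landmarks,
                 scale_factors = scale_factors),
            class = "skin_body")
}

#' Joint parameters: the 12 calibratable frame offsets of one joint
#'
#' Every joint carries a parent frame fixed in the parent body and a child
#' frame fixed in the child body, each defined by a translation (mm) and a
#' body-fixed X-Y-Z Euler rotation (rad).  These 12 scalars are the
#' calibration targets of the personalization procedure.
#'
#' @param parent_translation,child_translation length-3 numeric (mm).
#' @param parent_rotation,child_rotation length-3 numeric Euler angles (rad);
#'   wrapped to (-pi, pi].
#' @return An object of class `joint_parameters`.
#' @export
joint_parameters <- function(parent_translation = c(0, 0, 0),
                             parent_rotation = c(0, 0, 0),
                             child_translation = c(0, 0, 0),
                             child_rotation = c(0, 0, 0)) {
  p <- lapply(list(parent_translation = parent_translation,
                   parent_rotation = parent_rotation,
                   child_translation = child_translation,
                   child_rotation = child_rotation), as.numeric)
  if (any(lengths(p) != 3L)) stop("each joint-parameter block has length 3")
  p$parent_rotation <- wrap_angle(p$parent_rotation)
  p$child_rotation <- wrap_angle(p$child_rotation)
  structure(p, class = "joint_parameters")
}

#' Generalized coordinate
#'
#' @param name coordinate name (unique within a model).
#' @param kind `"rotational"` (rad) or `"translational"` (mm).
#' @param value initial value.
#' @param bounds optional length-2 numeric bounds; defaults to `c(-pi, pi)`
#'   for rotations and `c(-500, 500)` mm for translations.
#' @return An object of class `model_coordinate`.
#' @export
coordinate <- function(name, kind = c("rotational", "translational"),
                       value = 0, bounds = NULL) {
  kind <- match.arg(kind)
  if (is.null(bounds))
    bounds <- if (kind == "rotational") c(-pi, pi) else c(-500, 500)
  bounds <- as.numeric(bounds)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  value <- as.numeric(value)
  if (value < bounds[1] || value > bounds[2])
    stop("coordinate value outside bounds for ", name)
  structure(list(name = name, kind = kind, value = value, bounds = bounds),
            class = "model_coordinate")
}

#' Elementary joint motion
#'
#' One step of a joint's ordered motion sequence: a rotation about, or a
#' translation along, one axis of the current intermediate frame.
#' Intermediate massless frames are represented implicitly: each motion acts
#' in the frame produced by the preceding motions, so a body-fixed sequence of
#' elementary motions reproduces the usual massless-frame construction.
#'
#' The motion's value is either an independent coordinate (`coord`) or an
#' affine function of other coordinates (`coeffs`), which is how a coordinate
#' coupler is represented.
#'
#' @param type `"rotation"` or `"translation"`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param coord name of the driving coordinate, or `NULL` for a coupled
#'   motion.
#' @param coeffs for coupled motions, `list(constant =, terms = c(coord = w))`
#'   giving value `constant + sum(w * q[coord])`.
#' @return A list of class `joint_motion`.
#' @export
joint_motion <- function(type = c("rotation", "translation"),
                         axis = c("x", "y", "z"), coord = NULL,
                         coeffs = NULL) {
  type <- match.arg(type)
  axis <- match.arg(axis)
  if (is.null(coord) == is.null(coeffs))
    stop("exactly one of coord / coeffs must be given")
  if (!is.null(coeffs)) {
    stopifnot(is.list(coeffs), !is.null(coeffs$constant),
              !is.null(names(coeffs$terms)))
  }
  structure(list(type = type, axis = axis, coord = coord, coeffs = coeffs),
            class = "joint_motion")
}

#' Joint between two bodies
#'
#' The joint transform from the parent body frame to the child body frame is
#' `parent_offset o motion_1 o ... o motion_k o inverse(child_offset)`, with
#' the offsets taken from [joint_parameters()].
#'
#' @param name joint name.
#' @param parent,child parent and child body names (`"ground"` is the root).
#' @param params a [joint_parameters()] object.
#' @param coordinates list of [coordinate()] objects (0 to 6).
#' @param motions list of [joint_motion()] objects; every coordinate must
#'   drive exactly one motion.
#' @return An object of class `model_joint`.
#' @export
model_joint <- function(name, parent, child, params = joint_parameters(),
                        coordinates = list(), motions = list()) {
  stopifnot(inherits(params, "joint_parameters"))
  if (length(coordinates) > 6L) stop("a joint has at most 6 coordinates")
  cn <- vapply(coordinates, `[[`, character(1), "name")
  if (anyDuplicated(cn)) stop("duplicate coordinate names in joint ", name)
  driven <- unlist(lapply(motions, `[[`, "coord"))
  if (!setequal(driven, cn) || length(driven) != length(cn))
    stop("each coordinate of joint ", name,
         " must drive exactly one motion in the sequence")
  structure(list(name = name, parent = parent, child = child, params = params,
                 coordinates = coordinates, motions = motions),
            class = "model_joint")
}

#' Point constraint closing a kinematic loop
#'
#' Constrains a point fixed in one body to coincide with a point fixed in
#' another body; its residual is the Euclidean distance between the two
#' points in the ground frame.  Each point can optionally follow its body's
#' scale factors.
#'
#' @param body_a,body_b body names.
#' @param point_a,point_b length-3 local positions (mm).
#' @param scale_with_body logical; scale the points with their bodies
#'   (recycled to both sides).
#' @return An object of class `point_constraint`.
#' @export
point_constraint <- function(body_a, point_a, body_b, point_b,
                             scale_with_body = TRUE) {
  scale_with_body <- rep_len(as.logical(scale_with_body), 2L)
  structure(list(body_a = body_a, point_a = as.numeric(point_a),
                 body_b = body_b, point_b = as.numeric(point_b),
                 scale_a = scale_with_body[1], scale_b = scale_with_body[2]),
            class = "point_constraint")
}

#' Kinematic model
#'
#' A tree of bodies rooted at ground, joined by parameterized joints, with
#' optional point constraints closing loops.  Joints must be given in
#' topological order (each parent is ground or the child of an earlier
#' joint); every non-ground body is the child of exactly one joint.
#'
#' @param bodies list of [body_segment()] objects.
#' @param joints list of [model_joint()] objects in topological order.
#' @param constraints list of [point_constraint()] objects.
#' @return An object of class `kinematic_model`.
#' @export
kinematic_model <- function(bodies, joints, constraints = list()) {
  bnames <- vapply(bodies, `[[`, character(1), "name")
  if (anyDuplicated(bnames) || "ground" %in% bnames)
    stop("body names must be unique and must not include 'ground'")
  names(bodies) <- bnames
  jchildren <- vapply(joints, `[[`, character(1), "child")
  if (!setequal(jchildren, bnames) || length(jchildren) != length(bnames))
    stop("every non-ground body must be the child of exactly one joint")
  known <- "ground"
  for (j in joints) {
    if (!j$parent %in% known)
      stop("joints are not in topological order (parent '", j$parent,
           "' of joint '", j$name, "' not yet defined)")
    known <- c(known, j$child)
  }
  names(joints) <- vapply(joints, `[[`, character(1), "name")
  for (con in constraints) {
    if (!all(c(con$body_a, con$body_b) %in% c(bnames, "ground")))
      stop("constraint references unknown body")
  }
  cn <- unlist(lapply(joints, function(j)
    vapply(j$coordinates, `[[`, character(1), "name")))
  if (anyDuplicated(cn)) stop("coordinate names must be unique across joints")
  m <- structure(list(bodies = bodies, joints = joints,
                      constraints = constraints),
                 class = "kinematic_model")
  if (independent_dof_count(m) < 0)
    stop("model has fewer coordinates than constraint equations")
  m
}

#' @export
print.kinematic_model <- function(x, ...) {
  cat("kinematic_model:", length(x$bodies), "bodies,",
      length(x$joints), "joints,", length(x$constraints), "constraints\n")
  cat("  coordinates (", length(coordinate_names(x)), "):",
      paste(coordinate_names(x), collapse = ", "), "\n", sep = "")
  cat("  independent DOFs:", independent_dof_count(x), "\n")
  invisible(x)
}

#' Coordinate names of a model
#' @param model a `kinematic_model`.
#' @return character vector of coordinate names in model order.
#' @export
coordinate_names <- function(model) {
  unlist(lapply(model$joints, function(j)
    vapply(j$coordinates, `[[`, character(1), "name"))) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Current coordinate values of a model
#' @param model a `kinematic_model`.
#' @return named numeric vector `q`.
#' @export
model_q <- function(model) {
  q <- unlist(lapply(model$joints, function(j)
    vapply(j$coordinates, `[[`, numeric(1), "value")))
  stats::setNames(as.numeric(q %||% numeric(0)), coordinate_names(model))
}

#' Set coordinate values of a model
#' @param model a `kinematic_model`.
#' @param q numeric vector of length equal to the model's coordinate count.
#' @return the updated model.
#' @export
set_model_q <- function(model, q) {
  nms <- coordinate_names(model)
  if (length(q) != length(nms)) stop("q has wrong length")
  k <- 0L
  for (jn in names(model$joints)) {
    for (i in seq_along(model$joints[[jn]]$coordinates)) {
      k <- k + 1L
      model$joints[[jn]]$coordinates[[i]]$value <- as.numeric(q[k])
    }
  }
  model
}

#' Independent degree-of-freedom count
#'
#' The number of generalized coordinates minus three per point constraint
#' (each active, independent point constraint removes three DOFs).
#'
#' @param model a `kinematic_model`.
#' @return integer DOF count.
#' @export
independent_dof_count <- function(model) {
  length(coordinate_names(model)) - 3L * length(model$constraints)
}

axis_index <- function(axis) match(axis, c("x", "y", "z")) - 1L

#' Compile a model for the C++ kinematics core
#'
#' Flattens a [kinematic_model()] into the plain-numeric representation used
#' by the compiled forward-kinematics and inverse-kinematics routines.
#' Usually called internally.
#'
#' @param model a `kinematic_model`.
#' @param marker_names character vector of landmark names to expose as
#'   markers (each must exist on exactly one body); `NULL` for none.
#' @return a list understood by the compiled core.
#' @export
compile_model <- function(model, marker_names = NULL) {
  joints <- model$joints
  nj <- length(joints)
  # reorder bodies so body j+1 is the child of joint j
  childs <- vapply(joints, `[[`, character(1), "child")
  ord <- c("ground", childs)
  body_idx <- stats::setNames(seq_along(ord) - 1L, ord)

  qn <- coordinate_names(model)
  nq <- length(qn)
  jpar <- matrix(0, 12, max(nj, 1))
  jparent <- integer(nj)
  mot_joint <- integer(0); mot_type <- integer(0); mot_axis <- integer(0)
  W <- matrix(0, 0, nq); b <- numeric(0)
  qlo <- numeric(nq); qhi <- numeric(nq)
  k <- 0L
  for (j in seq_len(nj)) {
    jt <- joints[[j]]
    jparent[j] <- body_idx[[jt$parent]]
    jpar[, j] <- c(jt$params$parent_translation, jt$params$parent_rotation,
                   jt$params$child_translation, jt$params$child_rotation)
    for (co in jt$coordinates) {
      k <- k + 1L
      qlo[k] <- co$bounds[1]; qhi[k] <- co$bounds[2]
    }
    for (mo in jt$motions) {
      mot_joint <- c(mot_joint, j - 1L)
      mot_type <- c(mot_type, if (mo$type == "rotation") 0L else 1L)
      mot_axis <- c(mot_axis, axis_index(mo$axis))
      w <- numeric(nq); bb <- 0
      if (!is.null(mo$coord)) {
        w[match(mo$coord, qn)] <- 1
      } else {
        bb <- mo$coeffs$constant
        idx <- match(names(mo$coeffs$terms), qn)
        if (anyNA(idx)) stop("coupled motion references unknown coordinate")
        w[idx] <- as.numeric(mo$coeffs$terms)
      }
      W <- rbind(W, w); b <- c(b, bb)
    }
  }
  scales <- cbind(c(1, 1, 1), vapply(model$bodies[childs], `[[`,
                                     numeric(3), "scale_factors"))
  marker_body <- integer(0); marker_loc <- matrix(0, 3, 0)
  if (!is.null(marker_names)) {
    for (mn in marker_names) {
      hit <- NULL
      for (bn in names(model$bodies)) {
        lm <- model$bodies[[bn]]$landmarks
        if (!is.null(lm) && mn %in% colnames(lm)) {
          if (!is.null(hit)) stop("landmark '", mn, "' exists on two bodies")
          hit <- list(body = body_idx[[bn]], loc = lm[, mn])
        }
      }
      if (is.null(hit)) stop("landmark '", mn, "' not found in model")
      marker_body <- c(marker_body, hit$body)
      marker_loc <- cbind(marker_loc, hit$loc)
    }
  }
  nc <- length(model$constraints)
  con_a <- integer(nc); con_b <- integer(nc)
  con_pa <- matrix(0, 3, nc); con_pb <- matrix(0, 3, nc)
  con_sa <- integer(nc); con_sb <- integer(nc)
  for (i in seq_len(nc)) {
    con <- model$constraints[[i]]
    con_a[i] <- body_idx[[con$body_a]]; con_b[i] <- body_idx[[con$body_b]]
    con_pa[, i] <- con$point_a; con_pb[, i] <- con$point_b
    con_sa[i] <- as.integer(con$scale_a); con_sb[i] <- as.integer(con$scale_b)
  }
  list(nbody = length(ord), njoint = nj, nq = nq, jparent = jparent,
       jpar = jpar, mot_joint = mot_joint, mot_type = mot_type,
       mot_axis = mot_axis, W = W, b = as.numeric(b), scales = scales,
       marker_body = marker_body, marker_loc = marker_loc,
       con_a = con_a, con_b = con_b, con_pa = con_pa, con_pb = con_pb,
       con_sa = con_sa, con_sb = con_sb, qlo = qlo, qhi = qhi,
       body_order = ord, marker_names = marker_names, q_names = qn)
}

#' Forward kinematics
#'
#' Computes the ground-frame pose of every body at coordinate values `q`.
#' Each body pose is the composition of its ancestor joint transforms; each
#' joint transform applies the parent frame offset, the joint's coordinate
#' motions in their declared sequence, and the inverse child frame offset.
#'
#' @param model a `kinematic_model`.
#' @param q coordinate vector (defaults to the model's stored values).
#' @return named list of [rigid_transform()] body poses (including ground).
#' @export
forward_kinematics <- function(model, q = model_q(model)) {
  if (length(q) != length(coordinate_names(model)))
    stop("q has wrong length: expected ", length(coordinate_names(model)),
         ", got ", length(q))
  cm <- compile_model(model)
  out <- fk_cpp(cm, as.numeric(q))
  poses <- lapply(seq_along(cm$body_order), function(i)
    rigid_transform(out$rotations[, , i], out$translations[, i]))
  stats::setNames(poses, cm$body_order)
}

#' Landmark positions in the ground frame
#'
#' @param model a `kinematic_model`.
#' @param q coordinate vector.
#' @param body body name.
#' @return 3 x n matrix of landmark positions (mm), landmark names as
#'   column names.  Positions are the body pose applied to
#'   `scale_factors * local_landmark`.
#' @export
landmark_positions <- function(model, q = model_q(model), body) {
  if (!body %in% names(model$bodies)) stop("unknown body '", body, "'")
  lm <- model$bodies[[body]]$landmarks
  if (is.null(lm) || ncol(lm) == 0)
    return(matrix(numeric(0), 3, 0))
  cm <- compile_model(model, marker_names = colnames(lm))
  pos <- marker_positions_cpp(cm, as.numeric(q))
  colnames(pos) <- colnames(lm)
  pos
}

#' Point-constraint residuals
#'
#' @param model a `kinematic_model`.
#' @param q coordinate vector.
#' @return numeric vector of per-constraint point distances (mm, >= 0);
#'   zero iff the loop is exactly closed.
#' @export
constraint_residuals <- function(model, q = model_q(model)) {
  if (length(model$constraints) == 0) return(numeric(0))
  cm <- compile_model(model)
  as.numeric(constraint_residuals_cpp(cm, as.numeric(q)))
}
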