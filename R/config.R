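MODEL_SCHEMA <- "shoulderkin-model"
MODEL_SCHEMA_VERSION <- 1L

#' Write / read a model definition file
#'
#' Serializes a [kinematic_model()] — bodies with landmark tables and scale
#' factors, joints with parameters, coordinates and motion sequences, and
#' point constraints — to a versioned YAML document.  The round trip is
#' stable to full double precision.
#'
#' @param model a `kinematic_model`.
#' @param path file path.
#' @return `write_model_config`: `path` invisibly; `read_model_config`: the
#'   reconstructed `kinematic_model`.
#' @export
write_model_config <- function(model, path) {
  ser_body <- function(b) list(
    name = b$name,
    scale_factors = as.numeric(b$scale_factors),
    landmarks = if (is.null(b$landmarks)) NULL else
      stats::setNames(lapply(seq_len(ncol(b$landmarks)), function(i)
        as.numeric(b$landmarks[, i])), colnames(b$landmarks)))
  ser_joint <- function(j) list(
    name = j$name, parent = j$parent, child = j$child,
    params = lapply(unclass(j$params), as.numeric),
    coordinates = lapply(j$coordinates, function(co)
      list(name = co$name, kind = co$kind, value = co$value,
           bounds = co$bounds)),
    motions = lapply(j$motions, function(mo) {
      out <- list(type = mo$type, axis = mo$axis)
      if (!is.null(mo$coord)) out$coord <- mo$coord
      else out$coeffs <- list(constant = mo$coeffs$constant,
                              terms = as.list(mo$coeffs$terms))
      out
    }))
  ser_con <- function(con) list(
    body_a = con$body_a, point_a = as.numeric(con$point_a),
    body_b = con$body_b, point_b = as.numeric(con$point_b),
    scale_a = con$scale_a, scale_b = con$scale_b)
  doc <- list(schema = MODEL_SCHEMA, version = MODEL_SCHEMA_VERSION,
              bodies = lapply(unname(model$bodies), ser_body),
              joints = lapply(unname(model$joints), ser_joint),
              constraints = lapply(model$constraints, ser_con))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, MODEL_SCHEMA))
    stop("not a model definition file (schema '", doc$schema, "')")
  if (!identical(as.integer(doc$version), MODEL_SCHEMA_VERSION))
    stop("unsupported model schema version ", doc$version)
  bodies <- lapply(doc$bodies, function(b) body_segment(
    b$name,
    landmarks = if (!is.null(b$landmarks))
      vapply(b$landmarks, as.numeric, numeric(3)),
    scale_factors = b$scale_factors))
  joints <- lapply(doc$joints, function(j) model_joint(
    j$name, j$parent, j$child,
    params = do.call(joint_parameters, lapply(j$params, as.numeric)),
    coordinates = lapply(j$coordinates, function(co)
      coordinate(co$name, co$kind, co$value, as.numeric(co$bounds))),
    motions = lapply(j$motions, function(mo) {
      if (!is.null(mo$coord)) joint_motion(mo$type, mo$axis,
                                           coord = mo$coord)
      else joint_motion(mo$type, mo$axis, coeffs = list(
        constant = as.numeric(mo$coeffs$constant),
        terms = unlist(mo$coeffs$terms)))
    })))
  constraints <- lapply(doc$constraints, function(con) point_constraint(
    con$body_a, as.numeric(con$point_a), con$body_b,
    as.numeric(con$point_b),
    scale_with_body = c(con$scale_a, con$scale_b)))
  kinematic_model(bodies, joints, constraints)
}
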