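SCAPULA_LANDMARKS <- c("GC", "IA", "TS", "PLA", "AC")
HUMERUS_LANDMARKS <- c("HHC", "LE", "ME")
TORSO_LANDMARKS <- c("IJ", "C7", "T8")

check_landmarks <- function(lm, needed, what) {
  if (is.list(lm)) lm <- vapply(lm, as.numeric, numeric(3))
  lm <- as.matrix(lm)
  if (is.null(colnames(lm)) || !all(needed %in% colnames(lm)))
    stop(what, " landmarks must include: ", paste(needed, collapse = ", "))
  lm
}

#' Default generic torso and clavicle segments
#'
#' Deterministic generic geometry used when no subject-specific torso or
#' clavicle is available.  The torso frame follows the ISB convention
#' (origin at IJ, X anterior, Y superior, Z to the subject's right); the
#' clavicle is a straight 150 mm segment along its local x axis whose distal
#' endpoint (`clavicle_end`) is the attachment point for the
#' acromioclavicular point constraint.
#'
#' @return list with elements `torso` and `clavicle` ([body_segment()]
#'   objects) and `clavicle_end` (length-3 numeric, mm).
#' @export
default_generic_segments <- function() {
  torso <- body_segment("torso", landmarks = cbind(
    IJ = c(0, 0, 0), C7 = c(-110, 25, 0), T8 = c(-140, -180, 0)))
  clav_end <- c(150, 0, 0)
  clavicle <- body_segment("clavicle",
                           landmarks = cbind(clavicle_end = clav_end))
  list(torso = torso, clavicle = clavicle, clavicle_end = clav_end)
}

scapulothoracic_motions <- function(dofs, prefix = "scap") {
  co <- list(
    coordinate(paste0(prefix, "_q1"), "rotational"),
    coordinate(paste0(prefix, "_q2"), "rotational", bounds = c(-1.4, 1.4)),
    coordinate(paste0(prefix, "_q3"), "translational", bounds = c(-200, 200)))
  mo <- list(
    joint_motion("rotation", "y", coord = paste0(prefix, "_q1")),
    joint_motion("rotation", "x", coord = paste0(prefix, "_q2")),
    joint_motion("translation", "z", coord = paste0(prefix, "_q3")))
  if (dofs >= 4) {
    co <- c(co, list(coordinate(paste0(prefix, "_q4"), "rotational")))
    mo <- c(mo, list(joint_motion("rotation", "z",
                                  coord = paste0(prefix, "_q4"))))
  }
  if (dofs >= 5) {
    co <- c(co, list(coordinate(paste0(prefix, "_q5"), "rotational")))
    mo <- c(mo, list(joint_motion("rotation", "x",
                                  coord = paste0(prefix, "_q5"))))
  }
  list(coordinates = co, motions = mo)
}

#' Build an open-chain scapula-only model
#'
#' The scapulothoracic joint is modeled with spherical coordinates: two
#' orthogonal thorax-centered rotations (`q1` about the torso vertical axis,
#' `q2` about the once-rotated anterior-posterior axis) followed by a radial
#' translation `q3` along the twice-rotated lateral axis.  The 4-DOF variant
#' adds a scapula-centered rotation `q4` about an approximately
#' medial-lateral axis, and the 5-DOF variant a rotation `q5` about an
#' approximately anterior-posterior axis.
#'
#' @param dofs number of scapular DOFs: 3, 4, or 5.
#' @param scapula_landmarks 3 x n matrix (or named list) with at least
#'   columns GC, IA, TS, PLA, AC (mm, scapula frame).
#' @param torso_landmarks matrix/list with at least IJ, C7, T8 (mm, torso
#'   frame).
#' @param st_params optional [joint_parameters()] for the scapulothoracic
#'   joint.  Default: parent frame at the midpoint of IJ and T8 (thorax
#'   center) with axes aligned to the torso; child frame at the scapula
#'   landmark centroid with axes aligned to the scapula.
#' @return a `kinematic_model` with bodies `torso` (welded to ground) and
#'   `scapula`.
#' @export
build_scapula_model <- function(dofs, scapula_landmarks, torso_landmarks,
                                st_params = NULL) {
  if (!dofs %in% 3:5) stop("dofs must be 3, 4, or 5")
  slm <- check_landmarks(scapula_landmarks, SCAPULA_LANDMARKS, "scapula")
  tlm <- check_landmarks(torso_landmarks, TORSO_LANDMARKS, "torso")
  if (is.null(st_params)) {
    st_params <- joint_parameters(
      parent_translation = (tlm[, "IJ"] + tlm[, "T8"]) / 2,
      child_translation = rowMeans(slm[, SCAPULA_LANDMARKS]))
  }
  st <- scapulothoracic_motions(dofs)
  kinematic_model(
    bodies = list(body_segment("torso", tlm), body_segment("scapula", slm)),
    joints = list(
      model_joint("torso_ground", "ground", "torso"),
      model_joint("scapulothoracic", "torso", "scapula", params = st_params,
                  coordinates = st$coordinates, motions = st$motions)))
}

#' Build a closed-chain shoulder model
#'
#' Construction proceeds in five steps: a torso welded to ground, a
#' subject-specific scapula (4 or 5 scapulothoracic DOFs) as child of the
#' torso, a subject-specific humerus as child of the scapula through a
#' 3-DOF glenohumeral joint (ISB-style Y-X-Y sequence: plane of elevation,
#' elevation, axial rotation), a scaled generic clavicle as child of the
#' torso through a 2-DOF sternoclavicular joint (protraction-like and
#' elevation-like rotations), and finally a point constraint between the AC
#' landmark on the scapula and the distal end of the clavicle, closing the
#' kinematic loop and removing three DOFs (independent DOFs: 6 for the 4-DOF
#' scapula, 7 for the 5-DOF scapula).
#'
#' @param scapula_dofs 4 or 5 (the 3-DOF scapula falls short of the
#'   open-chain accuracy thresholds and is rejected).
#' @param landmarks list with elements `scapula`, `humerus`, `torso`: local
#'   landmark tables (mm).
#' @param st_params,gh_params,sc_params optional [joint_parameters()] for
#'   the scapulothoracic, glenohumeral, and sternoclavicular joints.
#'   Defaults: scapulothoracic as in [build_scapula_model()]; glenohumeral
#'   parent frame at the GC landmark and child frame at HHC; sternoclavicular
#'   parent frame at the IJ landmark.
#' @param clavicle_scale length-3 scale factors of the generic clavicle.
#' @param clavicle_length generic clavicle length (mm); its distal endpoint
#'   `(clavicle_length, 0, 0)` is the constraint point and scales with the
#'   clavicle body.
#' @return a `kinematic_model` with bodies torso, scapula, humerus, clavicle
#'   and one point constraint.
#' @export
build_closed_chain_model <- function(scapula_dofs, landmarks,
                                     st_params = NULL, gh_params = NULL,
                                     sc_params = NULL,
                                     clavicle_scale = c(1, 1, 1),
                                     clavicle_length = 150) {
  if (!scapula_dofs %in% c(4, 5))
    stop("scapula_dofs must be 4 or 5 for the closed-chain model ",
         "(the 3-DOF scapula does not meet the open-chain accuracy ",
         "thresholds)")
  slm <- check_landmarks(landmarks$scapula, SCAPULA_LANDMARKS, "scapula")
  hlm <- check_landmarks(landmarks$humerus, HUMERUS_LANDMARKS, "humerus")
  tlm <- check_landmarks(landmarks$torso, TORSO_LANDMARKS, "torso")
  gen <- default_generic_segments()
  clav_end <- gen$clavicle_end * clavicle_length / 150
  clavicle <- body_segment("clavicle",
                           landmarks = cbind(clavicle_end = clav_end),
                           scale_factors = clavicle_scale)
  if (is.null(st_params)) {
    st_params <- joint_parameters(
      parent_translation = (tlm[, "IJ"] + tlm[, "T8"]) / 2,
      child_translation = rowMeans(slm[, SCAPULA_LANDMARKS]))
  }
  if (is.null(gh_params)) {
    gh_params <- joint_parameters(parent_translation = slm[, "GC"],
                                  child_translation = hlm[, "HHC"])
  }
  if (is.null(sc_params)) {
    sc_params <- joint_parameters(parent_translation = tlm[, "IJ"])
  }
  st <- scapulothoracic_motions(scapula_dofs)
  # bounds cover the anatomical glenohumeral range while excluding the
  # mirrored Y-X-Y solution branch (plane and axial shifted by pi with
  # elevation negated), which IK can otherwise fall into near zero elevation
  gh_co <- list(coordinate("gh_plane", "rotational", bounds = c(-1.6, 1.6)),
                coordinate("gh_elev", "rotational", bounds = c(-0.5, 2.6)),
                coordinate("gh_axial", "rotational", bounds = c(-1.6, 1.6)))
  gh_mo <- list(joint_motion("rotation", "y", coord = "gh_plane"),
                joint_motion("rotation", "x", coord = "gh_elev"),
                joint_motion("rotation", "y", coord = "gh_axial"))
  sc_co <- list(coordinate("sc_q1", "rotational"),
                coordinate("sc_q2", "rotational"))
  sc_mo <- list(joint_motion("rotation", "y", coord = "sc_q1"),
                joint_motion("rotation", "z", coord = "sc_q2"))
  kinematic_model(
    bodies = list(body_segment("torso", tlm), body_segment("scapula", slm),
                  body_segment("humerus", hlm), clavicle),
    joints = list(
      model_joint("torso_ground", "ground", "torso"),
      model_joint("scapulothoracic", "torso", "scapula", params = st_params,
                  coordinates = st$coordinates, motions = st$motions),
      model_joint("glenohumeral", "scapula", "humerus", params = gh_params,
                  coordinates = gh_co, motions = gh_mo),
      model_joint("sternoclavicular", "torso", "clavicle",
                  params = sc_params, coordinates = sc_co, motions = sc_mo)),
    constraints = list(
      point_constraint("scapula", slm[, "AC"], "clavicle", clav_end,
                       scale_with_body = TRUE)))
}

#' Read / write a subject landmark table
#'
#' Delimited text with columns `body`, `name`, `x`, `y`, `z` (mm, local
#' body frames).
#'
#' @param path file path.
#' @return `read_landmarks`: named list of 3 x n landmark matrices, one per
#'   body.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("body", "name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$body), function(d) {
    m <- t(as.matrix(d[, c("x", "y", "z")]))
    colnames(m) <- d$name
    rownames(m) <- NULL
    m
  })
  out
}

#' @param landmarks named list of 3 x n landmark matrices.
#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- do.call(rbind, lapply(names(landmarks), function(bn) {
    m <- landmarks[[bn]]
    data.frame(body = bn, name = colnames(m), x = m[1, ], y = m[2, ],
               z = m[3, ], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
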