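# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SCAP_MARKERS <- c("GC", "IA", "TS", "PLA", "AC")
ALL_MARKERS <- c(SCAP_MARKERS, "HHC", "LE", "ME", "IJ", "C7", "T8")

fixture_subject <- function() cached("subject", make_subject(1))

# short catalog for unit tests: full marker schema, modest frame counts
fixture_catalog_short <- function() cached("catalog_short", {
  make_catalog(fixture_subject(), default_motion_scripts(duration = 0.5),
               rate = 20)
})

# study-condition catalog for acceptance tests: 8 tasks, 2 s, 100 Hz
fixture_catalog_full <- function() cached("catalog_full", {
  make_catalog(fixture_subject())
})

fixture_markers_full <- function() cached("markers_full", {
  concatenate_markers(fixture_catalog_full()$motions)
})

# one-DOF hinge: a single body rotating about the ground z axis, with a
# marker on a 100 mm lever arm
hinge_model <- function(marker_at = c(100, 0, 0)) {
  kinematic_model(
    bodies = list(body_segment("arm", landmarks = cbind(TIP = marker_at))),
    joints = list(model_joint(
      "hinge", "ground", "arm",
      coordinates = list(coordinate("theta", "rotational")),
      motions = list(joint_motion("rotation", "z", coord = "theta")))))
}

# planar two-body chain used for composition / scaling checks
random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rotation(q / sqrt(sum(q^2)))
}

random_transform <- function(scale = 100) {
  rigid_transform(random_rotation(), stats::runif(3, -scale, scale))
}

gh_center_selectors <- function(frame = "parent") {
  lapply(c("tx", "ty", "tz"), function(co)
    select_joint_parameter("glenohumeral", frame, co))
}

gh_center_error <- function(model_a, model_b, frame = "parent") {
  sel <- gh_center_selectors(frame)
  sqrt(sum((get_design(model_a, sel) - get_design(model_b, sel))^2))
}
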