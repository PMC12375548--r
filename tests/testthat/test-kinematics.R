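test_that("forward kinematics of trivial models", {
  m <- hinge_model()
  # all offsets identity, q = 0: body at ground identity
  fk <- forward_kinematics(m, 0)
  expect_equal(fk$arm$rotation, diag(3))
  expect_equal(fk$arm$translation, c(0, 0, 0))
  expect_error(forward_kinematics(m, c(0, 0)), "wrong length")

  slider <- kinematic_model(
    bodies = list(body_segment("b")),
    joints = list(model_joint(
      "slide", "ground", "b",
      coordinates = list(coordinate("d", "translational")),
      motions = list(joint_motion("translation", "x", coord = "d")))))
  expect_equal(forward_kinematics(slider, 5)$b$translation, c(5, 0, 0))
})

test_that("5-DOF scapula pose matches the elementary-transform chain oracle", {
  s <- fixture_subject()
  model <- subject_scapula_model(s, dofs = 5)
  p <- model$joints$scapulothoracic$params
  set.seed(5)
  for (i in 1:10) {
    q <- c(runif(2, -0.6, 0.6), runif(1, 60, 120), runif(2, -0.5, 0.5))
    oracle <- Reduce(rt_compose, list(
      rigid_transform(euler_to_rotation(p$parent_rotation),
                      p$parent_translation),
      rigid_transform(rot_y(q[1])),
      rigid_transform(rot_x(q[2])),
      rigid_transform(translation = c(0, 0, q[3])),
      rigid_transform(rot_z(q[4])),
      rigid_transform(rot_x(q[5])),
      rt_inverse(rigid_transform(euler_to_rotation(p$child_rotation),
                                 p$child_translation))))
    fk <- forward_kinematics(model, q)$scapula
    expect_lt(max(abs(fk$rotation - oracle$rotation)), 1e-10)
    expect_lt(max(abs(fk$translation - oracle$translation)), 1e-10)
  }
})

test_that("landmark positions apply scale then pose", {
  m <- hinge_model(marker_at = c(3, 0, 0))
  pos <- landmark_positions(m, 0, "arm")
  expect_equal(pos[, "TIP"], c(3, 0, 0))

  m$bodies$arm$scale_factors <- c(2, 1, 1)
  expect_equal(landmark_positions(m, 0, "arm")[, "TIP"], c(6, 0, 0))

  # rotated pose matches the quaternion oracle
  set.seed(9)
  theta <- runif(1, -2, 2)
  q <- c(cos(theta / 2), 0, 0, sin(theta / 2))  # about z
  expect_equal(landmark_positions(m, theta, "arm")[, "TIP"],
               as.numeric(quat_to_rotation(q) %*% c(6, 0, 0)),
               tolerance = 1e-10)
  expect_error(landmark_positions(m, 0, "nope"), "unknown body")
})

test_that("constraint residuals are distances and vanish iff closed", {
  s <- fixture_subject()
  q0 <- model_q(s$model)
  expect_lt(constraint_residuals(s$model, q0), 1e-9)
  # direct recomputation from landmark positions at random q
  set.seed(13)
  for (i in 1:5) {
    q <- q0 + runif(10, -0.2, 0.2)
    ac <- landmark_positions(s$model, q, "scapula")[, "AC"]
    clav <- landmark_positions(s$model, q, "clavicle")[, "clavicle_end"]
    expect_equal(constraint_residuals(s$model, q),
                 sqrt(sum((ac - clav)^2)), tolerance = 1e-10)
  }
})

test_that("constraint residuals are invariant under a rigid move of the assembly", {
  s <- fixture_subject()
  set.seed(21)
  q <- model_q(s$model) + runif(10, -0.2, 0.2)
  r0 <- constraint_residuals(s$model, q)
  moved <- s$model
  moved$joints$torso_ground$params <- joint_parameters(
    parent_translation = c(40, -30, 25),
    parent_rotation = c(0.4, -0.3, 0.8))
  expect_equal(constraint_residuals(moved, q), r0, tolerance = 1e-9)
})

test_that("inverting the R-side joint-transform chain recovers identity", {
  # independent R implementation of one joint transform
  r_joint_transform <- function(j, qv) {
    p <- j$params
    tf <- rigid_transform(euler_to_rotation(p$parent_rotation),
                          p$parent_translation)
    for (mo in j$motions) {
      val <- if (!is.null(mo$coord)) qv[[mo$coord]] else
        mo$coeffs$constant + sum(mo$coeffs$terms * qv[names(mo$coeffs$terms)])
      step <- if (mo$type == "rotation") {
        rigid_transform(switch(mo$axis, x = rot_x(val), y = rot_y(val),
                               z = rot_z(val)))
      } else {
        tr <- c(0, 0, 0); tr[match(mo$axis, c("x", "y", "z"))] <- val
        rigid_transform(translation = tr)
      }
      tf <- rt_compose(tf, step)
    }
    rt_compose(tf, rt_inverse(rigid_transform(
      euler_to_rotation(p$child_rotation), p$child_translation)))
  }
  s <- fixture_subject()
  set.seed(17)
  q <- model_q(s$model) + runif(10, -0.3, 0.3)
  fk <- forward_kinematics(s$model, q)
  for (j in s$model$joints) {
    parent <- if (j$parent == "ground") rt_identity() else fk[[j$parent]]
    chain <- rt_compose(parent, r_joint_transform(j, q))
    id <- rt_compose(rt_inverse(chain), fk[[j$child]])
    expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(id$translation)), 1e-9)
  }
})

test_that("independent DOF counting follows coordinates minus constraints", {
  s <- fixture_subject()
  expect_identical(independent_dof_count(s$model), 7L)
  m4 <- build_closed_chain_model(4, s$landmarks)
  expect_identical(independent_dof_count(m4), 6L)
  open5 <- subject_scapula_model(s, 5)
  expect_identical(independent_dof_count(open5), 5L)
})

test_that("model construction rejects malformed input", {
  expect_error(coordinate("x", "rotational", value = 10), "outside bounds")
  expect_error(joint_parameters(parent_translation = 1:2), "length 3")
  expect_error(body_segment("b", landmarks = cbind(A = 1:3, A = 4:6)),
               "unique")
  # a coordinate must drive exactly one motion
  expect_error(model_joint(
    "j", "ground", "b",
    coordinates = list(coordinate("a", "rotational")),
    motions = list()), "exactly one motion")
})
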