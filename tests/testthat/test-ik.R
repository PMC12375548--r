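test_that("single-frame IK recovers known poses and matches grid search", {
  m <- hinge_model()
  target <- landmark_positions(m, 0.7, "arm")
  # initialized at the solution: stays there with zero error
  at_sol <- solve_ik_frame(m, target, q_init = 0.7)
  expect_equal(unname(at_sol$q), 0.7, tolerance = 1e-10)
  expect_lt(max(at_sol$per_marker_error), 1e-8)

  # displaced marker: solution matches a dense grid search over the angle
  off_target <- target + c(5, -8, 2)
  sol <- solve_ik_frame(m, off_target, q_init = 0)
  grid <- seq(-pi, pi, length.out = 200001)
  cost <- vapply(grid, function(th) {
    sum((landmark_positions(m, th, "arm") - off_target)^2)
  }, numeric(1))
  expect_lt(abs(unname(sol$q) - grid[which.min(cost)]), 1e-3)

  expect_error(solve_ik_frame(m, target, q_init = NaN), "finite")
})

test_that("objective decreases monotonically across solver iterations", {
  m <- hinge_model()
  target <- landmark_positions(m, 1.1, "arm")
  sol <- solve_ik_frame(m, target, q_init = -0.5)
  expect_true(all(diff(sol$cost_history) <= 0))
})

test_that("unreachable closure flags assembly failure with penalty errors", {
  s <- fixture_subject()
  broken <- s$model
  # move the constraint attachment far outside the clavicle's reach
  broken$constraints[[1]]$point_b <- c(1500, 0, 0)
  ms <- fixture_catalog_short()$motions$FE
  sol <- solve_ik_frame(broken, marker_frame(ms, 1),
                        q_init = model_q(broken))
  expect_false(sol$assembled)
  expect_true(all(sol$per_marker_error ==
                    ik_settings()$failure_penalty))
  traj <- solve_ik_trajectory(broken, ms)
  expect_true(all(!traj$assembled))
  expect_true(all(traj$distances == ik_settings()$failure_penalty))
})

test_that("trajectory IK tracks generating coordinates on noise-free data", {
  s <- fixture_subject()
  cat_ <- fixture_catalog_short()
  for (mn in c("FE", "ERa90")) {
    ik <- solve_ik_trajectory(s$model, cat_$motions[[mn]])
    expect_true(all(ik$assembled))
    expect_lt(max(abs(ik$q - cat_$q_true[[mn]])), 1e-4)
    expect_lt(error_stats(ik)$avg, 1e-6)
    expect_true(all(ik$closure <= ik_settings()$closure_tolerance))
  }
})

test_that("constant markers give constant coordinates", {
  s <- fixture_subject()
  ms <- fixture_catalog_short()$motions$SA
  frozen <- marker_set(ms$names,
                       ms$positions[rep(5, 8), , , drop = FALSE],
                       rate = ms$rate)
  ik <- solve_ik_trajectory(s$model, frozen)
  expect_lt(max(abs(sweep(ik$q, 2, ik$q[1, ]))), 1e-6)
})

test_that("reversed trajectories give time-mirrored solutions", {
  s <- fixture_subject()
  ms <- fixture_catalog_short()$motions$CA
  nf <- dim(ms$positions)[1]
  rev_ms <- marker_set(ms$names, ms$positions[nf:1, , , drop = FALSE],
                       rate = ms$rate)
  fwd <- solve_ik_trajectory(s$model, ms)
  bwd <- solve_ik_trajectory(s$model, rev_ms,
                             q_init = fwd$q[nf, ])
  expect_lt(max(abs(bwd$q - fwd$q[nf:1, ])), 1e-6)
})

test_that("solutions are invariant to marker ordering", {
  s <- fixture_subject()
  ms <- fixture_catalog_short()$motions$WFE
  perm <- c(4, 9, 1, 11, 2, 7, 3, 10, 5, 8, 6)
  shuffled <- marker_set(ms$names[perm],
                         ms$positions[, perm, , drop = FALSE],
                         rate = ms$rate)
  a <- solve_ik_trajectory(s$model, ms)
  b <- solve_ik_trajectory(s$model, shuffled)
  expect_lt(max(abs(a$q - b$q)), 1e-8)
})

test_that("error statistics match direct arithmetic", {
  fake <- structure(list(
    distances = matrix(c(3, 4), 2, 1, dimnames = list(NULL, "M")),
    assembled = c(TRUE, TRUE)), class = "ik_result")
  st <- error_stats(fake)
  expect_equal(st$avg, 3.5)
  expect_equal(st$max, 4)
  expect_equal(unname(st$rmse), sqrt(12.5))
  zero <- structure(list(distances = matrix(0, 3, 2, dimnames =
    list(NULL, c("A", "B")))), class = "ik_result")
  expect_equal(error_stats(zero)$avg, 0)
  expect_equal(error_stats(zero)$max, 0)
  expect_error(error_stats(fake, markers = "nope"), "empty marker subset")

  # marker subsets restrict the statistics (scapula-only evaluation)
  s <- fixture_subject()
  ik <- solve_ik_trajectory(s$model, fixture_catalog_short()$motions$FE)
  sub <- error_stats(ik, markers = SCAP_MARKERS)
  expect_named(sub$rmse, SCAP_MARKERS)
})
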