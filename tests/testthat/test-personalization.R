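test_that("selectors address model scalars and reject duplicates", {
  s <- fixture_subject()
  m <- s$model
  sel <- list(select_joint_parameter("glenohumeral", "parent", "ty"),
              select_body_scale("clavicle", "x"),
              select_constraint_point(1L, "b", "z"),
              select_marker_position("scapula", "GC", "x"))
  x <- get_design(m, sel)
  expect_length(x, 4L)
  expect_equal(unname(x[1]), m$joints$glenohumeral$params$parent_translation[2])
  expect_equal(unname(x[2]), m$bodies$clavicle$scale_factors[1])
  m2 <- set_design(m, sel, x + c(5, 0.1, -2, 1))
  expect_equal(get_design(m2, sel), x + c(5, 0.1, -2, 1),
               tolerance = 1e-12)
  expect_error(get_design(m, list(select_joint_parameter("nope", "parent",
                                                         "tx"))),
               "unknown joint")
  expect_error(personalization_task(selectors = list(sel[[1]], sel[[1]])),
               "duplicate")
  expect_error(personalization_task(selectors = list()), "at least one")
})

test_that("starting at ground truth leaves the model unchanged", {
  s <- fixture_subject()
  ms <- concatenate_markers(fixture_catalog_short()$motions[c("FE", "SA")])
  task <- personalization_task(
    ms, gh_center_selectors(), name = "gh", maxiter = 5)
  res <- run_task(s$model, task)
  expect_lt(res$final_cost, 1e-10)
  expect_lt(gh_center_error(res$model, s$model), 1e-4)
  expect_lte(res$final_cost, res$initial_cost + 1e-12)
})

test_that("a single offset joint center is recovered to the line-search optimum", {
  s <- fixture_subject()
  ms <- concatenate_markers(fixture_catalog_short()$motions[c("FE", "ERa90")])
  sel <- list(select_joint_parameter("glenohumeral", "parent", "ty"))
  truth <- get_design(s$model, sel)
  start <- set_design(s$model, sel, truth + 10)
  task <- personalization_task(ms, sel, name = "1d", maxiter = 25)
  res <- run_task(start, task)
  expect_lt(abs(get_design(res$model, sel) - truth), 0.1)

  # brute-force line-search oracle over the single offset
  grid <- seq(truth - 12, truth + 12, by = 0.25)
  cost <- vapply(grid, function(v) {
    ik <- solve_ik_trajectory(set_design(s$model, sel, v), ms)
    sum(ik$marker_residuals^2)
  }, numeric(1))
  expect_lt(abs(get_design(res$model, sel) - grid[which.min(cost)]), 0.25)
  expect_lt(res$final_cost, min(cost) + 1e-6)
})

test_that("clavicle scaling rescales the attached constraint point", {
  s <- fixture_subject()
  sel <- list(select_body_scale("clavicle", "x"))
  sc0 <- get_design(s$model, sel)
  m2 <- set_design(s$model, sel, sc0 * 1.25)
  q0 <- model_q(s$model)
  end0 <- landmark_positions(s$model, q0, "clavicle")[, "clavicle_end"]
  end2 <- landmark_positions(m2, q0, "clavicle")[, "clavicle_end"]
  sc_origin <- s$model$joints$sternoclavicular$params$parent_translation
  expect_equal(sqrt(sum((end2 - sc_origin)^2)),
               1.25 * sqrt(sum((end0 - sc_origin)^2)), tolerance = 1e-9)
  # and the closure residual responds to the scale change
  expect_gt(constraint_residuals(m2, q0), 1)
})

test_that("task sequences execute in order and keep history", {
  s <- fixture_subject()
  ms <- concatenate_markers(fixture_catalog_short()$motions[c("FE", "SA")])
  sel <- gh_center_selectors()
  start <- set_design(s$model, sel, get_design(s$model, sel) + c(6, -4, 3))
  tasks <- list(
    personalization_task(ms, sel[1:2], name = "first", maxiter = 10),
    personalization_task(ms, sel, name = "second", maxiter = 15))
  res <- run_sequence(start, tasks)
  expect_length(res$history, 2L)
  expect_equal(vapply(res$history, `[[`, character(1), "name"),
               c("first", "second"))
  expect_lte(res$history[[2]]$final_cost, res$history[[1]]$final_cost)
  expect_lt(gh_center_error(res$model, s$model), 0.5)
})

test_that("final cost equals an independent recomputation", {
  s <- fixture_subject()
  ms <- fixture_catalog_short()$motions$WCA
  sel <- gh_center_selectors()
  start <- set_design(s$model, sel, get_design(s$model, sel) + c(4, 2, -5))
  res <- run_task(start, personalization_task(ms, sel, maxiter = 10))
  ik <- solve_ik_trajectory(res$model, ms)
  recomputed <- sum(ik$distances[is.finite(ik$distances)]^2)
  expect_equal(res$final_cost, recomputed,
               tolerance = 1e-6)
})

test_that("protocol builders emit the documented stage structure", {
  tasks <- shoulder_protocol(stage_rate = 20)
  expect_length(tasks, 6L)
  expect_equal(vapply(tasks, `[[`, character(1), "name"),
               c("glenohumeral", "acromioclavicular", "sternoclavicular",
                 "scapulothoracic_parent", "scapulothoracic_child",
                 "combined"))
  expect_equal(vapply(tasks[1:5], `[[`, numeric(1), "rate"), rep(20, 5))
  expect_null(tasks[[6]]$rate)
  expect_length(tasks[[6]]$selectors,
                sum(lengths(lapply(tasks[1:5], `[[`, "selectors"))))
  sc_tasks <- scapula_protocol()
  expect_length(sc_tasks, 2L)
  expect_length(sc_tasks[[1]]$selectors, 12L)
})
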