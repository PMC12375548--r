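test_that("coupler regression matches the normal-equations oracle", {
  # exactly linear synthetic relation is recovered with zero residual
  set.seed(41)
  q1 <- runif(60, -0.5, 0.5)
  q2 <- runif(60, -0.4, 0.4)
  q3 <- 92 - 18 * q1 + 7 * q2
  Q <- cbind(scap_q1 = q1, scap_q2 = q2, scap_q3 = q3)
  fit <- fit_coupler(Q)
  expect_equal(c(fit$c0, fit$c1, fit$c2), c(92, -18, 7), tolerance = 1e-9)
  expect_lt(fit$fit_error_avg_abs, 1e-10)

  # random data: coefficients equal the normal-equations solution
  q3n <- q3 + rnorm(60, sd = 2)
  fitn <- fit_coupler(cbind(scap_q1 = q1, scap_q2 = q2, scap_q3 = q3n))
  X <- cbind(1, q1, q2)
  beta <- solve(crossprod(X), crossprod(X, q3n))
  expect_lt(max(abs(c(fitn$c0, fitn$c1, fitn$c2) - beta)), 1e-10)
  expect_equal(fitn$fit_error_avg_abs, mean(abs(q3n - X %*% beta)),
               tolerance = 1e-12)

  # rank deficiency is a diagnostic error
  expect_error(fit_coupler(cbind(scap_q1 = rep(0.2, 10),
                                 scap_q2 = rep(0.1, 10),
                                 scap_q3 = rnorm(10))),
               "collinear")
  expect_error(fit_coupler(Q[1:2, ]), "three frames")
})

test_that("applying the coupler removes one independent DOF", {
  s <- fixture_subject()
  fit <- structure(list(c0 = 90, c1 = -10, c2 = 5,
                        fit_error_avg_abs = 0, n = 10,
                        coords = c("scap_q1", "scap_q2", "scap_q3")),
                   class = "coupler_fit")
  coupled <- apply_coupler(s$model, fit)
  expect_identical(independent_dof_count(coupled), 6L)
  expect_length(coordinate_names(coupled), 9L)
  # c1 = c2 = 0: translation held constant at c0
  flat <- fit; flat$c1 <- 0; flat$c2 <- 0
  mflat <- apply_coupler(s$model, flat)
  q <- stats::setNames(rep(0, 9), coordinate_names(mflat))
  pos_a <- landmark_positions(mflat, q, "scapula")
  q["scap_q4"] <- 0.3
  pos_b <- landmark_positions(mflat, q, "scapula")
  # the (now coupled) radial offset is c0 in both poses: distances from the
  # thorax-centered origin along the radial axis agree
  qfull <- stats::setNames(rep(0, 10), coordinate_names(s$model))
  qfull["scap_q3"] <- 90
  expect_equal(pos_a, landmark_positions(s$model, qfull, "scapula"))
  expect_false(isTRUE(all.equal(pos_a, pos_b)))
  # wrong topology rejected
  expect_error(apply_coupler(hinge_model(), fit), "topology")
})

test_that("coupled-model IK is exact when the data obey the linear relation", {
  s <- fixture_subject()
  open5 <- subject_scapula_model(s, 5)
  # generate scapula motion with q3 exactly linear in q1, q2
  fit <- structure(list(c0 = model_q(s$model)[["scap_q3"]], c1 = -12,
                        c2 = 6, fit_error_avg_abs = 0, n = 0,
                        coords = c("scap_q1", "scap_q2", "scap_q3")),
                   class = "coupler_fit")
  nf <- 15
  q1 <- seq(0, 0.5, length.out = nf)
  q2 <- 0.3 * sin(seq(0, pi, length.out = nf))
  Q <- cbind(q1, q2, fit$c0 + fit$c1 * q1 + fit$c2 * q2,
             0.2 * q1, -0.1 * q2)
  pos <- array(NA_real_, c(nf, 5, 3))
  for (f in seq_len(nf))
    pos[f, , ] <- t(landmark_positions(open5, Q[f, ], "scapula"))
  ms <- marker_set(SCAP_MARKERS, pos, rate = 20)
  coupled <- apply_coupler(open5, fit)
  ik <- solve_ik_trajectory(coupled, ms)
  expect_lt(error_stats(ik)$avg, 1e-6)
  # and the recovered rotations match the generating ones
  expect_lt(max(abs(ik$q[, "scap_q1"] - q1)), 1e-6)

  # fitting the generating trajectories recovers the coupler relation
  refit <- fit_coupler(cbind(scap_q1 = Q[, 1], scap_q2 = Q[, 2],
                             scap_q3 = Q[, 3]))
  expect_equal(c(refit$c0, refit$c1, refit$c2), c(fit$c0, fit$c1, fit$c2),
               tolerance = 1e-8)
})

test_that("LOOCV evaluates each omitted motion once", {
  s <- fixture_subject()
  cat_ <- fixture_catalog_short()
  sel <- gh_center_selectors()
  start <- set_design(s$model, sel, get_design(s$model, sel) + c(5, -4, 3))
  light_protocol <- function(markers) {
    list(personalization_task(markers, sel, name = "gh", maxiter = 12))
  }
  sub <- cat_$motions[c("FE", "SA", "ERa90")]
  res <- loocv(start, sub, protocol = light_protocol)
  expect_named(res$per_motion, names(sub))
  expect_true(all(res$per_motion >= 0))
  # noise-free ground-truth data: omitted-motion errors stay small
  expect_lt(max(res$per_motion), 0.5)
  expect_equal(res$overall, mean(res$per_motion))
  expect_named(res$rmse, ALL_MARKERS)
  expect_error(loocv(start, sub["FE"], protocol = light_protocol),
               "at least two")
})

test_that("identical catalog copies give omitted error equal to in-sample error", {
  s <- fixture_subject()
  ms <- fixture_catalog_short()$motions$FE
  sel <- list(select_joint_parameter("glenohumeral", "parent", "tz"))
  start <- set_design(s$model, sel, get_design(s$model, sel) + 6)
  proto <- function(markers)
    list(personalization_task(markers, sel, maxiter = 10))
  res <- loocv(start, list(a = ms, b = ms), protocol = proto)
  insample <- run_task(start, proto(ms)[[1]])
  expect_equal(unname(res$per_motion["a"]), insample$stats$avg,
               tolerance = 1e-6)
})

test_that("error reports tabulate per-motion per-marker statistics", {
  s <- fixture_subject()
  cat_ <- fixture_catalog_short()
  iks <- lapply(cat_$motions[c("FE", "SA")], function(m)
    solve_ik_trajectory(s$model, m))
  rep_ <- error_report(iks)
  expect_setequal(unique(rep_$table$marker), ALL_MARKERS)
  expect_equal(nrow(rep_$table), 2L * 11L)
  # avg / max agree with error_stats recomputation
  st <- error_stats(iks)
  expect_equal(rep_$summary$avg, st$avg, tolerance = 1e-12)
  expect_equal(rep_$summary$max, st$max, tolerance = 1e-12)
  expect_error(error_report(iks, markers = "nope"), "empty marker subset")
  dir <- withr::local_tempdir()
  write_error_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "marker_errors.tsv")))
  tab <- read.delim(file.path(dir, "marker_errors.tsv"))
  expect_equal(nrow(tab), 22L)
})
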