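#' Leave-one-out cross-validation over a motion catalog
#'
#' For each motion in the catalog, personalizes the starting model on the
#' concatenation of all remaining motions, then evaluates average marker
#' distance error on the held-out motion by inverse kinematics.  The overall
#' score is the mean across omitted motions; per-marker RMSE is pooled over
#' all omitted-motion frames.
#'
#' @param model starting (e.g. perturbed) `kinematic_model`.
#' @param catalog a [make_catalog()] result or a named list of
#'   [marker_set()] objects (at least two motions).
#' @param protocol function `(markers) -> list of tasks` building the
#'   personalization protocol for one fold (e.g. [shoulder_protocol()]).
#' @param settings [ik_settings()] used for held-out evaluation.
#' @param markers optional character vector restricting error statistics to
#'   a marker subset.
#' @return An object of class `loocv_result`: list with `per_motion` (named
#'   avg errors, mm), `overall` (mean across folds, mm), `rmse` (named
#'   per-marker RMSE over all held-out frames, mm), `folds` (per-fold
#'   details).
#' @export
loocv <- function(model, catalog, protocol = shoulder_protocol,
                  settings = ik_settings(), markers = NULL) {
  motions <- if (inherits(catalog, "motion_catalog")) catalog$motions
             else catalog
  if (length(motions) < 2) stop("LOOCV needs at least two motions")
  per_motion <- numeric(0)
  folds <- list()
  held_ik <- list()
  for (mn in names(motions)) {
    train <- concatenate_markers(motions[names(motions) != mn])
    fold <- tryCatch({
      res <- run_sequence(model, protocol(train))
      ik <- solve_ik_trajectory(res$model, motions[[mn]],
                                settings = settings)
      st <- error_stats(ik, markers = markers)
      held_ik[[mn]] <- ik
      list(motion = mn, avg = st$avg, max = st$max, rmse = st$rmse,
           final_cost = res$final_cost, error = NULL)
    }, error = function(e) list(motion = mn, avg = NA_real_,
                                max = NA_real_, rmse = NULL,
                                final_cost = NA_real_,
                                error = conditionMessage(e)))
    per_motion[mn] <- fold$avg
    folds[[mn]] <- fold
  }
  rmse <- if (length(held_ik)) error_stats(held_ik, markers = markers)$rmse
          else NULL
  structure(list(per_motion = per_motion,
                 overall = mean(per_motion, na.rm = TRUE), rmse = rmse,
                 folds = folds),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("loocv_result over", length(x$per_motion), "motions\n")
  print(round(x$per_motion, 3))
  cat("overall average omitted-motion error:", format(x$overall, digits = 4),
      "mm\n")
  invisible(x)
}

#' Fit a linear coordinate coupler for the scapular translation
#'
#' Ordinary least squares of the scapular radial translation on the two
#' thorax-centered scapular rotations, pooled over all frames of all
#' supplied trajectories with equal weight:
#' `q3 ~ c0 + c1 q1 + c2 q2`.
#'
#' @param results an `ik_result`, a list of them, or a numeric matrix of
#'   generalized coordinates with named columns.
#' @param coords length-3 character: names of the two rotation coordinates
#'   and the translation coordinate, in order (q1, q2, q3).
#' @return An object of class `coupler_fit`: coefficients `c0` (mm),
#'   `c1`, `c2` (mm/rad), `fit_error_avg_abs` (mean absolute residual, mm)
#'   and the frame count `n`.
#' @export
fit_coupler <- function(results,
                        coords = c("scap_q1", "scap_q2", "scap_q3")) {
  Q <- if (is.matrix(results)) results
       else if (inherits(results, "ik_result")) results$q
       else do.call(rbind, lapply(results, `[[`, "q"))
  if (!all(coords %in% colnames(Q)))
    stop("coordinates ", paste(setdiff(coords, colnames(Q)), collapse = ", "),
         " not present in results")
  if (nrow(Q) < 3) stop("at least three frames are required")
  d <- data.frame(q1 = Q[, coords[1]], q2 = Q[, coords[2]],
                  q3 = Q[, coords[3]])
  X <- cbind(1, d$q1, d$q2)
  if (qr(X)$rank < 3)
    stop("rank-deficient regression: q1 and q2 are collinear across frames")
  fit <- stats::lm(q3 ~ q1 + q2, data = d)
  co <- unname(stats::coef(fit))
  structure(list(c0 = co[1], c1 = co[2], c2 = co[3],
                 fit_error_avg_abs = mean(abs(stats::residuals(fit))),
                 n = nrow(d), coords = coords),
            class = "coupler_fit")
}

#' @export
print.coupler_fit <- function(x, ...) {
  cat(sprintf(
    "coupler_fit: %s = %.4g %+.4g %s %+.4g %s  (avg |resid| %.4g mm, n=%d)\n",
    x$coords[3], x$c0, x$c1, x$coords[1], x$c2, x$coords[2],
    x$fit_error_avg_abs, x$n))
  invisible(x)
}

#' Apply a coordinate coupler, eliminating the scapular translation DOF
#'
#' Replaces the scapular radial translation coordinate by the affine
#' function of the two thorax-centered rotations given by a [fit_coupler()]
#' result.  The translation is no longer an independent coordinate: it is
#' evaluated as `c0 + c1 q1 + c2 q2` inside forward kinematics, and the
#' independent DOF count drops by one (7 to 6 for the closed-chain model).
#'
#' @param model a `kinematic_model` whose scapulothoracic joint carries the
#'   coordinates named in `fit$coords`.
#' @param fit a [coupler_fit()].
#' @return the coupled `kinematic_model`.
#' @export
apply_coupler <- function(model, fit) {
  stopifnot(inherits(fit, "coupler_fit"))
  coords <- fit$coords
  jname <- NULL
  for (jn in names(model$joints)) {
    cn <- vapply(model$joints[[jn]]$coordinates, `[[`, character(1), "name")
    if (coords[3] %in% cn) jname <- jn
  }
  if (is.null(jname) ||
      !all(coords[1:2] %in% coordinate_names(model)))
    stop("model topology does not carry the coupler coordinates (",
         paste(coords, collapse = ", "), ")")
  j <- model$joints[[jname]]
  cn <- vapply(j$coordinates, `[[`, character(1), "name")
  j$coordinates <- j$coordinates[cn != coords[3]]
  j$motions <- lapply(j$motions, function(mo) {
    if (!is.null(mo$coord) && mo$coord == coords[3]) {
      terms <- c(fit$c1, fit$c2)
      names(terms) <- coords[1:2]
      joint_motion(mo$type, mo$axis,
                   coeffs = list(constant = fit$c0, terms = terms))
    } else mo
  })
  model$joints[[jname]] <- j
  # re-validate through the constructor
  kinematic_model(model$bodies, model$joints, model$constraints)
}

#' Per-motion, per-marker error report
#'
#' @param results named list of `ik_result` objects, one per motion.
#' @param markers optional marker subset.
#' @return list with `table` (long data.frame: motion, marker, avg, max,
#'   rmse in mm — the per-motion marker-error layout), `distances` (long
#'   data.frame of all per-frame distances, box-plot ready) and `summary`
#'   (overall avg / max).
#' @export
error_report <- function(results, markers = NULL) {
  if (length(results) == 0) stop("no results to report")
  if (inherits(results, "ik_result")) results <- list(all = results)
  rows <- list()
  dists <- list()
  for (mn in names(results)) {
    d <- results[[mn]]$distances
    if (!is.null(markers)) {
      keep <- intersect(markers, colnames(d))
      if (length(keep) == 0) stop("empty marker subset")
      d <- d[, keep, drop = FALSE]
    }
    for (mk in colnames(d)) {
      v <- d[, mk][is.finite(d[, mk])]
      rows[[paste(mn, mk)]] <- data.frame(
        motion = mn, marker = mk, avg = mean(v), max = max(v),
        rmse = sqrt(mean(v^2)), stringsAsFactors = FALSE)
    }
    dists[[mn]] <- data.frame(
      motion = mn,
      marker = rep(colnames(d), each = nrow(d)),
      distance = as.vector(d), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  all_d <- do.call(rbind, dists)
  list(table = tab,
       distances = all_d[is.finite(all_d$distance), ],
       summary = data.frame(avg = mean(all_d$distance, na.rm = TRUE),
                            max = max(all_d$distance, na.rm = TRUE)))
}

#' Write an error report as delimited text
#' @param report an [error_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_error_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$table, file.path(dir, "marker_errors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Box plot of marker distance errors by motion
#'
#' @param report an [error_report()] result.
#' @return a `ggplot` object (requires the ggplot2 package).
#' @export
plot_marker_errors <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_marker_errors requires the ggplot2 package")
  ggplot2::ggplot(report$distances,
                  ggplot2::aes(x = .data$motion, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "marker distance error (mm)") +
    ggplot2::theme_minimal()
}
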