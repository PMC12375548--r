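#' Marker trajectory set
#'
#' Timestamped 3-D marker positions at a uniform sampling rate, the in-memory
#' equivalent of a TRC file.
#'
#' @param names ordered character vector of marker names.
#' @param positions numeric array `frames x markers x 3` (mm).
#' @param rate sampling rate (Hz).
#' @param times optional time stamps (s); regenerated from `rate` when
#'   omitted.
#' @param units units label (only `"mm"` supported).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(names, positions, rate, times = NULL, units = "mm") {
  names <- as.character(names)
  if (length(names) == 0) stop("marker set must contain at least one marker")
  if (anyDuplicated(names)) stop("marker names must be unique")
  positions <- unname(positions)
  if (length(dim(positions)) != 3L || dim(positions)[2] != length(names) ||
      dim(positions)[3] != 3L)
    stop("positions must be a frames x markers x 3 array")
  if (units != "mm") stop("only mm units are supported")
  nf <- dim(positions)[1]
  if (nf < 1L) stop("marker set must contain at least one frame")
  if (is.null(times)) times <- (seq_len(nf) - 1) / rate
  if (length(times) != nf || nf > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing with one value per frame")
  structure(list(names = names, times = as.numeric(times),
                 positions = positions, rate = as.numeric(rate),
                 units = units),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", length(x$names), "markers,", dim(x$positions)[1],
      "frames at", x$rate, "Hz (", x$units, ")\n")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(x) dim(x$positions)[1]

#' Extract one frame of a marker set
#' @param x a `marker_set`.
#' @param frame frame index.
#' @return 3 x markers matrix with marker names as columns.
#' @export
marker_frame <- function(x, frame) {
  m <- t(x$positions[frame, , , drop = TRUE])
  if (length(x$names) == 1L) m <- matrix(x$positions[frame, 1, ], 3, 1)
  colnames(m) <- x$names
  m
}

#' 6-DOF pose trajectory of one body
#'
#' Per-frame unit quaternions (scalar-first) and translations expressed in
#' the torso frame, sampled uniformly.
#'
#' @param body body name.
#' @param quaternions `frames x 4` matrix of unit quaternions (normalized on
#'   construction; norms must be within 1e-6 of 1).
#' @param translations `frames x 3` matrix (mm).
#' @param rate sampling rate (Hz).
#' @param times optional time stamps (s).
#' @return An object of class `pose_trajectory`.
#' @export
pose_trajectory <- function(body, quaternions, translations, rate,
                            times = NULL) {
  quaternions <- as.matrix(quaternions)
  translations <- as.matrix(translations)
  if (ncol(quaternions) != 4L || ncol(translations) != 3L ||
      nrow(quaternions) != nrow(translations))
    stop("quaternions must be frames x 4 and translations frames x 3")
  norms <- sqrt(rowSums(quaternions^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("quaternions must have unit norm")
  quaternions <- quaternions / norms
  nf <- nrow(quaternions)
  if (is.null(times)) times <- (seq_len(nf) - 1) / rate
  structure(list(body = body, quaternions = quaternions,
                 translations = translations, rate = as.numeric(rate),
                 times = as.numeric(times)),
            class = "pose_trajectory")
}

#' Synthesize gold-standard markers from 6-DOF pose trajectories
#'
#' Places each body at its measured pose at every frame and records the
#' ground-frame (torso-frame) position of each anatomical landmark as a
#' synthetic marker.  Static torso landmarks are appended as
#' time-independent markers.  The standard shoulder set yields 11 markers in
#' the fixed order GC, IA, TS, PLA, AC (scapula), HHC, LE, ME (humerus),
#' IJ, C7, T8 (torso).
#'
#' @param poses list of [pose_trajectory()] objects (scapula and humerus);
#'   all must share a common time base.
#' @param landmark_tables named list (by body) of 3 x n landmark matrices in
#'   local frames (mm).
#' @param static_torso_landmarks 3 x n matrix of torso landmarks (mm, torso
#'   frame), constant across frames.
#' @return a [marker_set()].
#' @export
synthesize_markers <- function(poses, landmark_tables,
                               static_torso_landmarks) {
  if (length(poses) == 0) stop("at least one pose trajectory is required")
  t0 <- poses[[1]]$times
  rate <- poses[[1]]$rate
  for (p in poses) {
    if (length(p$times) != length(t0) || max(abs(p$times - t0)) > 1e-9 ||
        p$rate != rate)
      stop("pose trajectories do not share a common time base")
  }
  nf <- length(t0)
  marker_names <- character(0)
  blocks <- list()
  for (p in poses) {
    lm <- landmark_tables[[p$body]]
    if (is.null(lm)) stop("no landmark table for body '", p$body, "'")
    nmk <- ncol(lm)
    block <- array(NA_real_, c(nf, nmk, 3))
    for (f in seq_len(nf)) {
      R <- quat_to_rotation(p$quaternions[f, ])
      block[f, , ] <- t(R %*% lm + p$translations[f, ])
    }
    marker_names <- c(marker_names, colnames(lm))
    blocks <- c(blocks, list(block))
  }
  tor <- as.matrix(static_torso_landmarks)
  tor_block <- array(NA_real_, c(nf, ncol(tor), 3))
  for (f in seq_len(nf)) tor_block[f, , ] <- t(tor)
  marker_names <- c(marker_names, colnames(tor))
  blocks <- c(blocks, list(tor_block))
  positions <- array(NA_real_, c(nf, length(marker_names), 3))
  k <- 0L
  for (b in blocks) {
    positions[, k + seq_len(dim(b)[2]), ] <- b
    k <- k + dim(b)[2]
  }
  marker_set(marker_names, positions, rate, times = t0)
}

#' Read a TRC marker trajectory file
#'
#' Supports the standard tab-delimited TRC dialect: a `PathFileType` line,
#' a header key line (`DataRate  CameraRate  NumFrames  NumMarkers  Units
#' ...`), the header value line, a marker-name line, a coordinate-label
#' line, and per-frame rows of `Frame#  Time  X1 Y1 Z1 ...`.  The time
#' column is regenerated from the data rate rather than trusted from the
#' file.
#'
#' @param path file path.
#' @return a [marker_set()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("TRC parse error: file has fewer than 6 lines")
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% keys))
    stop("TRC parse error at line 2: missing header fields ",
         paste(setdiff(need, keys), collapse = ", "))
  hv <- stats::setNames(vals[seq_along(keys)], keys)
  rate <- as.numeric(hv["DataRate"])
  nfr <- as.integer(hv["NumFrames"])
  nmk <- as.integer(hv["NumMarkers"])
  units <- hv[["Units"]]
  name_fields <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  mnames <- name_fields[-(1:2)]
  mnames <- mnames[mnames != ""]
  if (length(mnames) != nmk)
    stop("TRC parse error at line 4: found ", length(mnames),
         " marker names but NumMarkers=", nmk)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nfr)
    stop("TRC parse error: expected ", nfr, " data rows, found ",
         length(data_lines))
  positions <- array(NA_real_, c(nfr, nmk, 3))
  for (i in seq_len(nfr)) {
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2 + 3 * nmk)
      stop("TRC parse error at line ", i + 5, ": expected ", 2 + 3 * nmk,
           " columns, found ", length(fields))
    xyz <- suppressWarnings(as.numeric(fields[3:(2 + 3 * nmk)]))
    positions[i, , ] <- matrix(xyz, nmk, 3, byrow = TRUE)
  }
  marker_set(mnames, positions, rate, units = units)
}

#' Write a TRC marker trajectory file
#' @param x a [marker_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(x, path) {
  stopifnot(inherits(x, "marker_set"))
  nfr <- n_frames(x)
  nmk <- length(x$names)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(x$rate, x$rate, nfr, nmk, x$units, x$rate, 1, nfr, sep = "\t"),
    paste(c("Frame#", "Time",
            as.vector(rbind(x$names, "", ""))), collapse = "\t"),
    paste(c("", "", as.vector(vapply(seq_len(nmk), function(i)
      paste0(c("X", "Y", "Z"), i), character(3)))), collapse = "\t")),
    con)
  times <- (seq_len(nfr) - 1) / x$rate
  for (f in seq_len(nfr)) {
    xyz <- as.vector(t(x$positions[f, , , drop = FALSE][1, , ]))
    writeLines(paste(c(f, format(times[f], nsmall = 5, trim = TRUE),
                       format(xyz, digits = 10, trim = TRUE,
                              scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Concatenate marker trajectory sets
#'
#' Appends frames in order and re-indexes time to remain uniform and
#' strictly increasing from zero.
#'
#' @param motions list of [marker_set()] objects sharing marker names and
#'   rate.
#' @return a single [marker_set()].
#' @export
concatenate_markers <- function(motions) {
  if (length(motions) == 0) stop("no marker sets to concatenate")
  ref <- motions[[1]]
  for (m in motions) {
    if (!identical(m$names, ref$names) || m$rate != ref$rate)
      stop("marker sets differ in names or rate")
  }
  positions <- do.call(abind3, lapply(motions, `[[`, "positions"))
  marker_set(ref$names, positions, ref$rate)
}

abind3 <- function(...) {
  parts <- list(...)
  nf <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(NA_real_, c(nf, dim(parts[[1]])[2], 3))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Downsample a marker set by decimation
#'
#' Keeps every `source_rate / target_rate`-th frame starting at frame 1;
#' the target rate must divide the source rate.
#'
#' @param x a [marker_set()].
#' @param target_rate target sampling rate (Hz).
#' @return the decimated [marker_set()].
#' @export
downsample_markers <- function(x, target_rate) {
  step <- x$rate / target_rate
  if (abs(step - round(step)) > 1e-9)
    stop("target rate ", target_rate, " Hz does not divide source rate ",
         x$rate, " Hz")
  step <- as.integer(round(step))
  keep <- seq(1L, n_frames(x), by = step)
  marker_set(x$names, x$positions[keep, , , drop = FALSE], target_rate)
}

#' Sinusoidal skin-marker noise specification
#'
#' Continuous soft-tissue-artifact-like noise: for every marker coordinate
#' one amplitude, frequency, and phase are drawn uniformly from the given
#' ranges, and `A * sin(2 pi f t + phi)` is added over the whole trajectory.
#' Defaults follow the skin-marker simulation ranges: amplitude
#' -6.5 to 6.5 mm, frequency 0 to 6 Hz, phase 0 to 2 pi rad.
#'
#' @param amplitude_range,frequency_range,phase_range length-2 numeric
#'   ranges (mm, Hz, rad).
#' @param seed integer RNG seed making the draw reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(amplitude_range = c(-6.5, 6.5),
                       frequency_range = c(0, 6),
                       phase_range = c(0, 2 * pi), seed = 0L) {
  chk <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!chk(amplitude_range) || !chk(frequency_range) || !chk(phase_range))
    stop("ranges must be valid intervals")
  structure(list(amplitude_range = as.numeric(amplitude_range),
                 frequency_range = as.numeric(frequency_range),
                 phase_range = as.numeric(phase_range),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add sinusoidal noise to a marker set
#'
#' For each marker coordinate independently, draws amplitude, frequency and
#' phase once per call (i.e. once per motion file) and adds
#' `A * sin(2 pi f t + phi)` to that coordinate at every frame.
#' Reproducible under the spec's fixed seed; the RNG is restored afterwards.
#'
#' @param x a [marker_set()].
#' @param spec a [noise_spec()].
#' @return the noisy [marker_set()].
#' @export
add_sinusoidal_noise <- function(x, spec = noise_spec()) {
  stopifnot(inherits(x, "marker_set"), inherits(spec, "noise_spec"))
  nmk <- length(x$names)
  pos <- x$positions
  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  draws <- withr_seed(spec$seed, function() {
    list(A = matrix(stats::runif(nmk * 3, spec$amplitude_range[1],
                                 spec$amplitude_range[2]), nmk, 3),
         f = matrix(stats::runif(nmk * 3, spec$frequency_range[1],
                                 spec$frequency_range[2]), nmk, 3),
         phi = matrix(stats::runif(nmk * 3, spec$phase_range[1],
                                   spec$phase_range[2]), nmk, 3))
  })
  for (m in seq_len(nmk)) {
    for (d in 1:3) {
      pos[, m, d] <- pos[, m, d] +
        draws$A[m, d] * sin(2 * pi * draws$f[m, d] * x$times +
                              draws$phi[m, d])
    }
  }
  marker_set(x$names, pos, x$rate, times = x$times)
}
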