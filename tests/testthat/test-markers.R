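test_that("marker synthesis places 11 markers and honors poses", {
  s <- fixture_subject()
  nf <- 5
  ident <- function(body) pose_trajectory(
    body, matrix(rep(c(1, 0, 0, 0), nf), nf, 4, byrow = TRUE),
    matrix(0, nf, 3), rate = 100)
  ms <- synthesize_markers(list(ident("scapula"), ident("humerus")),
                           s$landmarks[c("scapula", "humerus")],
                           s$landmarks$torso)
  expect_equal(ms$names, ALL_MARKERS)
  expect_length(ms$names, 11L)
  # identity poses: positions equal local landmark coordinates, constant
  expect_equal(marker_frame(ms, 1)[, "GC"],
               unname(s$landmarks$scapula[, "GC"]))
  expect_equal(ms$positions[1, , ], ms$positions[nf, , ])
  # torso markers constant by construction
  expect_equal(marker_frame(ms, 3)[, "C7"],
               unname(s$landmarks$torso[, "C7"]))

  # random unit quaternion pose matches the rotation-matrix oracle
  set.seed(23)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  tr <- runif(3, -50, 50)
  one <- function(body) pose_trajectory(body, matrix(q, 1), matrix(tr, 1),
                                        rate = 100)
  ms2 <- synthesize_markers(list(one("scapula"), one("humerus")),
                            s$landmarks[c("scapula", "humerus")],
                            s$landmarks$torso)
  expect_equal(marker_frame(ms2, 1)[, "IA"],
               as.numeric(quat_to_rotation(q) %*%
                            s$landmarks$scapula[, "IA"] + tr),
               tolerance = 1e-9)

  # mismatched time bases are rejected
  slow <- pose_trajectory("humerus", matrix(c(1, 0, 0, 0), 1), matrix(0, 1, 3),
                          rate = 50)
  expect_error(synthesize_markers(list(ident("scapula"), slow),
                                  s$landmarks, s$landmarks$torso),
               "common time base")
})

test_that("TRC files round-trip and carry the standard header", {
  one <- marker_set("M1", array(c(1, 2, 3), c(1, 1, 3)), rate = 100)
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(one, path)
  lines <- readLines(path)
  expect_match(lines[2], "DataRate\tCameraRate\tNumFrames\tNumMarkers")
  # one marker, one frame: data row has frame, time, x, y, z
  expect_length(strsplit(lines[6], "\t")[[1]], 5L)
  back <- read_trc(path)
  expect_equal(back$positions, one$positions, tolerance = 1e-5)

  ms <- fixture_catalog_short()$motions$FE
  write_trc(ms, path)
  hdr <- strsplit(readLines(path, n = 3)[3], "\t")[[1]]
  expect_equal(as.numeric(hdr[1]), 20)      # DataRate
  expect_equal(as.integer(hdr[4]), 11L)     # NumMarkers
  back <- read_trc(path)
  expect_equal(back$names, ms$names)
  expect_equal(back$times, ms$times, tolerance = 1e-9)
  expect_lt(max(abs(back$positions - ms$positions)), 1e-5)

  expect_error(marker_set(character(0), array(0, c(1, 0, 3)), 100))
})

test_that("TRC parse errors report line numbers", {
  path <- withr::local_tempfile(fileext = ".trc")
  writeLines(c("PathFileType\t4\t(X/Y/Z)\tx.trc",
               "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits",
               "100\t100\t1\t2\tmm",
               "Frame#\tTime\tA\t\t\t",
               "\t\tX1\tY1\tZ1",
               "1\t0.0\t1\t2\t3"), path)
  expect_error(read_trc(path), "line 4")
  writeLines(c("PathFileType\t4\t(X/Y/Z)\tx.trc",
               "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits",
               "100\t100\t1\t1\tmm",
               "Frame#\tTime\tA\t\t\t",
               "\t\tX1\tY1\tZ1",
               "1\t0.0\t1\t2"), path)
  expect_error(read_trc(path), "line 6")
})

test_that("concatenation appends frames and re-indexes time", {
  cat_ <- fixture_catalog_short()
  a <- cat_$motions$FE
  b <- cat_$motions$SA
  one <- concatenate_markers(list(a))
  expect_equal(one$positions, a$positions)
  expect_equal(one$times[1], 0)
  ab <- concatenate_markers(list(a, b))
  expect_equal(dim(ab$positions)[1], n_a <- dim(a$positions)[1] +
                 dim(b$positions)[1])
  expect_equal(diff(ab$times), rep(1 / a$rate, n_a - 1), tolerance = 1e-12)
  all8 <- concatenate_markers(cat_$motions)
  expect_equal(dim(all8$positions)[1],
               sum(vapply(cat_$motions, function(m) dim(m$positions)[1],
                          integer(1))))
  bad <- marker_set(c("X"), array(0, c(2, 1, 3)), rate = a$rate)
  expect_error(concatenate_markers(list(a, bad)), "names or rate")
})

test_that("downsampling decimates from frame one", {
  ms <- fixture_markers_short <- fixture_catalog_short()$motions$FE
  same <- downsample_markers(ms, ms$rate)
  expect_equal(same$positions, ms$positions)
  half <- downsample_markers(ms, ms$rate / 2)
  expect_equal(half$positions[1, , ], ms$positions[1, , ])
  expect_equal(half$positions[2, , ], ms$positions[3, , ])
  expect_equal(half$rate, ms$rate / 2)
  expect_error(downsample_markers(ms, 7), "does not divide")

  big <- marker_set("M", array(rnorm(3000), c(1000, 1, 3)), rate = 100)
  expect_equal(dim(downsample_markers(big, 20)$positions)[1], 200L)
})

test_that("sinusoidal noise follows its closed-form statistics", {
  ms <- fixture_catalog_short()$motions$FE
  silent <- add_sinusoidal_noise(ms, noise_spec(amplitude_range = c(0, 0)))
  expect_equal(silent$positions, ms$positions)

  # A = 6.5 mm, f = 1 Hz, phi = 0 at t = 0.25 s adds exactly 6.5 mm
  flat <- marker_set("M", array(0, c(26, 1, 3)), rate = 100)
  spiked <- add_sinusoidal_noise(flat, noise_spec(c(6.5, 6.5), c(1, 1),
                                                  c(0, 0)))
  expect_equal(spiked$positions[26, 1, 1], 6.5 * sin(2 * pi * 0.25),
               tolerance = 1e-12)

  # with the default ranges, pooled per-coordinate RMS approaches
  # sqrt(E[A^2] / 2) = 6.5 / sqrt(6)
  zero <- marker_set(ALL_MARKERS, array(0, c(1e4, 11, 3)), rate = 100)
  ss <- 0
  for (seed in 0:9) {
    noisy <- add_sinusoidal_noise(zero, noise_spec(seed = seed))
    ss <- ss + mean(noisy$positions^2)
  }
  rms <- sqrt(ss / 10)
  expect_lt(abs(rms - 6.5 / sqrt(6)) / (6.5 / sqrt(6)), 0.05)

  # frame count, rate, names preserved; zero-mean over integer periods
  noisy <- add_sinusoidal_noise(ms, noise_spec(seed = 4))
  expect_identical(noisy$names, ms$names)
  expect_identical(dim(noisy$positions), dim(ms$positions))
  expect_identical(noisy$rate, ms$rate)
  whole <- marker_set("M", array(0, c(401, 1, 3)), rate = 100)
  per <- add_sinusoidal_noise(whole, noise_spec(c(-6.5, 6.5), c(1, 1),
                                                c(0, 2 * pi), seed = 2))
  # 4 whole periods (omit the duplicated endpoint frame)
  expect_lt(abs(mean(per$positions[1:400, 1, 1])), 1e-12)

  # reproducible under a fixed seed
  n1 <- add_sinusoidal_noise(ms, noise_spec(seed = 11))
  n2 <- add_sinusoidal_noise(ms, noise_spec(seed = 11))
  expect_identical(n1$positions, n2$positions)
})
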