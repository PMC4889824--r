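test_that("recordings validate their invariants", {
  x <- cbind(a = 1:10 / 10, b = 10:1 / 10)
  rec <- semg_recording(x, 16, data.frame(start = 0, end = 8, label = "HC"))
  expect_s3_class(rec, "semg_recording")
  expect_identical(rec$channels, c("a", "b"))

  expect_error(semg_recording(x, 0), "positive")
  expect_error(
    semg_recording(x, 16, data.frame(start = 0, end = 11, label = "HC")),
    "start < end"
  )
  expect_error(
    semg_recording(x, 16, data.frame(start = c(0, 4), end = c(8, 10),
                                     label = c("HC", "HO"))),
    "overlap"
  )
  expect_error(
    semg_recording(x, 16, data.frame(start = 0, end = 8, label = "JUMP")),
    "JUMP"
  )
})

test_that("recording I/O round-trips losslessly at declared precision", {
  rec <- generate_recording(generator_config(reps_per_gesture = 2, rng_seed = 3))
  sig <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, sig, meta)
  back <- read_recording(sig, meta)

  expect_identical(back$channels, rec$channels)
  expect_equal(back$sampling_rate_hz, rec$sampling_rate_hz)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$annotations, rec$annotations)

  # 160 rows at 16 Hz is a 10 s recording
  expect_equal(nrow(rec$samples) / rec$sampling_rate_hz,
               nrow(rec$samples) / 16)
})

test_that("empty-annotation recordings survive the round trip", {
  x <- cbind(ch1 = abs(sin(1:40)), ch2 = abs(cos(1:40)))
  rec <- semg_recording(x, 16)
  sig <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, sig, meta)
  back <- read_recording(sig, meta)
  expect_equal(nrow(back$annotations), 0L)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
})

test_that("non-finite samples are rejected before writing", {
  x <- cbind(ch1 = c(1, NaN, 3), ch2 = c(1, 2, 3))
  rec <- semg_recording(x, 16)
  expect_error(write_recording(rec, tempfile(), tempfile()), "non-finite")
})

test_that("malformed signal files are rejected", {
  sig <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  writeLines(c("a,b", "1,2", "3"), sig)
  jsonlite::write_json(list(sampling_rate_hz = 16), meta, auto_unbox = TRUE)
  expect_error(read_recording(sig, meta), "malformed")

  writeLines(c("a,b", "1,2", "3,x"), sig)
  expect_error(read_recording(sig, meta), "malformed")
})

test_that("a leading time column is ignored on read", {
  sig <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  writeLines(c("time,a,b", "0.0,1,2", "0.0625,3,4", "0.125,5,6"), sig)
  jsonlite::write_json(list(sampling_rate_hz = 16), meta, auto_unbox = TRUE)
  rec <- read_recording(sig, meta)
  expect_identical(rec$channels, c("a", "b"))
  expect_equal(unname(rec$samples[, "a"]), c(1, 3, 5))
})

test_that("window length and count follow the sampling arithmetic", {
  # 187.5 ms at 16 Hz is exactly 3 samples
  x <- cbind(ch1 = as.numeric(1:10), ch2 = as.numeric(101:110))
  rec <- semg_recording(x, 16, data.frame(start = 0, end = 10, label = "WF"))
  segs <- sliding_segments(rec, 187.5)
  expect_length(segs, 3L)   # floor(10 / 3), trailing sample discarded
  expect_true(all(vapply(segs, function(s) nrow(s$window), integer(1)) == 3L))

  # partition prefix: concatenated windows reproduce the leading samples
  recon <- do.call(rbind, lapply(segs, `[[`, "window"))
  expect_identical(recon, x[1:9, ])

  # recording shorter than one window: empty list, not an error
  short <- semg_recording(x[1:2, ], 16)
  expect_identical(sliding_segments(short, 187.5), list())

  # windows below 3 samples are a configuration error
  expect_error(sliding_segments(rec, 100), "at least 3")
})

test_that("majority labelling prefers the dominant annotation and REST otherwise", {
  x <- cbind(ch1 = as.numeric(1:12))
  # annotation covers samples [0, 4): window 1 (0..2) inside, window 2 (3..5)
  # has 1 annotated + 2 rest samples, windows 3-4 are rest
  rec <- semg_recording(x, 16, data.frame(start = 0, end = 4, label = "HC"))
  labs <- vapply(sliding_segments(rec, 187.5, "majority"), `[[`, character(1), "label")
  expect_identical(labs, c("HC", "REST", "REST", "REST"))

  # gesture wins a tie against REST: annotation [0, 5) gives window 2 (3..5)
  # 2 annotated vs 1 rest; annotation [0, 4) would tie 1-2 -> REST above
  rec2 <- semg_recording(x, 16, data.frame(start = 0, end = 5, label = "HC"))
  labs2 <- vapply(sliding_segments(rec2, 187.5, "majority"), `[[`, character(1), "label")
  expect_identical(labs2[2], "HC")

  # the dominant annotation wins a mixed window
  rec3 <- semg_recording(
    x, 16,
    data.frame(start = c(0, 4), end = c(4, 8), label = c("HO", "WF"))
  )
  # window 2 covers samples 3..5: 1 sample of HO, 2 of WF -> WF
  labs3 <- vapply(sliding_segments(rec3, 187.5, "majority"), `[[`, character(1), "label")
  expect_identical(labs3, c("HO", "WF", "WF", "REST"))

  # a 1-1 tie between two gestures goes to the earlier-starting annotation
  rec4 <- semg_recording(
    x, 16,
    data.frame(start = c(0, 4), end = c(4, 5), label = c("HO", "WF"))
  )
  labs4 <- vapply(sliding_segments(rec4, 187.5, "majority"), `[[`, character(1), "label")
  expect_identical(labs4[2], "HO")
})

test_that("strict labelling drops mixed windows", {
  x <- cbind(ch1 = as.numeric(1:12))
  rec <- semg_recording(x, 16, data.frame(start = 0, end = 4, label = "HC"))
  segs <- sliding_segments(rec, 187.5, "strict")
  labs <- vapply(segs, `[[`, character(1), "label")
  # window 2 straddles the boundary and is dropped
  expect_identical(labs, c("HC", "REST", "REST"))
  starts <- vapply(segs, `[[`, integer(1), "start")
  expect_identical(starts, c(0L, 6L, 9L))
})

test_that("segment count equals floor(N_total / N) for covered recordings", {
  rec <- tiny_recording()
  for (w in c(187.5, 250)) {
    n <- round(w / 1000 * rec$sampling_rate_hz)
    segs <- sliding_segments(rec, w, "majority")
    expect_length(segs, nrow(rec$samples) %/% n)
  }
})
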