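test_that("a constructed DAM file parses into the right matrix", {
  counts <- matrix(0L, 2, 32)
  counts[2, 3] <- 5L
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam_fixture(counts, path)
  m <- read_dam_file(path)
  expect_s3_class(m, "activity_matrix")
  expect_identical(dim(m), c(2L, 32L))
  expect_identical(m$counts[2, 3], 5L)
  expect_identical(sum(m$counts), 5L)
})

test_that("malformed rows and bad counts raise informative errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  row41 <- paste(c("1", "1 Jun 19", "08:00:00", "1", rep("0", 5),
                   rep("0", 32)), collapse = "\t")
  writeLines(row41, path)
  expect_error(read_dam_file(path), "malformed.*line 1")

  good <- paste(c("1", "1 Jun 19", "08:00:00", "1", rep("0", 6),
                  rep("0", 32)), collapse = "\t")
  bad <- paste(c("2", "1 Jun 19", "08:01:00", "1", rep("0", 6),
                 "x", rep("0", 31)), collapse = "\t")
  writeLines(c(good, bad), path)
  expect_error(read_dam_file(path), "non-integer count")

  # reversed timestamps
  r1 <- sub("08:00:00", "08:05:00", good)
  writeLines(c(r1, sub("08:01:00", "08:00:00", bad)), path)
  expect_error(read_dam_file(path), "non-monotonic|non-integer")
})

test_that("write then read round-trips counts, timestamps and status", {
  set.seed(42)
  for (i in 1:20) {
    m <- random_activity_matrix(n_minutes = sample(10:200, 1))
    path <- withr::local_tempfile(fileext = ".txt")
    write_dam_file(m, path)
    m2 <- read_dam_file(path)
    expect_identical(m2$counts, m$counts)
    expect_equal(as.numeric(m2$timestamps), as.numeric(m$timestamps))
    expect_identical(m2$status, m$status)
    expect_identical(m2$device, m$device)
  }
})

test_that("an empty matrix writes an empty file that reads back empty", {
  m <- activity_matrix(timestamps = as.POSIXct(character(0), tz = "UTC"),
                       counts = matrix(integer(0), 0, 32))
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam_file(m, path)
  expect_identical(nrow(read_dam_file(path)$counts), 0L)
})

test_that("one all-zero minute writes a 42-field line with 32 zero counts", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam_fixture(matrix(0L, 1, 32), path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_length(fields, 42)
  expect_true(all(fields[11:42] == "0"))
})

test_that("invalid construction is rejected", {
  ts <- as.POSIXct("2019-06-01 08:00:00", tz = "UTC") + c(0, 60, 180)
  expect_error(activity_matrix(ts, matrix(0L, 3, 2)), "gap")
  ts2 <- as.POSIXct("2019-06-01 08:00:00", tz = "UTC") + c(0, 60)
  expect_error(activity_matrix(ts2, matrix(c(-1L, 0L), 2, 1)),
               "non-negative")
  expect_error(activity_matrix(ts2, matrix(0L, 2, 33)), "32 channels")
})

test_that("ZT alignment trims to whole days starting at the first ZT0", {
  sched <- light_schedule(lights_on = "08:00:00")
  # start at ZT6 (14:00) with 3 days of data
  start <- as.POSIXct("2019-06-01 14:00:00", tz = "UTC")
  m <- activity_matrix(start + (0:(3 * 1440 - 1)) * 60,
                       matrix(1L, 3 * 1440, 2))
  al <- align_to_zt(m, sched)
  expect_identical(nrow(al$counts), 2L * 1440L)
  expect_identical(al$zt_minute[1], 0L)
  expect_equal(as.numeric(al$timestamps[1] - m$timestamps[1], units = "mins"),
               1080)
  expect_true(all(al$light_state[al$zt_minute < 720]))
  expect_false(any(al$light_state[al$zt_minute >= 720]))

  # start exactly at ZT0: the first day is dropped
  m0 <- activity_matrix(as.POSIXct("2019-06-01 08:00:00", tz = "UTC") +
                          (0:(2 * 1440 - 1)) * 60,
                        matrix(1L, 2 * 1440, 1))
  al0 <- align_to_zt(m0, sched)
  expect_identical(nrow(al0$counts), 1440L)
  expect_equal(as.numeric(al0$timestamps[1] - m0$timestamps[1],
                          units = "mins"), 1440)

  # 12-hour recording: insufficient
  m12 <- activity_matrix(start + (0:719) * 60, matrix(1L, 720, 1))
  expect_error(align_to_zt(m12, sched), "insufficient")
})

test_that("alignment output is whole days and conserves trimmed counts", {
  set.seed(7)
  sched <- light_schedule(lights_on = "08:00:00")
  for (i in 1:5) {
    n <- sample(3000:6000, 1)
    start <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC") +
      sample(0:1439, 1) * 60
    m <- activity_matrix(start + (seq_len(n) - 1) * 60,
                         matrix(rpois(n * 3, 1), n, 3))
    al <- align_to_zt(m, sched)
    expect_identical(nrow(al$counts) %% 1440L, 0L)
    expect_identical(al$zt_minute[1], 0L)
    i0 <- which(as.numeric(m$timestamps) == as.numeric(al$timestamps[1]))
    expect_identical(sum(al$counts),
                     sum(m$counts[i0:(i0 + nrow(al$counts) - 1L), ]))
  }
})

test_that("design tables round-trip and reject duplicates and bad ages", {
  d <- data.frame(monitor = "M01", channel = 1:4,
                  genotype = c("ctrl", "ctrl", "kd", "kd"),
                  age_class = c("young", "mature", "young", "mature"),
                  include = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design_table(d, path)
  d2 <- read_design_table(path)
  expect_identical(d2$genotype, d$genotype)
  d$channel[2] <- 1L
  write_design_table(d, path)
  expect_error(read_design_table(path), "duplicate")
  d$channel[2] <- 2L
  d$age_class[1] <- "elderly"
  write_design_table(d, path)
  expect_error(read_design_table(path), "age_class")
})
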