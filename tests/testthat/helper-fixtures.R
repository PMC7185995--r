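# Shared fixtures and independent oracles.

# Random valid 32-channel activity matrix.
random_activity_matrix <- function(n_minutes = 120,
                                   start = as.POSIXct("2019-06-01 08:00:00",
                                                      tz = "UTC")) {
  activity_matrix(
    timestamps = start + (seq_len(n_minutes) - 1L) * 60,
    counts = matrix(rpois(n_minutes * 32L, 1.5), n_minutes, 32L),
    status = rep(1L, n_minutes),
    device = matrix(as.character(sample(0:9, n_minutes * 6, TRUE)),
                    n_minutes, 6))
}

# Independent brute-force sleep-bout scanner: walks the trace minute by
# minute, tracking the current zero run. Deliberately naive; the oracle for
# the run-length-encoding implementation.
brute_force_bouts <- function(counts, min_bout = 5L) {
  starts <- integer(0); durs <- integer(0)
  run_start <- NA_integer_; run_len <- 0L
  flush <- function() {
    if (run_len >= min_bout) {
      starts <<- c(starts, run_start)
      durs <<- c(durs, run_len)
    }
    run_start <<- NA_integer_; run_len <<- 0L
  }
  for (i in seq_along(counts)) {
    zero <- !is.na(counts[i]) && counts[i] == 0
    if (zero) {
      if (run_len == 0L) run_start <- i
      run_len <- run_len + 1L
    } else flush()
  }
  flush()
  data.frame(start = starts, duration = durs)
}

# A DAM file fixture written in code: n rows, given counts matrix.
write_dam_fixture <- function(counts, path,
                              start = as.POSIXct("2019-06-01 08:00:00",
                                                 tz = "UTC")) {
  m <- activity_matrix(timestamps = start + (seq_len(nrow(counts)) - 1) * 60,
                       counts = counts)
  write_dam_file(m, path)
  path
}
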