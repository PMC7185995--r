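# Sleep scoring and architecture metrics. Sleep is defined behaviourally as
# >= 5 consecutive minutes without beam breaks; a maximal such run is one
# sleep bout. Scoring runs over the continuous recording so bouts spanning
# ZT0 are preserved; minutes are then assigned to days and phases.

#' Detect sleep bouts in a minute-binned activity trace
#'
#' A sleep bout is a maximal run of at least `min_bout` consecutive minutes
#' with exactly zero activity counts. Runs of 1 to `min_bout - 1` zero
#' minutes contribute no sleep. Missing minutes (`NA`, e.g. invalid monitor
#' status) break runs: a bout can never span a gap.
#'
#' @param counts numeric vector of per-minute activity counts (`NA` =
#'   missing minute).
#' @param min_bout minimum bout duration in minutes (default 5).
#' @return A `data.frame` with columns `start` (1-based minute index of bout
#'   onset) and `duration` (minutes).
#' @export
detect_sleep_bouts <- function(counts, min_bout = 5L) {
  if (any(counts < 0, na.rm = TRUE))
    stop("activity counts must be non-negative", call. = FALSE)
  if (length(counts) == 0)
    return(data.frame(start = integer(0), duration = integer(0)))
  state <- ifelse(is.na(counts), 2L, as.integer(counts > 0))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 0L & r$lengths >= min_bout
  data.frame(start = starts[keep], duration = r$lengths[keep])
}

#' Per-minute sleep indicator
#'
#' Marks every minute inside a detected sleep bout. Missing minutes are
#' never sleep.
#'
#' @inheritParams detect_sleep_bouts
#' @return Logical vector, same length as `counts`.
#' @export
sleep_minutes <- function(counts, min_bout = 5L) {
  bouts <- detect_sleep_bouts(counts, min_bout)
  asleep <- rep(FALSE, length(counts))
  for (i in seq_len(nrow(bouts)))
    asleep[bouts$start[i]:(bouts$start[i] + bouts$duration[i] - 1L)] <- TRUE
  asleep
}

#' Summarise sleep architecture per day for one fly
#'
#' Scores the full trace once, then assigns each sleep minute to its own day
#' and phase (day = ZT0-ZT12, night = ZT12-ZT24). A bout spanning the ZT12
#' boundary contributes minutes to both phases but is counted once, in its
#' phase of onset; a bout spanning midnight-ZT0 likewise contributes minutes
#' to both days and is counted on its day of onset. Bout-length means are
#' over the full durations of bouts counted in that phase; a phase with zero
#' bouts reports mean length 0 and `*_mean_defined = FALSE`.
#'
#' @param counts per-minute activity counts for one fly, ZT-aligned (`NA` =
#'   missing minute).
#' @param zt_minute integer ZT minute (0-1439) per row.
#' @param day_index integer day index per row.
#' @param min_bout minimum bout duration in minutes.
#' @return A `data.frame` with one row per day: `day`, `total_sleep`,
#'   `day_sleep`, `night_sleep`, `day_bout_number`, `night_bout_number`,
#'   `day_bout_length_mean`, `night_bout_length_mean`, plus the
#'   `*_mean_defined` flags.
#' @export
summarize_sleep <- function(counts, zt_minute, day_index, min_bout = 5L) {
  stopifnot(length(counts) == length(zt_minute),
            length(counts) == length(day_index))
  bouts <- detect_sleep_bouts(counts, min_bout)
  asleep <- rep(FALSE, length(counts))
  for (i in seq_len(nrow(bouts)))
    asleep[bouts$start[i]:(bouts$start[i] + bouts$duration[i] - 1L)] <- TRUE
  is_day <- zt_minute < 720L
  days <- sort(unique(day_index))
  onset_day <- day_index[bouts$start]
  onset_is_day <- is_day[bouts$start]
  out <- lapply(days, function(d) {
    in_d <- day_index == d
    ds <- sum(asleep & in_d & is_day)
    ns <- sum(asleep & in_d & !is_day)
    db <- which(onset_day == d & onset_is_day)
    nb <- which(onset_day == d & !onset_is_day)
    data.frame(
      day = d,
      total_sleep = ds + ns,
      day_sleep = ds,
      night_sleep = ns,
      day_bout_number = length(db),
      night_bout_number = length(nb),
      day_bout_length_mean = if (length(db)) mean(bouts$duration[db]) else 0,
      night_bout_length_mean = if (length(nb)) mean(bouts$duration[nb]) else 0,
      day_mean_defined = length(db) > 0,
      night_mean_defined = length(nb) > 0)
  })
  do.call(rbind, out)
}

#' Sleep summaries for every channel of an aligned recording
#'
#' Applies [summarize_sleep()] to every channel of a ZT-aligned activity
#' matrix. Minutes with invalid monitor status are treated as missing.
#'
#' @param m an aligned [activity_matrix()] (see [align_to_zt()]).
#' @param min_bout minimum bout duration in minutes.
#' @return A `data.frame` with a `channel` column prepended to the per-day
#'   summaries.
#' @export
sleep_summary_matrix <- function(m, min_bout = 5L) {
  if (is.null(m$zt_minute) || is.null(m$day_index))
    stop("matrix must be ZT-aligned first (align_to_zt)", call. = FALSE)
  bad <- m$status != 1L
  res <- lapply(seq_len(ncol(m$counts)), function(ch) {
    x <- as.numeric(m$counts[, ch])
    x[bad] <- NA_real_
    s <- summarize_sleep(x, m$zt_minute, m$day_index, min_bout)
    cbind(channel = ch, s)
  })
  do.call(rbind, res)
}

#' Binned group sleep profile
#'
#' For a group of ZT-aligned flies, the fraction of each `bin_width`-minute
#' bin spent asleep, averaged over flies, with the standard error of that
#' mean. This is the quantity plotted in standard fly sleep traces.
#'
#' @param counts matrix of per-minute counts, minutes x flies, ZT-aligned so
#'   row 1 is ZT0 (any whole number of days).
#' @param bin_width bin width in minutes; must divide 1440.
#' @param min_bout minimum bout duration in minutes.
#' @return A `data.frame` with `bin` (1-based), `zt_start_min`, `fraction`
#'   (mean fraction asleep, in `[0, 1]`) and `sem` (0 for a single fly).
#' @export
sleep_profile <- function(counts, bin_width = 30L, min_bout = 5L) {
  counts <- as.matrix(counts)
  if (1440L %% bin_width != 0)
    stop("bin_width must divide 1440", call. = FALSE)
  n <- nrow(counts)
  if (n %% bin_width != 0)
    stop("trace length must be a multiple of bin_width", call. = FALSE)
  nbin <- n %/% bin_width
  bin_of <- rep(seq_len(nbin), each = bin_width)
  per_fly <- vapply(seq_len(ncol(counts)), function(j) {
    asleep <- sleep_minutes(counts[, j], min_bout)
    tapply(asleep, bin_of, mean)
  }, numeric(nbin))
  per_fly <- matrix(per_fly, nrow = nbin)
  frac <- rowMeans(per_fly)
  sem <- if (ncol(per_fly) > 1)
    apply(per_fly, 1, stats::sd) / sqrt(ncol(per_fly))
  else rep(0, nbin)
  data.frame(bin = seq_len(nbin),
             zt_start_min = ((seq_len(nbin) - 1L) * bin_width) %% 1440L,
             fraction = frac, sem = sem)
}

#' Flag dead or escaped flies
#'
#' Standard DAM hygiene: a fly whose activity is zero from some minute
#' through the end of the recording, for at least the final
#' `threshold_minutes`, is assumed dead (or escaped) and excluded.
#'
#' @param m an [activity_matrix()].
#' @param threshold_minutes terminal-inactivity window (default 720 = 12 h).
#' @return A `data.frame` with `channel`, `last_active_minute` (0 if never
#'   active) and `excluded`.
#' @export
filter_dead_flies <- function(m, threshold_minutes = 720L) {
  n <- nrow(m$counts)
  res <- lapply(seq_len(ncol(m$counts)), function(ch) {
    act <- which(m$counts[, ch] > 0L)
    last <- if (length(act)) max(act) else 0L
    data.frame(channel = ch, last_active_minute = last,
               excluded = (n - last) >= threshold_minutes)
  })
  do.call(rbind, res)
}
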