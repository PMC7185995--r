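# DAM monitor file ingestion: the Trikinetics DAM2 dialect (42 tab-separated
# fields: index, date "DD Mon YY", time "HH:MM:SS", status, six device fields,
# then counts for channels 1-32, one row per minute).

DAM_N_CHANNELS <- 32L
DAM_N_META <- 10L
.DAM_MONTHS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                 "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Construct an activity matrix
#'
#' An `activity_matrix` holds minute-binned beam-break counts for up to 32
#' monitor channels, with one row per minute. Rows whose monitor status code
#' differs from 1 are retained but flagged invalid; downstream sleep scoring
#' treats their minutes as missing.
#'
#' @param timestamps `POSIXct` vector, strictly increasing at 1-minute spacing.
#' @param counts integer matrix, minutes x channels (<= 32 columns), all
#'   entries non-negative.
#' @param status integer vector of per-row monitor status codes (1 = valid).
#' @param device optional character matrix (minutes x 6) of device fields
#'   carried verbatim from the monitor file; not interpreted.
#' @param light_state optional logical vector (lights on per row).
#' @param zt_minute optional integer vector of Zeitgeber minutes (0-1439).
#' @param day_index optional integer vector of experimental day indices.
#' @return An object of class `activity_matrix`.
#' @export
activity_matrix <- function(timestamps, counts, status = NULL, device = NULL,
                            light_state = NULL, zt_minute = NULL,
                            day_index = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  if (is.null(status)) status <- rep(1L, n)
  m <- structure(
    list(timestamps = timestamps, counts = counts, status = as.integer(status),
         device = device, light_state = light_state, zt_minute = zt_minute,
         day_index = day_index),
    class = "activity_matrix")
  validate_activity_matrix(m)
  m
}

#' Validate an activity matrix
#'
#' Checks the structural invariants: strictly increasing timestamps at exactly
#' 1-minute spacing, non-negative integer counts, at most 32 channels, and
#' congruent row counts across fields.
#'
#' @param m an `activity_matrix`.
#' @return `m`, invisibly. Errors on violation.
#' @export
validate_activity_matrix <- function(m) {
  stopifnot(inherits(m, "activity_matrix"))
  n <- nrow(m$counts)
  if (length(m$timestamps) != n || length(m$status) != n)
    stop("activity_matrix fields have inconsistent row counts", call. = FALSE)
  if (ncol(m$counts) > DAM_N_CHANNELS)
    stop("activity_matrix supports at most 32 channels", call. = FALSE)
  if (n > 1) {
    d <- diff(as.numeric(m$timestamps))
    if (any(d <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
    if (any(d != 60))
      stop("timestamps must be at exact 1-minute spacing (gap found)",
           call. = FALSE)
  }
  if (anyNA(m$counts) || any(m$counts < 0L))
    stop("counts must be non-negative integers", call. = FALSE)
  invisible(m)
}

#' @export
dim.activity_matrix <- function(x) dim(x$counts)

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d minutes x %d channels\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  start: %s UTC, %d invalid-status rows\n",
              format(x$timestamps[1], "%Y-%m-%d %H:%M"),
              sum(x$status != 1L)))
  invisible(x)
}

.parse_dam_datetime <- function(date_field, time_field, line_no) {
  parts <- strsplit(date_field, " ", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (any(!ok))
    stop(sprintf("malformed date field at line %d: '%s'",
                 line_no[which(!ok)[1]], date_field[which(!ok)[1]]),
         call. = FALSE)
  pm <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  mon <- match(pm[, 2], .DAM_MONTHS)
  if (anyNA(mon))
    stop(sprintf("unrecognised month at line %d: '%s'",
                 line_no[which(is.na(mon))[1]], pm[which(is.na(mon))[1], 2]),
         call. = FALSE)
  yr <- as.integer(pm[, 3])
  yr <- ifelse(yr < 100L, yr + 2000L, yr)
  iso <- sprintf("%04d-%02d-%02d %s", yr, mon, as.integer(pm[, 1]), time_field)
  ts <- as.POSIXct(iso, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(ts))
    stop(sprintf("unparseable date/time at line %d", line_no[which(is.na(ts))[1]]),
         call. = FALSE)
  ts
}

#' Read a DAM monitor file
#'
#' Parses a Trikinetics-style DAM2 monitor file: tab-delimited text with 10
#' metadata fields (index, date `DD Mon YY`, time `HH:MM:SS`, status, six
#' device fields) followed by exactly 32 integer channel counts per row.
#' Parsing is locale-independent (English month abbreviations are matched
#' explicitly). Rows with status codes other than 1 are retained and flagged.
#'
#' @param path path to the monitor file.
#' @return An [activity_matrix()] with 32 channel columns.
#' @export
read_dam_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(activity_matrix(
      timestamps = as.POSIXct(character(0), tz = "UTC"),
      counts = matrix(integer(0), 0, DAM_N_CHANNELS)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- DAM_N_META + DAM_N_CHANNELS
  if (any(nf != want))
    stop(sprintf("malformed DAM file '%s': line %d has %d fields (expected %d)",
                 path, which(nf != want)[1], nf[nf != want][1], want),
         call. = FALSE)
  fm <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  cnt_chr <- fm[, (DAM_N_META + 1):want]
  bad <- !grepl("^[0-9]+$", cnt_chr)
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1], dim(cnt_chr))
    stop(sprintf("non-integer count at line %d, channel %d: '%s'",
                 idx[1], idx[2], cnt_chr[which(bad)[1]]), call. = FALSE)
  }
  counts <- matrix(as.integer(cnt_chr), nrow = nrow(fm))
  ts <- .parse_dam_datetime(fm[, 2], fm[, 3], seq_len(nrow(fm)))
  if (nrow(fm) > 1 && any(diff(as.numeric(ts)) <= 0))
    stop("alignment error: non-monotonic timestamps in DAM file", call. = FALSE)
  activity_matrix(timestamps = ts, counts = counts,
                  status = as.integer(fm[, 4]),
                  device = fm[, 5:10, drop = FALSE])
}

#' Write a DAM monitor file
#'
#' Emits the 42-field DAM2 dialect accepted by [read_dam_file()]. Matrices
#' with fewer than 32 channels are padded with zero-count channels on write;
#' counts, timestamps and status round-trip bit-exactly.
#'
#' @param m an [activity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dam_file <- function(m, path) {
  validate_activity_matrix(m)
  if (ncol(m$counts) > DAM_N_CHANNELS)
    stop("unsupported width: more than 32 channels", call. = FALSE)
  n <- nrow(m$counts)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  counts <- m$counts
  if (ncol(counts) < DAM_N_CHANNELS) {
    pad <- matrix(0L, n, DAM_N_CHANNELS - ncol(counts))
    counts <- cbind(counts, pad)
  }
  lt <- as.POSIXlt(m$timestamps, tz = "UTC")
  date_f <- sprintf("%d %s %02d", lt$mday, .DAM_MONTHS[lt$mon + 1L],
                    lt$year %% 100L)
  time_f <- sprintf("%02d:%02d:%02d", lt$hour, lt$min, as.integer(lt$sec))
  device <- m$device
  if (is.null(device)) device <- matrix("0", n, 6)
  meta <- cbind(seq_len(n), date_f, time_f, m$status, device)
  body <- do.call(paste, c(lapply(seq_len(ncol(meta)), function(j) meta[, j]),
                           lapply(seq_len(DAM_N_CHANNELS),
                                  function(j) counts[, j]),
                           sep = "\t"))
  writeLines(body, path)
  invisible(path)
}

#' Define a light schedule
#'
#' A light schedule fixes Zeitgeber time: ZT0 is lights-on. Under LD the
#' lights are on for `photoperiod_hours` from ZT0; under DD (constant
#' darkness) ZT is still defined by the prior entrainment but lights are
#' never on. Light state is always derived from the declared schedule, not
#' from the monitor's light-sensor field.
#'
#' @param lights_on clock time of lights-on, `"HH:MM:SS"` (defines ZT0).
#' @param photoperiod_hours hours of light per day (12 for LD 12:12).
#' @param regime `"LD"` or `"DD"`.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(lights_on = "08:00:00", photoperiod_hours = 12,
                           regime = c("LD", "DD")) {
  regime <- match.arg(regime)
  if (photoperiod_hours < 0 || photoperiod_hours > 24)
    stop("photoperiod_hours must be in [0, 24]", call. = FALSE)
  p <- as.integer(strsplit(lights_on, ":", fixed = TRUE)[[1]])
  if (length(p) == 2) p <- c(p, 0L)
  stopifnot(length(p) == 3, !anyNA(p))
  structure(list(lights_on = lights_on,
                 lights_on_minute = p[1] * 60L + p[2],
                 photoperiod_hours = photoperiod_hours,
                 regime = regime),
            class = "light_schedule")
}

#' Zeitgeber minute of timestamps
#'
#' @param timestamps `POSIXct` vector.
#' @param schedule a [light_schedule()].
#' @return Integer vector of minutes since lights-on, in `[0, 1439]`.
#' @export
zt_minute_of <- function(timestamps, schedule) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  mins <- lt$hour * 60L + lt$min
  (mins - schedule$lights_on_minute) %% 1440L
}

#' Align a recording to Zeitgeber time
#'
#' Trims the recording to whole experimental days: the output starts at the
#' first ZT0 strictly after the first recorded minute (a recording that
#' begins exactly at ZT0 therefore discards its first day, keeping only
#' fully acclimated days) and is cut to an integer number of 1440-minute
#' days. Rows are annotated with ZT minute and day index, and light state is
#' derived from the schedule.
#'
#' @param m an [activity_matrix()].
#' @param schedule a [light_schedule()].
#' @return The aligned `activity_matrix` with `zt_minute`, `day_index` and
#'   `light_state` filled in.
#' @export
align_to_zt <- function(m, schedule) {
  validate_activity_matrix(m)
  n <- nrow(m$counts)
  zt <- zt_minute_of(m$timestamps, schedule)
  zt0 <- which(zt == 0L & seq_len(n) > 1L)
  if (length(zt0) == 0)
    stop("insufficient data: no ZT0 crossing after recording start",
         call. = FALSE)
  start <- zt0[1]
  n_days <- (n - start + 1L) %/% 1440L
  if (n_days < 1L)
    stop("insufficient data: less than one full day after the first ZT0",
         call. = FALSE)
  keep <- start:(start + n_days * 1440L - 1L)
  zt_keep <- rep(0:1439, times = n_days)
  light <- if (schedule$regime == "LD") {
    zt_keep < schedule$photoperiod_hours * 60
  } else rep(FALSE, length(keep))
  activity_matrix(
    timestamps = m$timestamps[keep],
    counts = m$counts[keep, , drop = FALSE],
    status = m$status[keep],
    device = if (!is.null(m$device)) m$device[keep, , drop = FALSE],
    light_state = light,
    zt_minute = zt_keep,
    day_index = rep(seq_len(n_days), each = 1440L))
}

#' Read an experiment design table
#'
#' The design table maps monitor channels to genotypes and age classes. It is
#' a TSV with header `monitor  channel  genotype  age_class  include`.
#'
#' @param path path to the TSV file.
#' @param allowed_ages permitted `age_class` labels; the study's two classes
#'   are `young` (day 1 post-eclosion) and `mature` (day 4-5).
#' @return A `data.frame` with one row per (monitor, channel).
#' @export
read_design_table <- function(path, allowed_ages = c("young", "mature")) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("monitor", "channel", "genotype", "age_class", "include")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(d$monitor, d$channel)
  if (anyDuplicated(key))
    stop("duplicate (monitor, channel) in design table: ",
         key[anyDuplicated(key)], call. = FALSE)
  if (!all(d$age_class %in% allowed_ages))
    stop("age_class outside allowed set: ",
         paste(setdiff(d$age_class, allowed_ages), collapse = ", "),
         call. = FALSE)
  d$include <- as.logical(d$include)
  d
}

#' Write an experiment design table
#'
#' @param design a design `data.frame` as returned by [read_design_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
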