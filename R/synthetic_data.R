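# Synthetic-data generators with known ground truth. The behavioural
# generator is a semi-Markov alternating-renewal sleep-wake model: bout
# lengths are drawn directly (5 + geometric for sleep, so every latent
# sleep bout is detectable; 1 + geometric for wake), the phase switches at
# ZT12, and waking activity is Poisson with an optional circadian
# modulation. Because the stationary occupied fraction of an alternating
# renewal process is m_s / (m_s + m_w), daytime sleep is calibrated
# analytically and the expected ontogeny ratio equals the target by
# construction.

#' Define a generative genotype model
#'
#' Parameterises the sleep-wake simulator for one genotype. The mature
#' daytime sleep level and the target ontogeny ratio fix the expected
#' day-sleep minutes of both ages; sleep-bout means are set per age/phase
#' and the matching wake-bout means are solved from the stationary fraction
#' `f = m_s / (m_s + m_w)`. The wild-type defaults emulate the study's
#' control flies: mature day sleep about 300 of 720 minutes, young roughly
#' twice that (target ratio 1.75, mid wild-type band), with the juvenile
#' day-sleep gain carried by longer sleep bouts.
#'
#' @param target_ontogeny_ratio expected young/mature day-sleep ratio.
#' @param mature_day_sleep expected mature daytime sleep, minutes per 720.
#' @param young_night_sleep,mature_night_sleep expected night sleep,
#'   minutes per 720.
#' @param sleep_bout_mean list of mean sleep-bout minutes per age/phase,
#'   `list(young = c(day =, night =), mature = c(day =, night =))`; all
#'   >= 5 so generated bouts are detectable.
#' @param wake_rate Poisson mean beam breaks per waking minute.
#' @param circ_period_h,circ_amplitude sinusoidal modulation of the waking
#'   activity rate (amplitude in `[0, 1]`).
#' @param redraw_prob probability that a zero-count waking minute is
#'   re-drawn to 1, so wake is rarely mistaken for sleep.
#' @param fragmentation multiplier (< 1 fragments) applied to all bout
#'   means; leaves expected sleep fractions, hence the ratio, unchanged.
#' @param rhythmic if `FALSE`, both phases use pooled bout means and the
#'   activity-rate modulation is switched off (an arrhythmic genotype).
#' @param genotype label.
#' @return An object of class `genotype_model` with the derived per
#'   age/phase sleep and wake bout means in `$bout_means`.
#' @export
genotype_model <- function(target_ontogeny_ratio = 1.75,
                           mature_day_sleep = 300,
                           young_night_sleep = 612,
                           mature_night_sleep = 576,
                           sleep_bout_mean = list(
                             young = c(day = 36, night = 60),
                             mature = c(day = 14, night = 45)),
                           wake_rate = 2,
                           circ_period_h = 24,
                           circ_amplitude = 0.5,
                           redraw_prob = 0.75,
                           fragmentation = 1,
                           rhythmic = TRUE,
                           genotype = "model") {
  young_day_sleep <- target_ontogeny_ratio * mature_day_sleep
  sleep_min <- list(
    young = c(day = young_day_sleep, night = young_night_sleep),
    mature = c(day = mature_day_sleep, night = mature_night_sleep))
  bad <- unlist(sleep_min)
  if (any(bad <= 0) || any(bad >= 720))
    stop("validation error: expected phase sleep must lie in (0, 720) ",
         "minutes; got ", paste(round(bad, 1), collapse = ", "),
         call. = FALSE)
  if (circ_amplitude < 0 || circ_amplitude > 1)
    stop("validation error: circ_amplitude must be in [0, 1]", call. = FALSE)
  if (wake_rate <= 0)
    stop("validation error: wake_rate must be > 0", call. = FALSE)
  if (fragmentation <= 0)
    stop("validation error: fragmentation must be > 0", call. = FALSE)
  bout_means <- list()
  for (age in c("young", "mature")) {
    bm <- list()
    for (ph in c("day", "night")) {
      f <- sleep_min[[age]][[ph]] / 720
      ms <- sleep_bout_mean[[age]][[ph]] * fragmentation
      if (ms < 5)
        stop("validation error: sleep-bout mean must be >= 5 minutes ",
             "(after fragmentation); got ", ms, call. = FALSE)
      mw <- max(1, ms * (1 - f) / f)
      bm[[ph]] <- c(sleep = ms, wake = mw)
    }
    bout_means[[age]] <- bm
  }
  structure(list(
    genotype = genotype,
    target_ontogeny_ratio = target_ontogeny_ratio,
    expected_sleep = sleep_min,
    bout_means = bout_means,
    wake_rate = wake_rate, circ_period_h = circ_period_h,
    circ_amplitude = circ_amplitude, redraw_prob = redraw_prob,
    fragmentation = fragmentation, rhythmic = rhythmic),
    class = "genotype_model")
}

#' Expected daytime sleep under a genotype model
#'
#' The analytic calibration target: the stationary fraction
#' `m_s / (m_s + m_w)` of the alternating-renewal process times 720
#' minutes, per age and phase.
#'
#' @param model a [genotype_model()].
#' @param age `"young"` or `"mature"`.
#' @param phase `"day"` or `"night"`.
#' @return Expected sleep minutes in that 720-minute phase.
#' @export
expected_phase_sleep <- function(model, age = c("young", "mature"),
                                 phase = c("day", "night")) {
  age <- match.arg(age); phase <- match.arg(phase)
  bm <- model$bout_means[[age]][[phase]]
  720 * bm[["sleep"]] / (bm[["sleep"]] + bm[["wake"]])
}

# Latent alternating-renewal state sequence for one phase segment.
# Sleep bouts: 5 + Geom, wake bouts: 1 + Geom, parameterised by their
# means. A burn-in (discarded) brings the chain to stationarity so the
# occupied fraction is unbiased. Returns a logical vector (TRUE = asleep).
.sim_alternating <- function(ms, mw, n, burn = 720L) {
  need <- burn + n
  p_s <- if (ms > 5) 1 / (ms - 4) else 1
  p_w <- if (mw > 1) 1 / mw else 1
  state <- logical(0)
  while (length(state) < need) {
    k <- ceiling(1.5 * need / (ms + mw)) + 10L
    wake_d <- 1L + stats::rgeom(k, p_w)
    sleep_d <- 5L + stats::rgeom(k, p_s)
    durs <- as.vector(rbind(wake_d, sleep_d))
    vals <- rep(c(FALSE, TRUE), k)
    state <- c(state, rep(vals, durs))
  }
  state[(burn + 1L):need]
}

#' Simulate one fly's minute-binned activity
#'
#' Generates the latent sleep-wake state by alternating-renewal bouts with
#' phase-specific parameters (switching at ZT12), then emits counts:
#' exactly 0 while asleep, Poisson(`wake_rate` x circadian multiplier)
#' while awake, with zero-count waking minutes re-drawn to 1 with
#' probability `redraw_prob`. Identical seeds give identical output.
#'
#' @param model a [genotype_model()].
#' @param age `"young"` or `"mature"`.
#' @param n_minutes number of minutes to simulate (>= 1440).
#' @param seed integer seed; `NULL` continues the current RNG stream (used
#'   when a caller manages the seed).
#' @param start_zt_min ZT minute of the first sample (default 0).
#' @return A list: `counts` (integer), `asleep` (logical latent state),
#'   `zt_minute`.
#' @export
simulate_fly_activity <- function(model, age = c("young", "mature"),
                                  n_minutes, seed = NULL,
                                  start_zt_min = 0L) {
  stopifnot(inherits(model, "genotype_model"))
  age <- match.arg(age)
  if (n_minutes < 1440)
    stop("n_minutes must be >= 1440", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  zt <- (start_zt_min + seq_len(n_minutes) - 1L) %% 1440L
  is_day <- zt < 720L
  r <- rle(is_day)
  asleep <- logical(0)
  bm_day <- model$bout_means[[age]][["day"]]
  bm_night <- model$bout_means[[age]][["night"]]
  if (!model$rhythmic) {
    pooled <- (bm_day + bm_night) / 2
    bm_day <- bm_night <- pooled
  }
  for (i in seq_along(r$lengths)) {
    bm <- if (r$values[i]) bm_day else bm_night
    asleep <- c(asleep,
                .sim_alternating(bm[["sleep"]], bm[["wake"]], r$lengths[i]))
  }
  counts <- integer(n_minutes)
  wake_idx <- which(!asleep)
  if (length(wake_idx)) {
    mult <- if (model$rhythmic && model$circ_amplitude > 0) {
      pmax(0, 1 + model$circ_amplitude *
             cos(2 * pi * zt[wake_idx] / (model$circ_period_h * 60)))
    } else rep(1, length(wake_idx))
    cts <- stats::rpois(length(wake_idx), model$wake_rate * mult)
    zero <- cts == 0L
    if (any(zero))
      cts[zero] <- ifelse(stats::runif(sum(zero)) < model$redraw_prob, 1L, 0L)
    counts[wake_idx] <- cts
  }
  list(counts = counts, asleep = asleep, zt_minute = zt)
}

#' Simulate a full DAM screen experiment
#'
#' Simulates `n_flies_per_group` flies per genotype and age class, packs
#' them into 32-channel monitors (spilling into additional monitors as
#' needed), and returns DAM-valid activity matrices together with the
#' experiment design and the ground truth. Recordings start at ZT18 of a
#' lead-in evening so that [align_to_zt()] yields exactly `n_days` full
#' days. With `out_dir` set, DAM monitor files, a design TSV and a truth
#' TSV are written.
#'
#' @param models named list of [genotype_model()]s (>= 1 genotype).
#' @param n_flies_per_group flies per genotype per age class.
#' @param seed integer master seed (the one source of randomness).
#' @param n_days full recorded days per fly after alignment.
#' @param lead_in_min lead-in minutes before the first ZT0.
#' @param lights_on clock time of lights-on.
#' @param out_dir optional directory to write `MonitorNN.txt`, `design.tsv`
#'   and `truth.tsv`.
#' @return A list: `monitors` (list of [activity_matrix()]), `design`
#'   (`data.frame`), `truth` (`data.frame` with per-fly latent day-sleep
#'   minutes and per-genotype target ratio), `schedule`.
#' @export
simulate_screen_experiment <- function(models, n_flies_per_group = 16L,
                                       seed = 1L, n_days = 1L,
                                       lead_in_min = 360L,
                                       lights_on = "08:00:00",
                                       out_dir = NULL) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "genotype")
  set.seed(seed)
  n_minutes <- lead_in_min + n_days * 1440L
  start_zt <- (1440L - lead_in_min) %% 1440L
  sched <- light_schedule(lights_on = lights_on, photoperiod_hours = 12,
                          regime = "LD")
  t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC") +
    (sched$lights_on_minute + start_zt) * 60
  flies <- expand.grid(fly = seq_len(n_flies_per_group),
                       age_class = c("young", "mature"),
                       genotype = names(models),
                       stringsAsFactors = FALSE)
  n_tot <- nrow(flies)
  flies$monitor <- sprintf("M%02d", (seq_len(n_tot) - 1L) %/% 32L + 1L)
  flies$channel <- (seq_len(n_tot) - 1L) %% 32L + 1L
  counts_all <- matrix(0L, n_minutes, n_tot)
  latent_day_sleep <- numeric(n_tot)
  post <- seq_len(n_days * 1440L) + lead_in_min
  zt_post <- (seq_len(n_days * 1440L) - 1L) %% 1440L
  for (i in seq_len(n_tot)) {
    sim <- simulate_fly_activity(models[[flies$genotype[i]]],
                                 flies$age_class[i], n_minutes,
                                 seed = NULL, start_zt_min = start_zt)
    counts_all[, i] <- sim$counts
    latent_day_sleep[i] <- sum(sim$asleep[post][zt_post < 720L]) / n_days
  }
  ts <- t0 + (seq_len(n_minutes) - 1L) * 60
  monitors <- lapply(split(seq_len(n_tot), flies$monitor), function(cols) {
    cnt <- matrix(0L, n_minutes, 32L)
    cnt[, flies$channel[cols]] <- counts_all[, cols]
    activity_matrix(timestamps = ts, counts = cnt)
  })
  design <- flies[, c("monitor", "channel", "genotype", "age_class")]
  design$include <- TRUE
  truth <- cbind(design[, c("monitor", "channel", "genotype", "age_class")],
                 latent_day_sleep = latent_day_sleep,
                 target_ratio = vapply(
                   flies$genotype,
                   function(g) models[[g]]$target_ontogeny_ratio, numeric(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mn in names(monitors))
      write_dam_file(monitors[[mn]], file.path(out_dir,
                                               paste0("Monitor_", mn, ".txt")))
    write_design_table(design, file.path(out_dir, "design.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(monitors = monitors, design = design, truth = truth, schedule = sched)
}

#' Score a simulated (or real) screen into ontogeny results
#'
#' Pipeline glue from monitors to per-genotype ontogeny results: aligns
#' each monitor to ZT, scores sleep, takes each fly's first full day of
#' daytime sleep (or the mean over `use_days` days), and groups flies by
#' genotype and age class.
#'
#' @param monitors list of [activity_matrix()]s.
#' @param design design `data.frame` (`monitor`, `channel`, `genotype`,
#'   `age_class`, `include`).
#' @param schedule a [light_schedule()].
#' @param use_days how many recorded days to average per fly (default 1,
#'   the first full day).
#' @param min_bout minimum sleep-bout duration.
#' @return A list of [compute_ontogeny_ratio()] objects, one per genotype.
#' @export
score_screen <- function(monitors, design, schedule, use_days = 1L,
                         min_bout = 5L) {
  if (is.null(names(monitors)))
    names(monitors) <- unique(design$monitor)
  per_fly <- lapply(names(monitors), function(mn) {
    al <- align_to_zt(monitors[[mn]], schedule)
    s <- sleep_summary_matrix(al, min_bout)
    s <- s[s$day <= use_days, , drop = FALSE]
    agg <- stats::aggregate(day_sleep ~ channel, data = s, FUN = mean)
    agg$monitor <- mn
    agg
  })
  per_fly <- do.call(rbind, per_fly)
  d <- merge(design[design$include, ], per_fly,
             by = c("monitor", "channel"))
  lapply(split(d, d$genotype), function(g) {
    compute_ontogeny_ratio(young = g$day_sleep[g$age_class == "young"],
                           mature = g$day_sleep[g$age_class == "mature"],
                           genotype = g$genotype[1])
  })
}

# --- synthetic image stacks -------------------------------------------------

.neighbors_6 <- function(coord, d) {
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  nb <- sweep(off, 2, coord, `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb[ok, , drop = FALSE]
}

.lin3 <- function(coord, d) {
  coord[, 1] + (coord[, 2] - 1L) * d[1] + (coord[, 3] - 1L) * d[1] * d[2]
}

# 26-neighbourhood halo (including the voxels themselves) as linear indices.
.halo_26 <- function(idx, d) {
  coord <- arrayInd(idx, d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- lapply(seq_len(nrow(off)), function(i) {
    nb <- sweep(coord, 2, off[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    .lin3(nb[ok, , drop = FALSE], d)
  })
  unique(unlist(out))
}

#' Simulate a confocal stack with known puncta
#'
#' Places `k_puncta` disjoint connected blobs (grown by 6-connected random
#' walk, so each is a single 26-connected component) inside the ROI, with
#' at least one empty voxel between blobs in the 26-neighbour sense, over a
#' noisy background. Background intensities are clamped below
#' `background_max` (default 40, under the detection threshold of 52) —
#' that clamp is a generator contract that keeps the planted truth exactly
#' recoverable.
#'
#' @param k_puncta number of blobs (>= 0).
#' @param dims stack dimensions `(z, y, x)`.
#' @param blob_size_range inclusive range of blob sizes in voxels.
#' @param intensity blob voxel intensity (default 60).
#' @param background_mean,noise_sd background noise parameters.
#' @param background_max clamp on background intensity.
#' @param roi optional `roi_mask`; default is the stack minus a 2-voxel
#'   border.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param z_step,pixel_size voxel spacing in micrometres.
#' @param max_tries placement retries per blob before a placement error.
#' @return A list: `stack` ([image_stack()]), `roi` ([roi_mask()]), `truth`
#'   (list with `count`, `sizes`, `voxel_indices`, `roi_volume_vox`,
#'   `density`).
#' @export
simulate_image_stack <- function(k_puncta, dims = c(20L, 40L, 40L),
                                 blob_size_range = c(3L, 20L),
                                 intensity = 60, background_mean = 10,
                                 noise_sd = 5, background_max = 40,
                                 roi = NULL, seed = NULL,
                                 z_step = 0.5, pixel_size = 1,
                                 max_tries = 200L) {
  if (!is.null(seed)) set.seed(seed)
  if (k_puncta < 0) stop("k_puncta must be >= 0", call. = FALSE)
  d <- as.integer(dims)
  if (is.null(roi)) {
    m <- array(FALSE, d)
    m[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
    roi <- roi_mask(m, "dFSB")
  }
  rmask <- .roi_logical(roi, d)
  forbidden <- array(FALSE, d)
  blobs <- vector("list", k_puncta)
  i <- 1L
  tries <- 0L
  while (i <= k_puncta) {
    tries <- tries + 1L
    if (tries > max_tries * max(1L, k_puncta))
      stop("placement error: ROI too small for ", k_puncta,
           " disjoint blobs", call. = FALSE)
    target <- sample(blob_size_range[1]:blob_size_range[2], 1L)
    open <- which(rmask & !forbidden)
    if (length(open) == 0)
      stop("placement error: ROI too small for ", k_puncta,
           " disjoint blobs", call. = FALSE)
    seed_vox <- open[sample.int(length(open), 1L)]
    blob <- seed_vox
    repeat {
      if (length(blob) >= target) break
      frontier <- unique(unlist(lapply(blob, function(v) {
        nb <- .neighbors_6(arrayInd(v, d)[1, ], d)
        .lin3(nb, d)
      })))
      frontier <- setdiff(frontier, blob)
      frontier <- frontier[rmask[frontier] & !forbidden[frontier]]
      if (length(frontier) == 0) break
      blob <- c(blob, frontier[sample.int(length(frontier), 1L)])
    }
    if (length(blob) < blob_size_range[1]) next  # stuck; retry elsewhere
    blobs[[i]] <- blob
    forbidden[.halo_26(blob, d)] <- TRUE
    i <- i + 1L
  }
  vox <- array(pmin(pmax(round(stats::rnorm(prod(d), background_mean,
                                            noise_sd)), 0), background_max),
               d)
  for (b in blobs) vox[b] <- intensity
  stack <- image_stack(vox, z_step = z_step, pixel_size = pixel_size)
  vol <- sum(rmask & vox >= 1)
  truth <- list(count = k_puncta,
                sizes = vapply(blobs, length, integer(1)),
                voxel_indices = blobs,
                roi_volume_vox = vol,
                density = if (vol > 0) k_puncta / vol else NA_real_)
  list(stack = stack, roi = roi, truth = truth)
}

#' Simulate DE and ChIP peak tables with planted truth
#'
#' Builds a gene-level differential-expression table and a peak table such
#' that [select_de_genes()] (at the methods preset) recovers exactly the
#' planted up- and down-regulated sets, [top_chip_genes()] recovers exactly
#' the planted top-peak gene set, and their intersection has exactly
#' `n_overlap` genes. Defaults mirror the study scale: 54 up, 35 down, top
#' 200 peak genes, 5 shared genes.
#'
#' @param n_genes total genes.
#' @param n_up,n_down planted DE set sizes.
#' @param n_top_peaks planted top-peak gene count.
#' @param n_overlap planted overlap size
#'   (<= min(n_up + n_down, n_top_peaks)).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A list: `de` (`data.frame`: `gene`, `log2fc`, `padj`), `peaks`
#'   (`data.frame`: `gene`, `pvalue`, `signal`), `truth` (list `up`,
#'   `down`, `top`, `overlap`).
#' @export
simulate_omics_tables <- function(n_genes = 2000L, n_up = 54L, n_down = 35L,
                                  n_top_peaks = 200L, n_overlap = 5L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_de <- n_up + n_down
  if (n_overlap > min(n_de, n_top_peaks))
    stop("parameter error: n_overlap exceeds min(n_up + n_down, n_top_peaks)",
         call. = FALSE)
  if (n_de + (n_top_peaks - n_overlap) > n_genes)
    stop("parameter error: n_genes too small for the planted sets",
         call. = FALSE)
  genes <- sprintf("g%05d", seq_len(n_genes))
  de_genes <- sample(genes, n_de)
  up <- de_genes[seq_len(n_up)]
  down <- setdiff(de_genes, up)
  overlap <- sample(de_genes, n_overlap)
  non_de <- setdiff(genes, de_genes)
  top <- c(overlap, sample(non_de, n_top_peaks - n_overlap))
  # DE table: planted genes pass strictly; the rest fail on padj or on lfc
  padj <- stats::runif(n_genes, 0.06, 1)
  lfc <- stats::runif(n_genes, -0.9, 0.9)
  sig_null <- sample(c(TRUE, FALSE), n_genes, replace = TRUE)
  padj[sig_null] <- stats::runif(sum(sig_null), 0.0001, 0.049)
  iu <- match(up, genes); idn <- match(down, genes)
  padj[iu] <- stats::runif(n_up, 0.0001, 0.049)
  lfc[iu] <- stats::runif(n_up, 1.1, 3)
  padj[idn] <- stats::runif(n_down, 0.0001, 0.049)
  lfc[idn] <- -stats::runif(n_down, 1.1, 3)
  de <- data.frame(gene = genes, log2fc = lfc, padj = padj,
                   stringsAsFactors = FALSE)
  # peak table: top genes get strictly smaller p than everything else
  other_peak_genes <- sample(setdiff(genes, top),
                             min(150L, n_genes - n_top_peaks))
  pk_top <- data.frame(gene = top,
                       pvalue = stats::runif(n_top_peaks, 1e-9, 1e-5),
                       signal = stats::runif(n_top_peaks, 5, 20))
  pk_oth <- data.frame(gene = other_peak_genes,
                       pvalue = stats::runif(length(other_peak_genes),
                                             1e-4, 0.5),
                       signal = stats::runif(length(other_peak_genes), 1, 10))
  # secondary (weaker) peaks for a subset of top genes: dedup must keep best
  dup <- pk_top[sample.int(n_top_peaks, min(20L, n_top_peaks)), ,
                drop = FALSE]
  dup$pvalue <- stats::runif(nrow(dup), 1e-3, 0.5)
  dup$signal <- stats::runif(nrow(dup), 1, 5)
  peaks <- rbind(pk_top, pk_oth, dup)
  peaks <- peaks[sample.int(nrow(peaks)), , drop = FALSE]
  rownames(peaks) <- NULL
  list(de = de, peaks = peaks,
       truth = list(up = sort(up), down = sort(down), top = sort(top),
                    overlap = sort(overlap)))
}
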