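# Ontogeny-ratio screening and the associated statistics. The ontogeny
# ratio of a genotype is mean young (day 1) daytime sleep divided by mean
# mature (day 4-5) daytime sleep; wild-type flies sit around 1.5-2.0 and a
# ratio of 1.2 or below calls a screen hit (loss of the juvenile sleep
# state). Young and mature flies are different individuals, so the ratio is
# a ratio of group means.

#' Compute the ontogeny ratio for one genotype
#'
#' ratio = mean(young daytime sleep) / mean(mature daytime sleep), per-fly
#' daytime sleep minutes in each age group. A mature group that never sleeps
#' gives an undefined ratio: it is flagged (not an error) so the genotype
#' can be excluded from hit ranking but still reported.
#'
#' @param young numeric vector of per-fly daytime sleep minutes, day-1 flies.
#' @param mature numeric vector of per-fly daytime sleep minutes, day-4-5
#'   flies.
#' @param genotype optional genotype label carried through.
#' @return An object of class `ontogeny_result`: `genotype`, `young`,
#'   `mature`, `young_mean`, `mature_mean`, `n_young`, `n_mature`, `ratio`
#'   (`NA` if undefined), `undefined`, and a `hit` slot filled by
#'   [call_screen_hits()].
#' @export
compute_ontogeny_ratio <- function(young, mature, genotype = NA_character_) {
  if (length(young) == 0 || length(mature) == 0)
    stop("both age groups must be non-empty", call. = FALSE)
  ym <- mean(young)
  mm <- mean(mature)
  undefined <- mm <= 0
  structure(list(
    genotype = genotype, young = young, mature = mature,
    young_mean = ym, mature_mean = mm,
    n_young = length(young), n_mature = length(mature),
    ratio = if (undefined) NA_real_ else ym / mm,
    undefined = undefined, hit = NA),
    class = "ontogeny_result")
}

#' @export
print.ontogeny_result <- function(x, ...) {
  cat(sprintf("<ontogeny_result> %s: ratio %s (young %.1f min, n=%d; mature %.1f min, n=%d)\n",
              x$genotype,
              if (x$undefined) "undefined" else sprintf("%.3f", x$ratio),
              x$young_mean, x$n_young, x$mature_mean, x$n_mature))
  invisible(x)
}

#' Call screen hits from ontogeny ratios
#'
#' A genotype is a hit when its ontogeny ratio is at or below the cutoff
#' (the cutoff is inclusive: "1.2 and below"). Genotypes with undefined
#' ratios or with fewer than `min_n` flies in either age group are excluded
#' from calling but reported with the reason. Output is sorted ascending by
#' ratio.
#'
#' @param results list of [compute_ontogeny_ratio()] objects.
#' @param cutoff hit cutoff on the ratio (default 1.2).
#' @param min_n minimum flies per age group (default 8, the screen's
#'   inclusion rule).
#' @return A `data.frame` with `genotype`, `n_young`, `n_mature`,
#'   `young_mean`, `mature_mean`, `ratio`, `eligible`, `reason` and `hit`
#'   (`NA` where ineligible), sorted ascending by ratio.
#' @export
call_screen_hits <- function(results, cutoff = 1.2, min_n = 8L) {
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "ontogeny_result"))
    reason <- ""
    if (r$undefined) reason <- "undefined ratio (mature mean 0)"
    else if (r$n_young < min_n || r$n_mature < min_n)
      reason <- sprintf("n below %d", min_n)
    data.frame(genotype = r$genotype, n_young = r$n_young,
               n_mature = r$n_mature, young_mean = r$young_mean,
               mature_mean = r$mature_mean, ratio = r$ratio,
               eligible = reason == "", reason = reason)
  })
  d <- do.call(rbind, rows)
  d$hit <- ifelse(d$eligible, d$ratio <= cutoff, NA)
  d[order(d$ratio, na.last = TRUE), , drop = FALSE]
}

# Two-sample t statistic; Student (pooled) or Welch. Returns statistic, df,
# two-tailed p, and a degenerate flag for zero-variance inputs.
.two_sample_t <- function(a, b, var_equal = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("each group needs n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (md == 0)
      return(list(statistic = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(statistic = sign(md) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- md / se
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

#' Holm-Sidak step-down adjustment
#'
#' Orders the raw p-values ascending and sets
#' `p_adj_(i) = max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`, capped at 1.
#' Adjusted values are monotone in rank and never below the raw p.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Multiple two-sample t tests with Holm-Sidak correction
#'
#' Runs a two-sample two-tailed t test for every (A, B) pair and applies the
#' Holm-Sidak step-down correction across the family. This is the screen's
#' workhorse for young-vs-mature contrasts across genotypes. Zero
#' within-group variance in both groups with equal means gives p = 1 by
#' convention (flagged degenerate).
#'
#' @param pairs named list; each element is a list with numeric vectors `a`
#'   and `b` (each n >= 2).
#' @param alpha family-wise significance level (default 0.05).
#' @param var_equal use the pooled-variance Student statistic (default TRUE,
#'   matching "multiple Student's t tests"); `FALSE` gives Welch.
#' @return A `data.frame` with `comparison`, `statistic`, `df`, `p`,
#'   `p_adj`, `alpha`, `significant` and `degenerate`.
#' @export
holm_sidak_ttests <- function(pairs, alpha = 0.05, var_equal = TRUE) {
  stopifnot(length(pairs) >= 1)
  labs <- names(pairs)
  if (is.null(labs)) labs <- paste0("pair", seq_along(pairs))
  rows <- lapply(pairs, function(pr)
    .two_sample_t(pr$a, pr$b, var_equal = var_equal))
  p <- vapply(rows, `[[`, numeric(1), "p")
  adj <- holm_sidak_adjust(p)
  data.frame(
    comparison = labs,
    statistic = vapply(rows, `[[`, numeric(1), "statistic"),
    df = vapply(rows, `[[`, numeric(1), "df"),
    p = p, p_adj = adj, alpha = alpha,
    significant = adj < alpha,
    degenerate = vapply(rows, `[[`, logical(1), "degenerate"),
    row.names = NULL)
}

#' Welch's unequal-variance t test
#'
#' Unpaired two-tailed t test with Welch's correction: the statistic uses
#' per-group variances and the Welch-Satterthwaite degrees of freedom. Two
#' zero-variance groups are handled by convention (p = 1 if means equal,
#' p = 0 with infinite statistic otherwise; flagged degenerate).
#'
#' @param a,b numeric samples, n >= 2 each.
#' @param alpha significance level.
#' @return A one-row `data.frame`: `statistic`, `df`, `p`, `alpha`,
#'   `significant`, `degenerate`.
#' @export
welch_ttest <- function(a, b, alpha = 0.05) {
  r <- .two_sample_t(a, b, var_equal = FALSE)
  data.frame(statistic = r$statistic, df = r$df, p = r$p, alpha = alpha,
             significant = r$p < alpha, degenerate = r$degenerate)
}

#' One-way ANOVA with Tukey's HSD
#'
#' Overall one-way ANOVA F test across three or more groups, followed by
#' Tukey honestly-significant-difference p-values for all pairwise
#' contrasts, using the studentized-range distribution with the pooled
#' within-group variance (Tukey-Kramer for unequal n).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param alpha significance level.
#' @return A list with `overall` (one-row `data.frame`: `F`, `df1`, `df2`,
#'   `p`) and `pairwise` (`data.frame` with `comparison`, `diff`, `q`,
#'   `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 3)
    stop("anova_tukey needs >= 3 groups (use a t test for two)",
         call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, vapply(groups, length, integer(1))), levels = labs)
  ow <- stats::oneway.test(x ~ g, var.equal = TRUE)
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  df2 <- sum(ns) - k
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) / df2
  pw <- utils::combn(k, 2)
  rows <- apply(pw, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[j] - means[i]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (se == 0) { if (d == 0) 0 else Inf } else abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    data.frame(comparison = paste(labs[j], "-", labs[i]),
               diff = d, q = q, p_adj = p, significant = p < alpha)
  })
  list(overall = data.frame(F = unname(ow$statistic),
                            df1 = unname(ow$parameter[1]),
                            df2 = unname(ow$parameter[2]),
                            p = ow$p.value),
       pairwise = do.call(rbind, rows))
}

#' Modifier-screen contrast between two genotypes
#'
#' For a modifier screen (co-expressing a second RNAi alongside the base
#' knockdown), compares the modified genotype's ontogeny result against the
#' base: reports the ratio difference, per-age Welch comparisons (young vs
#' young, mature vs mature), and a rescue call. "Rescue" requires the
#' modified ratio to exceed the base ratio and the modified genotype's
#' young-vs-mature contrast to regain significance.
#'
#' @param base,modified [compute_ontogeny_ratio()] objects from the same run.
#' @param alpha significance level for the rescue criterion.
#' @return A list: `ratio_delta`, `rescue`, `flagged` (TRUE when either
#'   ratio is undefined), `young_vs_mature_modified`, `young_contrast`,
#'   `mature_contrast` (Welch results).
#' @export
modifier_contrast <- function(base, modified, alpha = 0.05) {
  stopifnot(inherits(base, "ontogeny_result"),
            inherits(modified, "ontogeny_result"))
  flagged <- base$undefined || modified$undefined
  yvm <- welch_ttest(modified$young, modified$mature, alpha)
  out <- list(
    ratio_delta = if (flagged) NA_real_ else modified$ratio - base$ratio,
    flagged = flagged,
    young_vs_mature_modified = yvm,
    young_contrast = welch_ttest(modified$young, base$young, alpha),
    mature_contrast = welch_ttest(modified$mature, base$mature, alpha))
  out$rescue <- !flagged && modified$ratio > base$ratio && yvm$significant
  out
}
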