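test_that("the ontogeny ratio is the ratio of group means", {
  r <- compute_ontogeny_ratio(c(600, 600), c(400, 400))
  expect_equal(r$ratio, 1.5)
  expect_equal(compute_ontogeny_ratio(c(1, 2, 3), c(1, 2, 3))$ratio, 1)
  r2 <- compute_ontogeny_ratio(c(300, 350), c(650, 710))
  expect_equal(r2$ratio, 325 / 680)
  expect_error(compute_ontogeny_ratio(numeric(0), 1), "non-empty")
})

test_that("the ratio is scale-equivariant and zero-mature flagged", {
  set.seed(21)
  y <- runif(10, 100, 700); m <- runif(10, 100, 700)
  r1 <- compute_ontogeny_ratio(y, m)$ratio
  r2 <- compute_ontogeny_ratio(3.7 * y, 3.7 * m)$ratio
  expect_equal(r1, r2)
  und <- compute_ontogeny_ratio(c(100, 200), c(0, 0))
  expect_true(und$undefined)
  expect_true(is.na(und$ratio))
})

test_that("hit calling is inclusive at the cutoff and sorted by ratio", {
  mk <- function(g, ratio, n = 16) {
    compute_ontogeny_ratio(rep(ratio * 100, n), rep(100, n), genotype = g)
  }
  res <- list(mk("a", 1.21), mk("b", 1.0), mk("c", 1.2), mk("d", 1.75))
  tab <- call_screen_hits(res, cutoff = 1.2)
  expect_identical(tab$genotype, c("b", "c", "a", "d"))
  expect_identical(tab$hit, c(TRUE, TRUE, FALSE, FALSE))
  # all high ratios: zero hits
  expect_false(any(call_screen_hits(list(mk("x", 1.75), mk("y", 1.75)))$hit))
  # undefined and low-n genotypes are reported but not called
  low_n <- mk("low", 1.0, n = 4)
  und <- compute_ontogeny_ratio(c(10, 20), c(0, 0), genotype = "und")
  tab2 <- call_screen_hits(list(mk("ok", 1.0), low_n, und))
  expect_identical(tab2$eligible, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(tab2$hit[!tab2$eligible])))
})

test_that("Holm-Sidak adjustment matches the closed-form step-down", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(holm_sidak_adjust(0.03), 0.03)  # m = 1: identity
  set.seed(22)
  for (i in 1:50) {
    p <- runif(sample(2:10, 1))
    adj <- holm_sidak_adjust(p)
    # independent evaluation of the formula
    o <- order(p)
    ref <- pmin(1, cummax(sapply(seq_along(p), function(j)
      1 - (1 - p[o][j])^(length(p) - j + 1))))
    expect_equal(adj[o], ref, tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[o]) >= 0))
  }
})

test_that("holm_sidak_ttests runs the family and flags degenerates", {
  set.seed(23)
  pairs <- list(p1 = list(a = rnorm(10), b = rnorm(10, 3)),
                p2 = list(a = rnorm(10), b = rnorm(10)),
                const = list(a = rep(1, 5), b = rep(1, 5)))
  res <- holm_sidak_ttests(pairs)
  expect_identical(nrow(res), 3L)
  expect_true(res$significant[1])
  expect_true(res$degenerate[3])
  expect_equal(res$p[3], 1)
  expect_true(all(res$p_adj >= res$p))
  # identical groups in every pair: nothing significant
  x <- rnorm(8)
  same <- holm_sidak_ttests(list(a = list(a = x, b = x),
                                 b = list(a = x, b = x)))
  expect_false(any(same$significant))
  # Student statistic agrees with the reference implementation
  ref <- t.test(pairs$p1$a, pairs$p1$b, var.equal = TRUE)
  expect_equal(res$statistic[1], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p[1], ref$p.value, tolerance = 1e-10)
})

test_that("Welch test agrees with the reference implementation", {
  a <- c(1, 2, 3)
  r0 <- welch_ttest(a, a)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  deg <- welch_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_true(is.infinite(deg$statistic))
  set.seed(24)
  for (i in 1:100) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    mine <- welch_ttest(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA + Tukey matches aov/TukeyHSD and separates groups", {
  g <- list(a = c(0.01, -0.02, 0.005, 0.01),
            b = c(0.0, 0.02, -0.01, 0.005),
            c = c(10.01, 9.98, 10.02, 10.0))
  res <- anova_tukey(g)
  sig <- res$pairwise$significant
  names(sig) <- res$pairwise$comparison
  expect_false(sig[["b - a"]])
  expect_true(sig[["c - a"]])
  expect_true(sig[["c - b"]])
  # identical groups: F ~ 0, no significant pairs
  same <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same$overall$F, 0, tolerance = 1e-12)
  expect_false(any(same$pairwise$significant))
  expect_error(anova_tukey(list(a = 1:3, b = 1:3)), ">= 3 groups")
  set.seed(25)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    gs <- lapply(seq_len(k), function(j) rnorm(sample(4:12, 1), mean = j / 2))
    names(gs) <- letters[seq_len(k)]
    mine <- anova_tukey(gs)
    x <- unlist(gs)
    f <- factor(rep(names(gs), lengths(gs)), levels = names(gs))
    fit <- aov(x ~ f)
    ref <- TukeyHSD(fit)$f
    expect_equal(mine$pairwise$p_adj, unname(ref[, "p adj"]),
                 tolerance = 1e-8)
    ref_f <- summary(fit)[[1]]$`F value`[1]
    expect_equal(mine$overall$F, ref_f, tolerance = 1e-8)
  }
})

test_that("modifier contrasts flag rescue by the stated rule", {
  set.seed(26)
  base <- compute_ontogeny_ratio(rnorm(16, 270, 20), rnorm(16, 300, 20),
                                 genotype = "pdm3")     # ratio ~ 0.9
  resc <- compute_ontogeny_ratio(rnorm(16, 480, 20), rnorm(16, 300, 20),
                                 genotype = "pdm3+mod") # ratio ~ 1.6
  mc <- modifier_contrast(base, resc)
  expect_true(mc$rescue)
  expect_gt(mc$ratio_delta, 0)
  # identical genotypes: delta 0, no rescue
  mc0 <- modifier_contrast(base, base)
  expect_equal(mc0$ratio_delta, 0)
  expect_false(mc0$rescue)
  # undefined base propagates as flagged, never rescue
  und <- compute_ontogeny_ratio(c(10, 20, 15), c(0, 0, 0), genotype = "dead")
  mcu <- modifier_contrast(und, resc)
  expect_true(mcu$flagged)
  expect_false(mcu$rescue)
})

test_that("family-wise error under a small global null stays near alpha", {
  set.seed(27)
  reps <- 1000
  fwe <- mean(replicate(reps, {
    pairs <- lapply(1:6, function(i) list(a = rnorm(8), b = rnorm(8)))
    any(holm_sidak_ttests(pairs)$significant)
  }))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(fwe, 0.05 + 3 * se)
})
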