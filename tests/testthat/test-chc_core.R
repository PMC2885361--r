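test_that("informative markers need HV at least the reciprocal cohort size", {
  expect_true(select_informative(0.30, 4, 4))
  expect_false(select_informative(0.20, 4, 4))
  expect_true(select_informative(0.25, 4, 4))  # inclusive
  # the larger reciprocal of the two cohorts governs
  expect_false(select_informative(0.20, 10, 4))
  expect_true(select_informative(0.20, 10, 5))
  # missing HV: dropped by default, substitutable otherwise
  ann <- data.frame(heterozygosity = c(0.3, NA))
  expect_message(mask <- select_informative(ann, 4, 4),
                 "without heterozygosity")
  expect_identical(mask, c(TRUE, FALSE))
  mask2 <- select_informative(ann, 4, 4, na_action = "substitute",
                              fallback_het = c(0, 0.5))
  expect_identical(mask2, c(TRUE, TRUE))
})

test_that("markers with any absent call are removed from the analysis", {
  set.seed(42)
  calls <- matrix("AB", nrow = 10, ncol = 2)
  calls[1, 1] <- "NoCall"; calls[4, 2] <- "NoCall"; calls[9, 1] <- "NoCall"
  case <- make_cohort(list(calls[, 1], calls[, 2]))
  control <- make_cohort(list(rep("AA", 10), rep("AB", 10)))
  mask <- filter_complete_calls(case, control)
  expect_identical(sum(mask), 7L)
  expect_false(mask[1]); expect_false(mask[4]); expect_false(mask[9])
  # a NoCall in the control cohort also removes the marker
  mask2 <- filter_complete_calls(control, case)
  expect_identical(mask, mask2)
})

test_that("heterozygosity frequency is the fraction of AB calls", {
  expect_equal(heterozygosity_frequency(c("AB", "AA", "AB", "BB")), 0.5)
  expect_equal(heterozygosity_frequency(c("AA", "AA", "BB")), 0)
  expect_equal(heterozygosity_frequency(c("AB", "AB")), 1)
  expect_error(heterozygosity_frequency(character()), "empty")
  expect_error(heterozygosity_frequency(c("AB", "NoCall")), "NoCall")
})

test_that("delta is control minus case heterozygosity", {
  case <- make_cohort(list(c("AA", "AB", "AB"), c("AA", "AB", "AA")))
  control <- make_cohort(list(c("AB", "AB", "AA"), c("AA", "AB", "BB")))
  track <- delta_values(case, control, informative = rep(TRUE, 3),
                        retained = rep(TRUE, 3))
  expect_equal(track$delta, c(0.5 - 0, 1 - 1, 0 - 0.5))
  expect_true(all(track$delta >= -1 & track$delta <= 1))
  expect_equal(track$delta, track$het_control - track$het_case)
  # informative never exceeds retained
  track2 <- delta_values(case, control, informative = rep(TRUE, 3),
                         retained = c(TRUE, FALSE, TRUE))
  expect_false(track2$informative[2])
  expect_true(is.na(track2$delta[2]))
})

test_that("power-derived thresholds reproduce the published values", {
  expect_equal(as.numeric(suppressMessages(delta_threshold(4))), 0.5)
  expect_equal(as.numeric(suppressMessages(delta_threshold(10))), 0.3)
  unr <- attr(suppressMessages(delta_threshold(4)), "unrounded")
  expect_equal(unr, (qnorm(0.95) + qnorm(0.8)) * 0.3 * sqrt(2 / 4))
  expect_equal(as.numeric(suppressMessages(
    delta_threshold(4, round_threshold = FALSE))), unr)
})

test_that("threshold scales as sigma * sqrt(2/n) and errors on bad input", {
  dt <- function(...) as.numeric(suppressMessages(
    delta_threshold(..., round_threshold = FALSE)))
  expect_equal(dt(8, sigma = 0.6), 2 * dt(8, sigma = 0.3))
  expect_lt(dt(1e6), 1e-2)  # vanishes with large cohorts
  expect_gt(dt(4), dt(10))
  expect_error(suppressMessages(delta_threshold(1)), "at least 2")
  expect_warning(suppressMessages(delta_threshold(2, sigma = 0.5)),
                 ">= 1")
})

test_that("contiguous runs at or above both thresholds become regions", {
  r <- call_regions(make_track(rep(0.6, 5)), 0.5, 5)
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_snps, 5L)
  expect_equal(r$enrichment_score, 3.0)
  expect_identical(r$start, 1000L)
  expect_identical(r$end, 5000L)

  # one SNP short of the CPT
  expect_identical(nrow(call_regions(make_track(rep(0.6, 4)), 0.5, 5)), 0L)
  # comparisons are inclusive at the delta threshold
  expect_identical(nrow(call_regions(make_track(rep(0.5, 5)), 0.5, 5)), 1L)
  # a sub-threshold informative SNP breaks the run
  broken <- make_track(c(rep(0.6, 3), 0.2, rep(0.6, 3)))
  expect_identical(nrow(call_regions(broken, 0.5, 5)), 0L)
  # ... but a non-retained SNP in the same place is invisible
  bridged <- make_track(c(rep(0.6, 3), 0.2, rep(0.6, 3)),
                        retained = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                                     TRUE))
  r2 <- call_regions(bridged, 0.5, 5)
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$n_snps, 6L)
  # runs never cross a chromosome boundary
  split <- make_track(rep(0.6, 6), chromosome = rep(c("1", "2"), each = 3))
  expect_identical(nrow(call_regions(split, 0.5, 3)), 2L)
})

test_that("region calling matches the brute-force enumerator on fuzzed tracks", {
  set.seed(11)
  for (i in 1:300) {
    track <- random_track()
    delta_t <- sample(c(0.3, 0.4, 0.5), 1)
    cpt <- sample(2:6, 1)
    got <- call_regions(track, delta_t, cpt)
    want <- bf_call_regions(track, delta_t, cpt)
    got <- as.data.frame(got)[order(got$chromosome, got$start),
                              c("chromosome", "start", "end", "n_snps",
                                "enrichment_score")]
    want <- want[order(want$chromosome, want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("every called region satisfies its defining contracts", {
  set.seed(12)
  for (i in 1:50) {
    track <- random_track()
    delta_t <- sample(c(0.3, 0.5), 1)
    cpt <- sample(3:6, 1)
    r <- call_regions(track, delta_t, cpt)
    if (!nrow(r)) next
    expect_true(all(r$n_snps >= cpt))
    expect_true(all(vapply(r$deltas, min, 0) >= delta_t))
    expect_equal(r$enrichment_score, vapply(r$deltas, sum, 0))
    expect_true(all(r$enrichment_score >= r$n_snps * delta_t - 1e-9))
    expect_true(all(r$start <= r$end))
    expect_true(all(lengths(r$snp_ids) == r$n_snps))
  }
})

test_that("region counts are monotone in CPT and delta threshold", {
  set.seed(13)
  track <- make_track(round(runif(400, -0.2, 0.8), 2),
                      chromosome = rep(c("1", "2"), each = 200))
  counts <- vapply(3:6, function(cpt) nrow(call_regions(track, 0.4, cpt)),
                   0L)
  expect_true(all(diff(counts) <= 0))
  counts_dt <- vapply(c(0.3, 0.4, 0.5, 0.6),
                      function(dt) nrow(call_regions(track, dt, 5)), 0L)
  expect_true(all(diff(counts_dt) <= 0))
})

test_that("enrichment score sums the deltas of a region", {
  expect_equal(enrichment_score(rep(0.5, 5)), 2.5)
  expect_equal(enrichment_score(c(0.4, 0.45)), 0.85)
  expect_error(enrichment_score(numeric()), "empty")
})

test_that("regions rank by score, then SNP count, then coordinates", {
  r <- call_regions(make_track(
    c(rep(0.7, 5), 0.1, rep(0.5, 6), 0.1, rep(0.6, 5)),
    chromosome = rep("1", 18)), 0.5, 5)
  ranked <- rank_regions(r)
  expect_equal(ranked$enrichment_score, c(3.5, 3.0, 3.0))
  # tie at ES 3.0 broken by larger n_snps (6-SNP run of 0.5 first)
  expect_identical(ranked$n_snps, c(5L, 6L, 5L))
  expect_identical(nrow(rank_regions(r[0, ])), 0L)
  # equal ES and n_snps: earlier coordinate first
  r2 <- call_regions(make_track(c(rep(0.5, 5), 0.1, rep(0.5, 5))), 0.5, 5)
  ranked2 <- rank_regions(r2)
  expect_true(ranked2$start[1] < ranked2$start[2])
})

test_that("rolling windows average deltas over visible SNPs", {
  track <- make_track(c(0.1, 0.2, 0.3, 0.4, 0.5))
  win <- rolling_window_delta(track, window = 5, step = 1)
  expect_identical(nrow(win), 1L)
  expect_equal(win$mean_delta, 0.3)
  expect_equal(win$midpoint, (1000 + 5000) / 2)

  const <- rolling_window_delta(make_track(rep(0.4, 12)), 4, 2)
  expect_equal(const$mean_delta, rep(0.4, nrow(const)))

  # a window never exceeds the track maximum
  set.seed(14)
  for (i in 1:20) {
    tr <- random_track()
    w <- rolling_window_delta(tr, sample(2:5, 1), sample(1:3, 1))
    if (!nrow(w)) next
    expect_lte(max(w$mean_delta),
               max(tr$delta[tr$retained & tr$informative]) + 1e-12)
  }
  # window wider than the chromosome yields no windows
  expect_identical(nrow(rolling_window_delta(make_track(rep(0.4, 3)), 5)),
                   0L)
})

test_that("the fitted object reports thresholds, masks and ranked regions", {
  sim <- simulate_cohorts(sim_preset_recovery(seed = 5))
  fit <- suppressMessages(chc(sim$case, sim$control,
                              chc_params(delta_threshold = 0.4, cpt = 5)))
  expect_s3_class(fit, "chc")
  expect_identical(fit$n_case, 10L)
  expect_equal(fit$delta_threshold, 0.4)
  expect_equal(fit$delta_threshold_computed, 0.3)  # power formula at n=10
  expect_true(all(diff(fit$regions$enrichment_score) <= 0))
  expect_identical(fit$n_informative,
                   sum(fit$track$informative))
  expect_output(print(fit), "delta threshold: 0.40 \\[manual override\\]")
  s <- summary(fit)
  expect_s3_class(s, "summary.chc")
  expect_identical(s$n_regions, nrow(fit$regions))
})

test_that("identical inputs give byte-identical region tables", {
  sim <- simulate_cohorts(sim_preset_recovery(seed = 5))
  p <- chc_params(delta_threshold = 0.4, cpt = 5)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_regions(suppressMessages(chc(sim$case, sim$control, p))$regions,
                f1)
  write_regions(suppressMessages(chc(sim$case, sim$control, p))$regions,
                f2)
  expect_identical(readLines(f1), readLines(f2))
})
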