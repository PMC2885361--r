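# Evaluation of inferred-LOH regions against validated LOH markers or a
# simulated ground truth.

#' Evaluate inferred regions against LOH marker positions
#'
#' For every region the physical size (`end - start`) and the distance to
#' the nearest same-chromosome LOH marker are computed.  A region that
#' encompasses at least one marker has distance 0; otherwise the distance
#' is the minimum, over markers on the chromosome, of the distance to
#' either region end.  Regions on chromosomes without any LOH marker have
#' undefined distance and are excluded from the distance summaries with a
#' warning.
#'
#' @param regions A region table ([call_regions()] output or any data frame
#'   with `chromosome`, `start`, `end`).
#' @param loh_snps Data frame with columns `chromosome` and `position`
#'   giving the validated LOH marker positions.
#' @return An object of class `chc_region_eval`: list with a per-region
#'   data frame (`size_bp`, `distance_bp`, `encompasses_loh`) and the
#'   cohort summary `n_regions`, `mean_size_bp`, `fraction_within_100kb`
#'   (distance <= 100,000 bp, inclusive) and `mean_distance_bp`.
#' @export
evaluate_regions <- function(regions, loh_snps) {
  n <- nrow(regions)
  size <- regions$end - regions$start
  dist <- rep(NA_real_, n)
  enc <- rep(FALSE, n)
  loh_snps$chromosome <- normalize_chromosome(loh_snps$chromosome)
  for (i in seq_len(n)) {
    p <- loh_snps$position[loh_snps$chromosome == regions$chromosome[i]]
    if (!length(p)) next
    if (any(p >= regions$start[i] & p <= regions$end[i])) {
      dist[i] <- 0
      enc[i] <- TRUE
    } else {
      dist[i] <- min(pmin(abs(p - regions$start[i]),
                          abs(p - regions$end[i])))
    }
  }
  if (any(is.na(dist)) && n > 0) {
    warning(sum(is.na(dist)), " region(s) on chromosomes without LOH ",
            "markers excluded from distance summaries")
  }
  per_region <- data.frame(chromosome = regions$chromosome,
                           start = regions$start, end = regions$end,
                           size_bp = size, distance_bp = dist,
                           encompasses_loh = enc, stringsAsFactors = FALSE)
  structure(list(regions = per_region,
                 n_regions = n,
                 mean_size_bp = if (n) mean(size) else NA_real_,
                 fraction_within_100kb =
                   if (any(!is.na(dist))) mean(dist[!is.na(dist)] <= 1e5)
                   else NA_real_,
                 mean_distance_bp =
                   if (any(!is.na(dist))) mean(dist[!is.na(dist)])
                   else NA_real_),
            class = "chc_region_eval")
}

#' @export
print.chc_region_eval <- function(x, ...) {
  cat(sprintf("Region evaluation: %d region(s)\n", x$n_regions))
  cat(sprintf("  mean size: %.0f bp\n", x$mean_size_bp))
  cat(sprintf("  within 100 kb of LOH: %.0f%%\n",
              100 * x$fraction_within_100kb))
  cat(sprintf("  mean distance from LOH: %.0f bp\n", x$mean_distance_bp))
  invisible(x)
}

#' Merge per-sample region lists into independent regions
#'
#' Takes one region list per sample, forms the interval union per
#' chromosome (1-based inclusive coordinates; intervals merge when their
#' covered base pairs are contiguous, i.e. overlapping or book-ended) and
#' annotates every merged region with the number of distinct samples
#' contributing at least one interval to it.
#'
#' @param regions_by_sample A list of data frames, each with `chromosome`,
#'   `start`, `end`.
#' @return Data frame with `chromosome`, `start`, `end`, `support`; the
#'   number of independent merged regions is `nrow()` of the result.
#' @export
overlap_count <- function(regions_by_sample) {
  stopifnot(length(regions_by_sample) >= 1)
  all <- do.call(rbind, lapply(seq_along(regions_by_sample), function(s) {
    r <- regions_by_sample[[s]]
    if (is.null(r) || !nrow(r)) return(NULL)
    data.frame(chromosome = normalize_chromosome(r$chromosome),
               start = r$start, end = r$end, sample = s,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), support = integer()))
  }
  res <- list()
  for (chrom in chrom_levels(all$chromosome)) {
    a <- all[all$chromosome == chrom, , drop = FALSE]
    if (!nrow(a)) next
    a <- a[order(a$start, a$end), , drop = FALSE]
    cur_start <- a$start[1]; cur_end <- a$end[1]
    members <- a$sample[1]
    flush <- function(start, end, members) {
      data.frame(chromosome = chrom, start = start, end = end,
                 support = length(unique(members)),
                 stringsAsFactors = FALSE)
    }
    out <- list()
    for (i in seq_len(nrow(a))[-1]) {
      if (a$start[i] <= cur_end + 1L) {
        cur_end <- max(cur_end, a$end[i])
        members <- c(members, a$sample[i])
      } else {
        out[[length(out) + 1L]] <- flush(cur_start, cur_end, members)
        cur_start <- a$start[i]; cur_end <- a$end[i]
        members <- a$sample[i]
      }
    }
    out[[length(out) + 1L]] <- flush(cur_start, cur_end, members)
    res[[chrom]] <- do.call(rbind, out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlation and two-sample comparison for region evaluations
#'
#' Convenience wrapper around [stats::cor.test()] (Pearson) and
#' [stats::t.test()] used to relate region properties (e.g. enrichment
#' score, CPT) to evaluation outcomes (e.g. distance to validated LOH), and
#' to compare a property between two groups of markers (e.g. heterozygosity
#' of LOH markers inside vs adjacent to candidate regions).
#'
#' @param x Numeric vector.
#' @param y Optional numeric vector paired with `x`; triggers the Pearson
#'   correlation (requires at least 3 complete pairs).
#' @param group Optional two-level factor parallel to `x`; triggers the
#'   two-sample t-test.
#' @param var_equal Assume equal variances in the t-test (classical
#'   Student's test, the default); `FALSE` gives Welch's test.
#' @return A list of class `chc_stats` with components `correlation`
#'   (`r`, `p_value`, `n`, possibly `note` when degenerate) and/or `t_test`
#'   (`statistic`, `p_value`, `estimate`).
#' @export
evaluation_statistics <- function(x, y = NULL, group = NULL,
                                  var_equal = TRUE) {
  out <- list()
  if (!is.null(y)) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) stop("correlation requires at least 3 complete pairs")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      out$correlation <- list(r = NA_real_, p_value = NA_real_,
                              n = sum(ok),
                              note = "degenerate variance: correlation undefined")
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      out$correlation <- list(r = unname(ct$estimate),
                              p_value = ct$p.value, n = sum(ok))
    }
  }
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) != 2) stop("group must have exactly 2 levels")
    if (min(table(group)) < 2) stop("t-test requires >= 2 values per group")
    tt <- stats::t.test(x ~ group, var.equal = var_equal)
    out$t_test <- list(statistic = unname(tt$statistic),
                       p_value = tt$p.value,
                       estimate = unname(diff(rev(tt$estimate))))
  }
  if (!length(out)) stop("supply y (correlation) and/or group (t-test)")
  structure(out, class = "chc_stats")
}

#' Sensitivity and precision of inferred regions against a ground truth
#'
#' A planted segment counts as recovered when at least one inferred region
#' overlaps it (same chromosome, at least one shared base pair); an
#' inferred region counts as true when it overlaps at least one planted
#' segment.
#'
#' @param regions Region table with `chromosome`, `start`, `end`.
#' @param truth Ground-truth segment table with the same columns (e.g. the
#'   `truth` element of [simulate_cohorts()]).
#' @return List with `sensitivity`, `precision`, `n_regions`, `n_truth`.
#'   `precision` is `NA` when no regions were inferred; `sensitivity` is
#'   `NA` when the truth is empty.
#' @export
region_recovery <- function(regions, truth) {
  overlaps <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chromosome == a$chromosome[i] &
            b$start <= a$end[i] & b$end >= a$start[i])
    }, logical(1))
  }
  sens <- if (nrow(truth)) mean(overlaps(truth, regions)) else NA_real_
  prec <- if (nrow(regions)) mean(overlaps(regions, truth)) else NA_real_
  list(sensitivity = sens, precision = prec,
       n_regions = nrow(regions), n_truth = nrow(truth))
}
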