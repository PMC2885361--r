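# Cohort heterozygosity comparison: informative-marker selection, delta
# values, power-derived delta threshold, contiguous-run region calling,
# enrichment scoring and rolling-window summaries.

#' Parameters for a cohort heterozygosity comparison
#'
#' @param alpha One-sided significance level of the power analysis.
#' @param power Target statistical power (1 - beta).
#' @param sigma Assumed standard deviation of the per-SNP heterozygosity
#'   difference between cohorts.
#' @param delta_threshold Optional manual delta threshold in (0, 1\];
#'   overrides the power-derived value when set.
#' @param cpt Contiguous point threshold: the minimum number of consecutive
#'   suggestive SNPs required to call a region.
#' @param round_threshold Round the power-derived threshold to one decimal
#'   place (the unrounded value is kept alongside).
#' @param threshold_n Which cohort size enters the power formula: the case
#'   cohort (default) or the smaller of the two cohorts.
#' @return A list of class `chc_params`.
#' @export
chc_params <- function(alpha = 0.05, power = 0.80, sigma = 0.3,
                       delta_threshold = NULL, cpt = 5L,
                       round_threshold = TRUE,
                       threshold_n = c("case", "min")) {
  threshold_n <- match.arg(threshold_n)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, sigma > 0,
            cpt >= 1)
  if (!is.null(delta_threshold)) {
    stopifnot(delta_threshold > 0, delta_threshold <= 1)
  }
  structure(list(alpha = alpha, power = power, sigma = sigma,
                 delta_threshold = delta_threshold, cpt = as.integer(cpt),
                 round_threshold = round_threshold,
                 threshold_n = threshold_n),
            class = "chc_params")
}

#' Power-derived delta threshold
#'
#' Computes the minimum heterozygosity-frequency difference detectable with
#' the requested power in a one-sided two-sample comparison of cohorts of
#' size `n` under a normal approximation with common standard deviation
#' `sigma`:
#' \deqn{\Delta_T = (z_{1-\alpha} + z_{power})\,\sigma\sqrt{2/n}.}
#'
#' With the defaults (`sigma = 0.3`, `alpha = 0.05`, `power = 0.8`) the
#' rounded threshold is 0.5 for `n = 4` and 0.3 for `n = 10`.
#'
#' @param n Cohort sample size (at least 2).
#' @param sigma,alpha,power See [chc_params()].
#' @param round_threshold Round the result to one decimal place.
#' @return The threshold, with the unrounded value in attribute
#'   `"unrounded"`.  The unrounded value is also reported via `message()`.
#' @export
#' @examples
#' delta_threshold(4)   # 0.5
#' delta_threshold(10)  # 0.3
delta_threshold <- function(n, sigma = 0.3, alpha = 0.05, power = 0.80,
                            round_threshold = TRUE) {
  if (n < 2) stop("n must be at least 2")
  stopifnot(sigma > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  raw <- (stats::qnorm(1 - alpha) + stats::qnorm(power)) * sigma * sqrt(2 / n)
  value <- if (round_threshold) round(raw, 1) else raw
  message(sprintf("delta threshold: %.4f unrounded%s", raw,
                  if (round_threshold) sprintf(", %.1f rounded", value)
                  else ""))
  if (value >= 1) {
    warning("delta threshold >= 1: no SNP can be suggestive of LOH")
  }
  structure(value, unrounded = raw)
}

#' Select informative markers
#'
#' A SNP is informative when its population heterozygosity value is high
#' enough that at least one heterozygous genotype is expected in each
#' cohort, i.e. HV >= max(1/n_case, 1/n_control).
#'
#' @param annotation Annotation data frame with a `heterozygosity` column
#'   (or a numeric vector of heterozygosity values).
#' @param n_case,n_control Cohort sample sizes.
#' @param na_action What to do with SNPs lacking a heterozygosity value:
#'   `"drop"` marks them non-informative (logged), `"substitute"` uses
#'   `fallback_het` (e.g. the observed control heterozygosity) in the test.
#' @param fallback_het Numeric vector, parallel to the annotation, used when
#'   `na_action = "substitute"`.
#' @return Logical mask, one element per SNP.
#' @export
select_informative <- function(annotation, n_case, n_control,
                               na_action = c("drop", "substitute"),
                               fallback_het = NULL) {
  na_action <- match.arg(na_action)
  stopifnot(n_case >= 1, n_control >= 1)
  hv <- if (is.data.frame(annotation)) annotation$heterozygosity
        else as.numeric(annotation)
  if (anyNA(hv)) {
    if (na_action == "substitute") {
      if (is.null(fallback_het)) stop("fallback_het required to substitute")
      hv[is.na(hv)] <- fallback_het[is.na(hv)]
    } else {
      message(sum(is.na(hv)),
              " SNP(s) without heterozygosity value marked non-informative")
    }
  }
  cutoff <- max(1 / n_case, 1 / n_control)
  !is.na(hv) & hv >= cutoff
}

#' Retain only fully genotyped markers
#'
#' A SNP is retained only when every sample in both cohorts has a genotype
#' call; markers with any absent call are removed from the analysis.
#'
#' @param case,control Aligned [cohort_genotypes()] objects.
#' @return Logical mask, one element per shared SNP.
#' @export
filter_complete_calls <- function(case, control) {
  stopifnot(nrow(case$calls) == nrow(control$calls))
  rowSums(case$calls == "NoCall") == 0L &
    rowSums(control$calls == "NoCall") == 0L
}

#' Heterozygosity frequency of a set of calls
#'
#' @param calls Character vector of genotype calls without `NoCall` (absent
#'   calls must be filtered upstream).
#' @return Fraction of calls that are heterozygous (`AB`).
#' @export
heterozygosity_frequency <- function(calls) {
  if (!length(calls)) stop("empty call list")
  if (any(calls == "NoCall")) {
    stop("NoCall present; remove markers with absent calls first")
  }
  mean(calls == "AB")
}

#' Per-SNP heterozygosity deltas
#'
#' For every retained SNP the heterozygosity frequency is computed in each
#' cohort and their difference `delta = het_control - het_case` recorded.
#' Positive deltas indicate a heterozygosity deficit in the case cohort and
#' are the only ones ever suggestive of LOH.  Non-retained SNPs carry `NA`
#' frequencies; the `informative` flag is restricted to retained SNPs.
#'
#' @param case,control Aligned [cohort_genotypes()] objects.
#' @param informative Logical mask from [select_informative()].
#' @param retained Logical mask from [filter_complete_calls()].
#' @return A `chc_delta_track` data frame ordered by (chromosome, position)
#'   with columns `snp_id`, `chromosome`, `position`, `het_case`,
#'   `het_control`, `delta`, `informative`, `retained`.
#' @export
delta_values <- function(case, control, informative, retained) {
  ann <- case$annotation
  stopifnot(length(informative) == nrow(ann), length(retained) == nrow(ann))
  het_case <- rowMeans(case$calls == "AB")
  het_control <- rowMeans(control$calls == "AB")
  het_case[!retained] <- NA_real_
  het_control[!retained] <- NA_real_
  track <- data.frame(snp_id = ann$snp_id,
                      chromosome = ann$chromosome,
                      position = ann$position,
                      het_case = het_case,
                      het_control = het_control,
                      delta = het_control - het_case,
                      informative = informative & retained,
                      retained = retained,
                      stringsAsFactors = FALSE)
  class(track) <- c("chc_delta_track", "data.frame")
  track
}

empty_regions <- function() {
  structure(data.frame(chromosome = character(), start = integer(),
                       end = integer(), n_snps = integer(),
                       enrichment_score = numeric(),
                       first_snp_id = character(),
                       last_snp_id = character(),
                       snp_ids = I(list()), deltas = I(list()),
                       stringsAsFactors = FALSE),
            class = c("chc_regions", "data.frame"))
}

#' Call inferred-LOH regions from a delta track
#'
#' Within each chromosome, maximal runs of consecutive retained informative
#' SNPs whose delta is at least `delta_t`, of length at least `cpt`, are
#' reported as inferred-LOH regions.  Non-retained and non-informative SNPs
#' are invisible to contiguity: they neither extend nor break a run.  Runs
#' never cross a chromosome boundary.
#'
#' @param track A delta track from [delta_values()].
#' @param delta_t Delta threshold (> 0); deltas are compared inclusively.
#' @param cpt Contiguous point threshold (>= 1), also inclusive.
#' @return A `chc_regions` data frame with one row per region: `chromosome`,
#'   `start`/`end` (positions of the first and last SNP, 1-based inclusive),
#'   `n_snps`, `enrichment_score` (sum of deltas), first/last SNP IDs, and
#'   list columns `snp_ids` and `deltas`.
#' @export
call_regions <- function(track, delta_t, cpt) {
  stopifnot(delta_t > 0, cpt >= 1)
  cpt <- as.integer(cpt)
  vis <- track[track$retained & track$informative, , drop = FALSE]
  out <- empty_regions()
  if (!nrow(vis)) return(out)
  rows <- vector("list", 8L)
  n_out <- 0L
  for (chrom in unique(vis$chromosome)) {
    v <- vis[vis$chromosome == chrom, , drop = FALSE]
    sug <- !is.na(v$delta) & v$delta >= delta_t
    r <- rle(sug)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= cpt)
    for (k in keep) {
      idx <- starts[k]:ends[k]
      n_out <- n_out + 1L
      if (n_out > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[n_out]] <- list(chromosome = chrom,
                            start = v$position[idx[1L]],
                            end = v$position[idx[length(idx)]],
                            n_snps = length(idx),
                            enrichment_score = sum(v$delta[idx]),
                            first_snp_id = v$snp_id[idx[1L]],
                            last_snp_id = v$snp_id[idx[length(idx)]],
                            snp_ids = v$snp_id[idx],
                            deltas = v$delta[idx])
    }
  }
  if (!n_out) return(out)
  rows <- rows[seq_len(n_out)]
  res <- data.frame(
    chromosome = vapply(rows, `[[`, "", "chromosome"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    n_snps = vapply(rows, `[[`, 0L, "n_snps"),
    enrichment_score = vapply(rows, `[[`, 0, "enrichment_score"),
    first_snp_id = vapply(rows, `[[`, "", "first_snp_id"),
    last_snp_id = vapply(rows, `[[`, "", "last_snp_id"),
    stringsAsFactors = FALSE)
  res$snp_ids <- I(lapply(rows, `[[`, "snp_ids"))
  res$deltas <- I(lapply(rows, `[[`, "deltas"))
  class(res) <- c("chc_regions", "data.frame")
  res
}

#' Enrichment score of a region
#'
#' The enrichment score is the sum of the delta values inside an
#' inferred-LOH region; higher scores predict closer proximity to true LOH.
#'
#' @param deltas Non-empty numeric vector of per-SNP deltas.
#' @return The sum of `deltas`.
#' @export
enrichment_score <- function(deltas) {
  if (!length(deltas)) stop("empty delta list")
  sum(deltas)
}

#' Rank regions by enrichment score
#'
#' Descending by enrichment score; ties broken by larger SNP count, then by
#' (chromosome, start) so the order is a deterministic total order.
#'
#' @param regions A `chc_regions` data frame.
#' @return The same regions, reordered.
#' @export
rank_regions <- function(regions) {
  if (!nrow(regions)) return(regions)
  ord <- order(-regions$enrichment_score, -regions$n_snps,
               chrom_factor(regions$chromosome), regions$start)
  out <- regions[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rolling-window summary of a delta track
#'
#' Averages deltas over sliding windows of consecutive retained informative
#' SNPs within each chromosome, for visualisation of candidate loci.
#'
#' @param track A delta track from [delta_values()].
#' @param window Window width in SNPs (>= 1).
#' @param step Step between window starts in SNPs (>= 1).
#' @return Data frame with columns `chromosome`, `midpoint` (mean of the
#'   first and last SNP position), `mean_delta`, `start`, `end`.
#'   Chromosomes with fewer SNPs than `window` contribute no windows.
#' @export
rolling_window_delta <- function(track, window, step = 1L) {
  stopifnot(window >= 1, step >= 1)
  window <- as.integer(window); step <- as.integer(step)
  vis <- track[track$retained & track$informative, , drop = FALSE]
  res <- list()
  for (chrom in unique(vis$chromosome)) {
    v <- vis[vis$chromosome == chrom, , drop = FALSE]
    n <- nrow(v)
    if (n < window) next
    starts <- seq.int(1L, n - window + 1L, by = step)
    lasts <- starts + window - 1L
    cs <- cumsum(c(0, v$delta))
    res[[chrom]] <- data.frame(
      chromosome = chrom,
      midpoint = (v$position[starts] + v$position[lasts]) / 2,
      mean_delta = (cs[lasts + 1L] - cs[starts]) / window,
      start = v$position[starts],
      end = v$position[lasts],
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(chromosome = character(), midpoint = numeric(),
                      mean_delta = numeric(), start = integer(),
                      end = integer()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fit a cohort heterozygosity comparison
#'
#' Runs the full method on an unmatched case and control cohort: the
#' cohorts are aligned on shared SNPs, markers with absent calls are
#' removed, informative markers are selected by population heterozygosity,
#' per-SNP deltas `het_control - het_case` are computed, a delta threshold
#' is derived by power analysis (or taken from
#' `params$delta_threshold`), and contiguous runs of at least `params$cpt`
#' suggestive SNPs are reported as inferred-LOH regions ranked by
#' enrichment score.
#'
#' @param case,control [cohort_genotypes()] objects (need not be aligned).
#' @param params A [chc_params()] object.
#' @param na_action,fallback_het Passed to [select_informative()]; by
#'   default SNPs without a heterozygosity value are dropped.
#' @return An object of class `chc` with components `track` (the per-SNP
#'   delta track), `regions` (ranked region table), `delta_threshold`
#'   (effective), `delta_threshold_computed` and
#'   `delta_threshold_unrounded`, cohort sizes and marker counts, and the
#'   parameters used.
#' @seealso [call_regions()], [delta_threshold()], [write_regions()]
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_preset_recovery(seed = 1))
#' fit <- chc(sim$case, sim$control,
#'            chc_params(delta_threshold = 0.4, cpt = 5))
#' fit
chc <- function(case, control, params = chc_params(),
                na_action = c("drop", "substitute"), fallback_het = NULL) {
  stopifnot(inherits(params, "chc_params"))
  na_action <- match.arg(na_action)
  aligned <- align_cohorts(case, control)
  case <- aligned$case; control <- aligned$control
  n_case <- length(case$samples)
  n_control <- length(control$samples)

  retained <- filter_complete_calls(case, control)
  if (na_action == "substitute" && is.null(fallback_het)) {
    fallback_het <- rowMeans(control$calls == "AB")
  }
  informative <- select_informative(case$annotation, n_case, n_control,
                                    na_action = na_action,
                                    fallback_het = fallback_het)

  n_threshold <- switch(params$threshold_n,
                        case = n_case,
                        min = min(n_case, n_control))
  computed <- withCallingHandlers(
    delta_threshold(n_threshold, sigma = params$sigma, alpha = params$alpha,
                    power = params$power,
                    round_threshold = params$round_threshold),
    message = function(m) invokeRestart("muffleMessage"))
  effective <- if (is.null(params$delta_threshold)) as.numeric(computed)
               else params$delta_threshold

  track <- delta_values(case, control, informative, retained)
  regions <- rank_regions(call_regions(track, effective, params$cpt))

  structure(list(params = params,
                 n_case = n_case, n_control = n_control,
                 n_snps = nrow(track),
                 n_retained = sum(retained),
                 n_informative = sum(track$informative),
                 delta_threshold = effective,
                 delta_threshold_computed = as.numeric(computed),
                 delta_threshold_unrounded = attr(computed, "unrounded"),
                 track = track, regions = regions,
                 call = match.call()),
            class = "chc")
}

#' @export
print.chc <- function(x, ...) {
  cat("Cohort heterozygosity comparison\n")
  cat(sprintf("  cohorts: %d case, %d control samples; %d shared SNPs\n",
              x$n_case, x$n_control, x$n_snps))
  cat(sprintf("  retained (complete calls): %d; informative: %d\n",
              x$n_retained, x$n_informative))
  over <- !is.null(x$params$delta_threshold)
  cat(sprintf(
    "  delta threshold: %.2f%s (power formula: %.2f, unrounded %.4f)\n",
    x$delta_threshold, if (over) " [manual override]" else "",
    x$delta_threshold_computed, x$delta_threshold_unrounded))
  cat(sprintf("  contiguous point threshold: %d\n", x$params$cpt))
  cat(sprintf("  inferred-LOH regions: %d\n", nrow(x$regions)))
  if (nrow(x$regions)) {
    top <- utils::head(x$regions, 3)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s:%d-%d  n_snps=%d  ES=%.2f\n",
                  top$chromosome[i], top$start[i], top$end[i],
                  top$n_snps[i], top$enrichment_score[i]))
    }
  }
  invisible(x)
}

#' @export
summary.chc <- function(object, ...) {
  r <- object$regions
  structure(list(fit = object,
                 n_regions = nrow(r),
                 es_range = if (nrow(r)) range(r$enrichment_score)
                            else c(NA_real_, NA_real_),
                 mean_size_bp = if (nrow(r)) mean(r$end - r$start)
                                else NA_real_,
                 regions = utils::head(
                   r[c("chromosome", "start", "end", "n_snps",
                       "enrichment_score")], 10)),
            class = "summary.chc")
}

#' @export
print.summary.chc <- function(x, ...) {
  print(x$fit)
  if (x$n_regions) {
    cat(sprintf("  enrichment scores: %.2f to %.2f; mean size %.0f bp\n",
                x$es_range[1], x$es_range[2], x$mean_size_bp))
    cat("  top regions:\n")
    print(x$regions, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the rolling-window delta profile of a fit
#'
#' Draws the windowed mean delta along one chromosome with SNP positions as
#' a rug, the delta threshold as a horizontal line, and inferred-LOH
#' regions shaded.
#'
#' @param x A `chc` object.
#' @param chromosome Chromosome to plot; defaults to the chromosome of the
#'   top-ranked region (or the first chromosome if no regions were called).
#' @param window,step Rolling-window width and step, in SNPs.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return The windowed data, invisibly.
#' @export
plot.chc <- function(x, chromosome = NULL, window = 10L, step = 1L, ...) {
  if (is.null(chromosome)) {
    chromosome <- if (nrow(x$regions)) x$regions$chromosome[1]
                  else x$track$chromosome[1]
  }
  win <- rolling_window_delta(x$track, window, step)
  win <- win[win$chromosome == chromosome, , drop = FALSE]
  vis <- x$track[x$track$informative & x$track$chromosome == chromosome, ]
  graphics::plot(win$midpoint, win$mean_delta, type = "l",
                 xlab = sprintf("position on chromosome %s (bp)", chromosome),
                 ylab = sprintf("mean delta (%d-SNP window)", window),
                 ylim = range(c(win$mean_delta, 0, x$delta_threshold)), ...)
  graphics::rug(vis$position)
  graphics::abline(h = x$delta_threshold, lty = 2)
  reg <- x$regions[x$regions$chromosome == chromosome, , drop = FALSE]
  if (nrow(reg)) {
    graphics::rect(reg$start, graphics::par("usr")[3], reg$end,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  invisible(win)
}
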