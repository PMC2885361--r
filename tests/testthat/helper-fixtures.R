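# Fixture builders and independent brute-force oracles used across tests.

# Build a tiny cohort from per-SNP call strings (one string per sample).
make_cohort <- function(calls_by_sample, chromosome = NULL, position = NULL,
                        hv = NULL, snp_id = NULL) {
  m <- do.call(cbind, calls_by_sample)
  n <- nrow(m)
  ann <- data.frame(
    snp_id = if (is.null(snp_id)) sprintf("rs%d", seq_len(n)) else snp_id,
    chromosome = if (is.null(chromosome)) rep("1", n) else chromosome,
    position = if (is.null(position)) seq_len(n) * 100L else position,
    heterozygosity = if (is.null(hv)) rep(0.4, n) else hv,
    stringsAsFactors = FALSE)
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  }
  suppressMessages(cohort_genotypes(ann, m))
}

# Build a delta track directly (for region-calling tests).
make_track <- function(delta, chromosome = NULL, position = NULL,
                       informative = TRUE, retained = TRUE) {
  n <- length(delta)
  retained <- rep_len(retained, n)
  informative <- rep_len(informative, n) & retained
  tr <- data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    chromosome = if (is.null(chromosome)) rep("1", n) else chromosome,
    position = if (is.null(position)) seq_len(n) * 1000L else position,
    het_case = NA_real_, het_control = NA_real_,
    delta = delta, informative = informative, retained = retained,
    stringsAsFactors = FALSE)
  class(tr) <- c("chc_delta_track", "data.frame")
  tr
}

# Independent quadratic oracle for region calling: enumerate every
# contiguous window of visible SNPs and keep qualifying maximal ones.
bf_call_regions <- function(track, delta_t, cpt) {
  vis <- track[track$retained & track$informative, , drop = FALSE]
  out <- list()
  for (chrom in unique(vis$chromosome)) {
    v <- vis[vis$chromosome == chrom, , drop = FALSE]
    n <- nrow(v)
    ok <- v$delta >= delta_t
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1 < cpt) next
        if (!all(ok[i:j])) next
        maximal <- (i == 1 || !ok[i - 1]) && (j == n || !ok[j + 1])
        if (!maximal) next
        out[[length(out) + 1L]] <- data.frame(
          chromosome = chrom, start = v$position[i], end = v$position[j],
          n_snps = j - i + 1L, enrichment_score = sum(v$delta[i:j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      enrichment_score = numeric()))
  }
  do.call(rbind, out)
}

# Random delta track for fuzzing.
random_track <- function() {
  n <- sample(5:40, 1)
  n_chrom <- sample(1:3, 1)
  make_track(
    delta = round(runif(n, -0.4, 0.9), 2),
    chromosome = sort(sample(as.character(seq_len(n_chrom)), n,
                             replace = TRUE)),
    informative = runif(n) > 0.15,
    retained = runif(n) > 0.1)
}

# Coordinate-sweep oracle for interval merging with sample support.
bf_overlap <- function(regions_by_sample, max_pos = 400L) {
  chroms <- unique(unlist(lapply(regions_by_sample,
                                 function(r) r$chromosome)))
  out <- list()
  for (chrom in sort(chroms)) {
    covered <- matrix(FALSE, nrow = length(regions_by_sample),
                      ncol = max_pos)
    for (s in seq_along(regions_by_sample)) {
      r <- regions_by_sample[[s]]
      r <- r[r$chromosome == chrom, , drop = FALSE]
      for (i in seq_len(nrow(r))) covered[s, r$start[i]:r$end[i]] <- TRUE
    }
    any_cov <- colSums(covered) > 0
    r <- rle(any_cov)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      span <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom, start = starts[k], end = ends[k],
        support = sum(rowSums(covered[, span, drop = FALSE]) > 0),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), support = integer()))
  }
  do.call(rbind, out)
}

# Random per-sample interval lists for overlap fuzzing.
random_interval_sets <- function(max_pos = 400L) {
  n_samples <- sample(1:4, 1)
  lapply(seq_len(n_samples), function(s) {
    k <- sample(0:4, 1)
    if (!k) {
      return(data.frame(chromosome = character(), start = integer(),
                        end = integer()))
    }
    start <- sample(seq_len(max_pos - 20L), k)
    data.frame(chromosome = sample(c("1", "2"), k, replace = TRUE),
               start = start,
               end = start + sample(1:19, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# A noiseless config for forced-outcome simulator checks.
quiet_config <- function(..., seed = 1L) {
  simulation_config(..., missing_rate = 0, error_rate = 0, seed = seed)
}
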