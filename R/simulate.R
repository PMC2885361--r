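# Hardy-Weinberg cohort simulator with planted copy-neutral LOH segments.

#' Configure a cohort simulation
#'
#' Describes a synthetic SNP-array experiment: a genome of evenly
#' interspersed SNPs with annotated population heterozygosity values,
#' case and control cohorts drawn under Hardy-Weinberg equilibrium, and
#' optional planted copy-neutral LOH segments in which heterozygous case
#' calls are converted to homozygotes.
#'
#' Each SNP's heterozygosity value HV is drawn uniformly from `hv_range`
#' and converted to a minor allele frequency p solving `2p(1-p) = HV`
#' (taking p <= 0.5), so the control-cohort heterozygosity is an unbiased
#' estimate of HV.  Inter-SNP gaps are uniform on `[1, 2*gap_mean - 1]` bp.
#' Symmetric genotyping errors (a call replaced by one of the other two
#' categories) and missing calls (`NoCall`) are applied last.
#'
#' @param n_chromosomes Number of chromosomes (labelled `"1"`, `"2"`, ...).
#' @param n_snps SNPs per chromosome.
#' @param gap_mean Mean inter-SNP gap in base pairs.
#' @param hv_range Range of the uniform HV distribution; the upper bound
#'   must not exceed 0.5 (no real allele frequency exists above it).
#' @param n_case,n_control Cohort sizes.
#' @param segments Planted LOH segments: a data frame with columns
#'   `chromosome` (integer index), `start_index` (first SNP of the segment,
#'   1-based within the chromosome), `n_snps`, `affected_fraction` (share
#'   of case samples carrying the event) and `penetrance` (probability that
#'   a heterozygous call inside the segment converts to a homozygote).
#'   `NULL` for a null simulation.
#' @param missing_rate Per-call probability of `NoCall`.
#' @param error_rate Per-call probability of a symmetric genotyping error.
#' @param seed Random seed fixing the full output.
#' @return A list of class `chc_sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 4L, n_snps = 1500L,
                              gap_mean = 12000L,
                              hv_range = c(0.05, 0.5),
                              n_case = 4L, n_control = 60L,
                              segments = NULL,
                              missing_rate = 0.01, error_rate = 0.005,
                              seed = 1L) {
  stopifnot(n_chromosomes >= 1, n_snps >= 1, gap_mean >= 1,
            length(hv_range) == 2, hv_range[1] > 0,
            hv_range[1] <= hv_range[2],
            n_case >= 1, n_control >= 1,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  if (hv_range[2] > 0.5) {
    stop("hv_range above 0.5: no allele frequency solves 2p(1-p) = HV")
  }
  if (!is.null(segments)) {
    req <- c("chromosome", "start_index", "n_snps", "affected_fraction",
             "penetrance")
    stopifnot(all(req %in% names(segments)),
              all(segments$affected_fraction >= 0),
              all(segments$affected_fraction <= 1),
              all(segments$penetrance >= 0), all(segments$penetrance <= 1),
              all(segments$chromosome >= 1),
              all(segments$chromosome <= n_chromosomes),
              all(segments$start_index >= 1),
              all(segments$start_index + segments$n_snps - 1 <= n_snps))
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_snps = as.integer(n_snps),
                 gap_mean = as.integer(gap_mean),
                 hv_range = as.numeric(hv_range),
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 segments = segments,
                 missing_rate = missing_rate, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "chc_sim_config")
}

#' Recovery-benchmark simulation preset
#'
#' Ten planted 8-SNP segments with full penetrance in every case sample,
#' 10 case and 10 control samples, HV uniform on \[0.3, 0.5\], on a genome
#' of 4 chromosomes x 1500 SNPs.  Intended for sensitivity/precision
#' benchmarking of the region caller at a manual delta threshold of 0.4
#' and CPT 5.
#'
#' @param seed Random seed.
#' @return A `chc_sim_config`.
#' @export
sim_preset_recovery <- function(seed = 1L) {
  segments <- data.frame(
    chromosome = rep(1:4, length.out = 10),
    start_index = 200L + 400L * ((0:9) %/% 4L),
    n_snps = 8L,
    affected_fraction = 1.0,
    penetrance = 1.0)
  simulation_config(n_chromosomes = 4L, n_snps = 1500L,
                    hv_range = c(0.3, 0.5),
                    n_case = 10L, n_control = 10L,
                    segments = segments, seed = seed)
}

#' Null-calibration simulation preset
#'
#' No planted segments; 6000 SNPs with the default genome-wide HV
#' distribution and 10+10 samples.  Used to measure the false-region rate
#' of the caller at the power-derived threshold.
#'
#' @param seed Random seed.
#' @return A `chc_sim_config`.
#' @export
sim_preset_null <- function(seed = 1L) {
  simulation_config(n_chromosomes = 4L, n_snps = 1500L,
                    n_case = 10L, n_control = 10L,
                    segments = NULL, seed = seed)
}

# Draw an n_snps x n_samples HWE genotype matrix given per-SNP p (minor
# allele frequency).  Column-recycling of p keeps this vectorized.
draw_hwe <- function(p, n_samples) {
  n <- length(p)
  u <- matrix(stats::runif(n * n_samples), nrow = n)
  g <- matrix("BB", nrow = n, ncol = n_samples)
  het <- 2 * p * (1 - p)
  g[u < p^2 + het] <- "AB"
  g[u < p^2] <- "AA"
  g
}

# Convert heterozygous calls to homozygotes with probability `penetrance`;
# the homozygote is chosen in proportion to the conditional HWE homozygote
# frequencies p^2 : (1-p)^2.
convert_het <- function(g, p, penetrance) {
  het <- which(g == "AB")
  if (!length(het)) return(g)
  hit <- het[stats::runif(length(het)) < penetrance]
  if (!length(hit)) return(g)
  row <- (hit - 1L) %% nrow(g) + 1L
  paa <- p[row]^2 / (p[row]^2 + (1 - p[row])^2)
  g[hit] <- ifelse(stats::runif(length(hit)) < paa, "AA", "BB")
  g
}

# Symmetric genotyping error: with probability `rate` replace a call by one
# of the other two categories, uniformly.
apply_errors <- function(g, rate) {
  if (rate <= 0) return(g)
  hit <- which(stats::runif(length(g)) < rate)
  if (!length(hit)) return(g)
  alt <- list(AA = c("AB", "BB"), AB = c("AA", "BB"), BB = c("AA", "AB"))
  pick <- stats::runif(length(hit)) < 0.5
  g[hit] <- vapply(seq_along(hit), function(i) {
    alt[[g[hit[i]]]][if (pick[i]) 1L else 2L]
  }, character(1))
  g
}

apply_missing <- function(g, rate) {
  if (rate <= 0) return(g)
  g[stats::runif(length(g)) < rate] <- "NoCall"
  g
}

# Simulated annotation shared by both cohorts; also returns p per SNP.
sim_annotation <- function(config) {
  n_total <- config$n_chromosomes * config$n_snps
  gaps <- sample.int(2L * config$gap_mean - 1L, n_total, replace = TRUE)
  pos <- as.vector(vapply(seq_len(config$n_chromosomes), function(ch) {
    cumsum(gaps[((ch - 1L) * config$n_snps + 1L):(ch * config$n_snps)])
  }, integer(config$n_snps)))
  hv <- stats::runif(n_total, config$hv_range[1], config$hv_range[2])
  data.frame(snp_id = sprintf("sim%06d", seq_len(n_total)),
             chromosome = as.character(rep(seq_len(config$n_chromosomes),
                                           each = config$n_snps)),
             position = pos,
             heterozygosity = hv,
             p = (1 - sqrt(1 - 2 * hv)) / 2,
             stringsAsFactors = FALSE)
}

segment_rows <- function(config, seg) {
  offset <- (seg$chromosome - 1L) * config$n_snps
  offset + seq.int(seg$start_index, length.out = seg$n_snps)
}

#' Simulate case and control cohorts with planted LOH segments
#'
#' Control genotypes are drawn under Hardy-Weinberg equilibrium at each
#' SNP's annotated heterozygosity value; case genotypes are drawn
#' identically and then, inside each planted segment, heterozygous calls
#' of the affected case samples are converted to homozygotes at the
#' segment's penetrance.  Genotyping errors and missing calls are applied
#' last to both cohorts.  The same seed always reproduces the same output.
#'
#' @param config A [simulation_config()].
#' @return List with elements `case` and `control`
#'   ([cohort_genotypes()] objects) and `truth`, a data frame of planted
#'   segments with physical coordinates (`chromosome`, `start`, `end`,
#'   `start_index`, `n_snps`).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "chc_sim_config"))
  set.seed(config$seed)
  ann <- sim_annotation(config)
  p <- ann$p
  control <- draw_hwe(p, config$n_control)
  case <- draw_hwe(p, config$n_case)

  truth <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), start_index = integer(),
                      n_snps = integer(), stringsAsFactors = FALSE)
  if (!is.null(config$segments)) {
    for (i in seq_len(nrow(config$segments))) {
      seg <- config$segments[i, ]
      rows <- segment_rows(config, seg)
      n_aff <- ceiling(seg$affected_fraction * config$n_case)
      if (n_aff > 0) {
        affected <- sample.int(config$n_case, n_aff)
        sub <- case[rows, affected, drop = FALSE]
        case[rows, affected] <- convert_het(sub, p[rows], seg$penetrance)
      }
      truth <- rbind(truth, data.frame(
        chromosome = as.character(seg$chromosome),
        start = ann$position[rows[1L]],
        end = ann$position[rows[length(rows)]],
        start_index = seg$start_index, n_snps = seg$n_snps,
        stringsAsFactors = FALSE))
    }
  }

  case <- apply_missing(apply_errors(case, config$error_rate),
                        config$missing_rate)
  control <- apply_missing(apply_errors(control, config$error_rate),
                           config$missing_rate)

  anno <- ann[c("snp_id", "chromosome", "position", "heterozygosity")]
  colnames(case) <- sprintf("case%02d", seq_len(config$n_case))
  colnames(control) <- sprintf("ctrl%02d", seq_len(config$n_control))
  list(case = suppressMessages(cohort_genotypes(anno, case)),
       control = suppressMessages(cohort_genotypes(anno, control)),
       truth = truth)
}

#' Simulate a matched tumor/normal genotype pair
#'
#' One germ-line (normal) sample is drawn under Hardy-Weinberg equilibrium;
#' the tumor is a copy in which heterozygous calls inside planted segments
#' convert to homozygotes at the segment penetrance.  Genotyping errors are
#' applied to the tumor sample only -- the germ-line sample acts as the
#' reference -- so that among heterozygous germ-line SNPs outside planted
#' segments the false-LOH rate equals the error rate.  Missing calls are
#' applied to both samples.
#'
#' @param config A [simulation_config()]; `n_case`/`n_control` are ignored.
#' @return List with elements `tumor` and `normal` (single-sample
#'   [cohort_genotypes()] objects) and `truth` as in [simulate_cohorts()].
#' @export
simulate_matched_pair <- function(config) {
  stopifnot(inherits(config, "chc_sim_config"))
  set.seed(config$seed)
  ann <- sim_annotation(config)
  p <- ann$p
  normal <- draw_hwe(p, 1L)
  tumor <- normal

  truth <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), start_index = integer(),
                      n_snps = integer(), stringsAsFactors = FALSE)
  if (!is.null(config$segments)) {
    for (i in seq_len(nrow(config$segments))) {
      seg <- config$segments[i, ]
      rows <- segment_rows(config, seg)
      tumor[rows, 1L] <- convert_het(tumor[rows, , drop = FALSE], p[rows],
                                     seg$penetrance)
      truth <- rbind(truth, data.frame(
        chromosome = as.character(seg$chromosome),
        start = ann$position[rows[1L]],
        end = ann$position[rows[length(rows)]],
        start_index = seg$start_index, n_snps = seg$n_snps,
        stringsAsFactors = FALSE))
    }
  }

  tumor <- apply_missing(apply_errors(tumor, config$error_rate),
                         config$missing_rate)
  normal <- apply_missing(normal, config$missing_rate)
  anno <- ann[c("snp_id", "chromosome", "position", "heterozygosity")]
  colnames(tumor) <- "tumor"
  colnames(normal) <- "normal"
  list(tumor = suppressMessages(cohort_genotypes(anno, tumor)),
       normal = suppressMessages(cohort_genotypes(anno, normal)),
       truth = truth)
}
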