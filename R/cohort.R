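# Cohort genotype container and validation.

GENOTYPE_LEVELS <- c("AA", "AB", "BB", "NoCall")

# Chromosome labels sort as 1..22, X, Y, MT, then anything else alphabetically.
chrom_levels <- function(x) {
  known <- c(as.character(1:22), "X", "Y", "MT")
  c(known, sort(setdiff(unique(as.character(x)), known)))
}

chrom_factor <- function(x) factor(as.character(x), levels = chrom_levels(x))

normalize_chromosome <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Construct a cohort genotype set
#'
#' Bundles per-SNP annotation with a SNP-by-sample matrix of genotype calls
#' for one cohort.  SNPs are sorted by (chromosome, position); chromosome
#' labels are normalized by stripping any `"chr"` prefix.
#'
#' @param annotation Data frame with columns `snp_id`, `chromosome`,
#'   `position` (1-based base pairs) and `heterozygosity` (the population
#'   heterozygosity value from the array annotation, a fraction in
#'   \[0, 1\]; may be `NA`).
#' @param calls Character matrix of genotype calls, one row per SNP in
#'   `annotation` order, one column per sample.  Values must be one of
#'   `"AA"`, `"AB"`, `"BB"`, `"NoCall"`.
#' @param samples Sample identifiers; defaults to `colnames(calls)`.
#'
#' @return An object of class `cohort_genotypes`: a list with elements
#'   `annotation` (sorted data frame), `samples` and `calls` (matrix with
#'   `snp_id` rownames and sample colnames).
#' @export
#' @examples
#' ann <- data.frame(snp_id = c("rs1", "rs2"), chromosome = "1",
#'                   position = c(100L, 200L), heterozygosity = c(0.4, 0.3))
#' calls <- matrix(c("AB", "AA", "BB", "AB"), nrow = 2,
#'                 dimnames = list(NULL, c("s1", "s2")))
#' cohort_genotypes(ann, calls)
cohort_genotypes <- function(annotation, calls, samples = colnames(calls)) {
  required <- c("snp_id", "chromosome", "position", "heterozygosity")
  missing_cols <- setdiff(required, names(annotation))
  if (length(missing_cols)) {
    stop("annotation is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  annotation <- annotation[required]
  annotation$snp_id <- as.character(annotation$snp_id)
  annotation$chromosome <- normalize_chromosome(annotation$chromosome)
  annotation$position <- as.integer(annotation$position)
  annotation$heterozygosity <- as.numeric(annotation$heterozygosity)

  dup <- unique(annotation$snp_id[duplicated(annotation$snp_id)])
  if (length(dup)) {
    stop("duplicate snp_id in annotation: ", paste(dup, collapse = ", "))
  }
  if (anyNA(annotation$position) || any(annotation$position < 1L)) {
    stop("SNP positions must be integers >= 1")
  }
  hv <- annotation$heterozygosity
  if (any(!is.na(hv) & (hv < 0 | hv > 1))) {
    stop("heterozygosity values must lie in [0, 1]")
  }

  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(calls)))
  samples <- as.character(samples)
  if (nrow(calls) != nrow(annotation) || ncol(calls) != length(samples)) {
    stop("calls must be a |annotation| x |samples| matrix")
  }
  if (ncol(calls) < 1L) stop("at least one sample is required")
  storage.mode(calls) <- "character"
  bad <- !(calls %in% GENOTYPE_LEVELS)
  if (any(bad)) {
    stop("invalid genotype call(s): ",
         paste(unique(calls[bad]), collapse = ", "),
         " (expected AA/AB/BB/NoCall; use read_cohort_table() for raw tables)")
  }

  ord <- order(chrom_factor(annotation$chromosome), annotation$position)
  annotation <- annotation[ord, , drop = FALSE]
  rownames(annotation) <- NULL
  calls <- calls[ord, , drop = FALSE]
  dimnames(calls) <- list(annotation$snp_id, samples)

  key <- paste(annotation$chromosome, annotation$position, annotation$snp_id)
  if (anyDuplicated(key)) {
    stop("duplicate (chromosome, position, snp_id) in annotation")
  }
  sex <- intersect(unique(annotation$chromosome), c("X", "Y"))
  if (length(sex)) {
    message("cohort includes sex chromosome(s) ", paste(sex, collapse = ", "),
            "; processed without hemizygosity correction")
  }

  structure(list(annotation = annotation, samples = samples, calls = calls),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("Cohort genotypes: %d SNPs x %d samples\n",
              nrow(x$annotation), length(x$samples)))
  cat("  chromosomes:",
      paste(chrom_levels(x$annotation$chromosome)[
        chrom_levels(x$annotation$chromosome) %in% x$annotation$chromosome],
        collapse = ", "), "\n")
  nc <- sum(x$calls == "NoCall")
  cat(sprintf("  NoCall rate: %.3f\n", nc / length(x$calls)))
  invisible(x)
}

#' @export
dim.cohort_genotypes <- function(x) dim(x$calls)

# Row-subset a cohort (internal).
subset_cohort <- function(x, i) {
  structure(list(annotation = {
    a <- x$annotation[i, , drop = FALSE]
    rownames(a) <- NULL
    a
  },
  samples = x$samples,
  calls = x$calls[i, , drop = FALSE]),
  class = "cohort_genotypes")
}
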