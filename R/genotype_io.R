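# Reading and writing genotype tables, region tables and delta tracks.

#' Describe the layout of a cohort genotype table
#'
#' A dialect names the annotation columns of a tab-delimited genotype table
#' and the tokens used for heterozygous, homozygous and absent calls.  All
#' remaining columns are treated as sample columns.
#'
#' @param snp_id,chromosome,position,heterozygosity Column names holding the
#'   SNP identifier, chromosome label, physical position and population
#'   heterozygosity value.
#' @param het_tokens,hom_a_tokens,hom_b_tokens,nocall_tokens Character vectors
#'   of genotype tokens normalized to `AB`, `AA`, `BB` and `NoCall`
#'   respectively.  Any token matching none of the four sets becomes `NoCall`
#'   and is counted in a warning.
#' @return A list of class `cohort_dialect`.
#' @export
cohort_dialect <- function(snp_id = "snp_id",
                           chromosome = "chromosome",
                           position = "position",
                           heterozygosity = "heterozygosity",
                           het_tokens = c("AB", "BA", "het", "HET", "Het"),
                           hom_a_tokens = c("AA"),
                           hom_b_tokens = c("BB"),
                           nocall_tokens = c("NoCall", "NC", "--", "./.",
                                             "NA", "")) {
  structure(list(snp_id = snp_id, chromosome = chromosome,
                 position = position, heterozygosity = heterozygosity,
                 het_tokens = het_tokens, hom_a_tokens = hom_a_tokens,
                 hom_b_tokens = hom_b_tokens, nocall_tokens = nocall_tokens),
            class = "cohort_dialect")
}

# Map raw genotype tokens onto AA/AB/BB/NoCall; warn about unparseable ones.
normalize_calls <- function(x, dialect) {
  out <- matrix("NoCall", nrow = nrow(x), ncol = ncol(x),
                dimnames = dimnames(x))
  out[x %in% dialect$hom_a_tokens] <- "AA"
  out[x %in% dialect$hom_b_tokens] <- "BB"
  out[x %in% dialect$het_tokens] <- "AB"
  known <- c(dialect$hom_a_tokens, dialect$hom_b_tokens,
             dialect$het_tokens, dialect$nocall_tokens)
  n_bad <- sum(!(x %in% known) & !is.na(x)) + sum(is.na(x))
  if (n_bad > 0) {
    warning(sprintf("%d unparseable genotype token(s) set to NoCall", n_bad))
  }
  out
}

#' Read a cohort genotype table
#'
#' Reads a tab-delimited table whose rows are SNPs.  Annotation columns are
#' named by the dialect; every other column is a sample of genotype calls.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @param dialect A [cohort_dialect()] describing column names and genotype
#'   tokens.
#' @return A validated, coordinate-sorted [cohort_genotypes()] object.
#' @export
read_cohort_table <- function(path, dialect = cohort_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  anno_cols <- c(dialect$snp_id, dialect$chromosome, dialect$position,
                 dialect$heterozygosity)
  missing_cols <- setdiff(anno_cols, names(tab))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(tab), anno_cols)
  if (!length(sample_cols)) stop("no sample columns found")
  annotation <- data.frame(snp_id = tab[[dialect$snp_id]],
                           chromosome = tab[[dialect$chromosome]],
                           position = suppressWarnings(
                             as.integer(tab[[dialect$position]])),
                           heterozygosity = suppressWarnings(
                             as.numeric(tab[[dialect$heterozygosity]])),
                           stringsAsFactors = FALSE)
  calls <- normalize_calls(as.matrix(tab[sample_cols]), dialect)
  cohort_genotypes(annotation, calls, samples = sample_cols)
}

#' Write a cohort genotype table
#'
#' Inverse of [read_cohort_table()] under the default dialect: annotation
#' columns `snp_id`, `chromosome`, `position`, `heterozygosity`, then one
#' column per sample.
#'
#' @param cohort A [cohort_genotypes()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  out <- cbind(cohort$annotation,
               as.data.frame(cohort$calls, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort genotypes from a VCF file
#'
#' Maps diploid GT fields onto categorical calls: `0/0` to `AA`, `1/1` to
#' `BB`, `0/1` and `1/0` to `AB` (phased separators included), anything else
#' to `NoCall`.  VCF carries no population heterozygosity annotation, so it
#' is either supplied explicitly or estimated from the observed calls.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param heterozygosity Optional numeric vector of population
#'   heterozygosity values named by variant ID; variants without a value get
#'   the observed heterozygosity frequency (with a message).
#' @return A [cohort_genotypes()] object.
#' @export
read_cohort_vcf <- function(path, heterozygosity = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required for VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- matrix("NoCall", nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
  calls[gt %in% c("0/0", "0|0")] <- "AA"
  calls[gt %in% c("1/1", "1|1")] <- "BB"
  calls[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "AB"
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  hv <- rowMeans(calls == "AB")
  if (!is.null(heterozygosity)) {
    hit <- ids %in% names(heterozygosity)
    hv[hit] <- heterozygosity[ids[hit]]
    if (any(!hit)) {
      message(sum(!hit), " variant(s) without supplied heterozygosity; ",
              "using observed heterozygosity frequency")
    }
  } else {
    message("no population heterozygosity supplied; ",
            "using observed heterozygosity frequency")
  }
  annotation <- data.frame(snp_id = ids, chromosome = fix[, "CHROM"],
                           position = as.integer(fix[, "POS"]),
                           heterozygosity = hv, stringsAsFactors = FALSE)
  cohort_genotypes(annotation, calls)
}

#' Restrict two cohorts to their shared SNPs
#'
#' Both cohorts are cut down to the intersection of their SNP identifiers,
#' in identical (chromosome, position) order.  Shared SNPs must agree on
#' chromosome and position.
#'
#' @param case,control [cohort_genotypes()] objects.
#' @return A list with elements `case` and `control`.
#' @export
align_cohorts <- function(case, control) {
  shared <- intersect(case$annotation$snp_id, control$annotation$snp_id)
  if (!length(shared)) {
    stop("empty intersection: case and control cohorts share no SNPs")
  }
  ia <- match(shared, case$annotation$snp_id)
  ib <- match(shared, control$annotation$snp_id)
  bad <- case$annotation$chromosome[ia] != control$annotation$chromosome[ib] |
    case$annotation$position[ia] != control$annotation$position[ib]
  if (any(bad)) {
    stop("inconsistent annotation between cohorts for snp_id: ",
         paste(utils::head(shared[bad], 5), collapse = ", "))
  }
  case2 <- subset_cohort(case, sort(ia))
  control2 <- subset_cohort(control,
                            match(case2$annotation$snp_id,
                                  control$annotation$snp_id))
  list(case = case2, control = control2)
}

#' Write inferred-LOH regions to TSV or BED
#'
#' TSV output uses 1-based inclusive coordinates with columns `chromosome`,
#' `start`, `end`, `n_snps`, `enrichment_score`, `first_snp_id`,
#' `last_snp_id`.  BED output is 0-based half-open; the BED score column
#' rescales enrichment scores linearly so the top region scores 1000.
#'
#' @param regions A region table from [call_regions()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(chromosome = regions$chromosome,
                      start = regions$start,
                      end = regions$end,
                      n_snps = regions$n_snps,
                      enrichment_score = regions$enrichment_score,
                      first_snp_id = regions$first_snp_id,
                      last_snp_id = regions$last_snp_id,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (nrow(regions)) {
      score <- as.integer(round(
        1000 * regions$enrichment_score / max(regions$enrichment_score)))
      out <- data.frame(chrom = regions$chromosome,
                        start = regions$start - 1L,
                        end = regions$end,
                        name = sprintf("%s:%d-%d", regions$chromosome,
                                       regions$start, regions$end),
                        score = score, stringsAsFactors = FALSE)
    } else {
      out <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = integer())
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a region TSV written by [write_regions()]
#' @param path Path to a TSV region table.
#' @return A data frame of regions.
#' @export
read_regions <- function(path) {
  out <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if ("chromosome" %in% names(out)) {
    out$chromosome <- as.character(out$chromosome)
  }
  out
}

#' Write a per-SNP delta track
#'
#' @param track A delta track from [delta_values()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_delta_track <- function(track, path) {
  out <- track[c("chromosome", "position", "snp_id", "het_case",
                 "het_control", "delta", "informative", "retained")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
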