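# Per-SNP LOH calling from a matched tumor/normal genotype pair.

LOH_LEVELS <- c("LOH", "RETENTION", "NON_INFORMATIVE", "NO_CALL")

#' Call per-SNP LOH from a matched tumor/normal pair
#'
#' Applies the standard matched-pair convention: a SNP shows LOH when the
#' germ-line (normal) call is heterozygous and the tumor call homozygous;
#' retention when both are heterozygous; a homozygous normal call is
#' non-informative; any absent call yields `NO_CALL`.  A homozygous normal
#' with the opposite homozygote in the tumor is classified
#' `NON_INFORMATIVE` and counted as a discordance (message), since LOH
#' requires germ-line heterozygosity and such flips are most plausibly
#' genotyping error.
#'
#' @param tumor,normal Single-sample [cohort_genotypes()] objects; they are
#'   aligned on shared SNPs first.
#' @return A `chc_loh_track` data frame with columns `snp_id`,
#'   `chromosome`, `position`, `call` (factor with levels `LOH`,
#'   `RETENTION`, `NON_INFORMATIVE`, `NO_CALL`).
#' @export
call_conventional_loh <- function(tumor, normal) {
  if (length(tumor$samples) != 1L || length(normal$samples) != 1L) {
    stop("tumor and normal must each contain exactly one sample")
  }
  aligned <- align_cohorts(tumor, normal)
  tum <- aligned$case$calls[, 1L]
  nor <- aligned$control$calls[, 1L]

  call <- rep("NON_INFORMATIVE", length(tum))
  call[nor == "AB" & tum %in% c("AA", "BB")] <- "LOH"
  call[nor == "AB" & tum == "AB"] <- "RETENTION"
  call[nor == "NoCall" | tum == "NoCall"] <- "NO_CALL"

  flips <- sum((nor == "AA" & tum == "BB") | (nor == "BB" & tum == "AA"))
  if (flips > 0) {
    message(flips, " homozygote-to-opposite-homozygote discordance(s) ",
            "classified NON_INFORMATIVE")
  }

  ann <- aligned$case$annotation
  out <- data.frame(snp_id = ann$snp_id,
                    chromosome = ann$chromosome,
                    position = ann$position,
                    call = factor(call, levels = LOH_LEVELS),
                    stringsAsFactors = FALSE)
  class(out) <- c("chc_loh_track", "data.frame")
  out
}

#' Extract the positions of SNPs showing conventional LOH
#'
#' @param track A `chc_loh_track` from [call_conventional_loh()].
#' @return Data frame with columns `chromosome` and `position`, one row per
#'   SNP called `LOH`.
#' @export
loh_snp_positions <- function(track) {
  out <- track[track$call == "LOH", c("chromosome", "position")]
  rownames(out) <- NULL
  out
}
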