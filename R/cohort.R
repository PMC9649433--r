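# Pooling of per-locus mismatch observations into analysis records, and
# normalization of score families.

SCORE_FAMILIES <- c("snowflake", "all_eps", "abv_eps")

.pircheCols <- function(df) grep("^pirche_", names(df), value = TRUE)

#' Pool a pregnancy cohort into per-mismatch records
#'
#' Each case contributes up to three data points — one per Class I locus
#' — excluding matched loci (child alleles all present in the mother's
#' genotype) and homozygous loci, where there is no immunizing mismatch.
#' The per-locus antibody flag (CSA) becomes the record outcome.
#'
#' @param scores per-locus score table as produced by
#'   \code{\link{locusScores}} with columns \code{matched},
#'   \code{homozygous} and a logical \code{outcome} column (CSA per
#'   locus).
#' @return data.frame of retained records.
#' @export
poolPregnancy <- function(scores) {
  need <- c("case_id", "locus", "matched", "homozygous", "outcome")
  if (!all(need %in% names(scores)))
    stop("scores needs columns: ", paste(need, collapse = ", "))
  keep <- !scores$matched & !scores$homozygous
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool a transplant cohort into per-locus records
#'
#' One record per locus per case, dropping records whose four score
#' families (Snowflake, both eplet counts, every surrogate peptide
#' column) are all zero — with low-resolution typing, "HLA-matched" can
#' only be recognized from the scores themselves. The DSA flag is
#' per-locus: antibody against either donor allele of the locus counts
#' as positive.
#'
#' @param scores per-locus score table with a logical \code{outcome}
#'   (DSA per locus) and numeric \code{follow_up} column (years).
#' @return data.frame of retained records.
#' @export
poolKtc <- function(scores) {
  need <- c("case_id", "locus", "snowflake", "all_eps", "abv_eps",
            "outcome", "follow_up")
  if (!all(need %in% names(scores)))
    stop("scores needs columns: ", paste(need, collapse = ", "))
  if (any(scores$follow_up < 0, na.rm = TRUE))
    stop("invalid-input: negative follow-up time")
  pir <- .pircheCols(scores)
  pirZero <- if (length(pir))
    rowSums(abs(as.matrix(scores[, pir, drop = FALSE]))) == 0
  else rep(TRUE, nrow(scores))
  allZero <- scores$snowflake == 0 & scores$all_eps == 0 &
    scores$abv_eps == 0 & pirZero
  out <- scores[!allZero, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize score families within locus
#'
#' Snowflake and the eplet counts are centred and scaled to unit sample
#' standard deviation within each locus of the post-exclusion analysis
#' set (so effect estimates read "per 1 SD"); surrogate peptide counts
#' are log-transformed as log(1 + x) instead, following their reported
#' logarithmic hazard shape.
#'
#' @param records pooled records (\code{\link{poolPregnancy}} /
#'   \code{\link{poolKtc}} output).
#' @return records with added \code{z_snowflake}, \code{z_all_eps},
#'   \code{z_abv_eps} and \code{log_pirche_*} columns.
#' @export
normalizeRecords <- function(records) {
  out <- records
  for (L in unique(records$locus)) {
    sel <- records$locus == L
    for (col in intersect(SCORE_FAMILIES, names(records))) {
      x <- records[[col]][sel]
      s <- stats::sd(x)
      if (is.na(s) || s == 0)
        stop("degenerate-locus: ", col, " has zero variance at locus ", L)
      out[[paste0("z_", col)]][sel] <- (x - mean(x)) / s
    }
  }
  for (col in .pircheCols(records))
    out[[paste0("log_", col)]] <- log1p(records[[col]])
  out
}
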