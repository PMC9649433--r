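# Resolution of intermediate-resolution typings to frequency-weighted
# high-resolution genotypes via haplotype frequencies, plus
# frequency-weighted score expectation.

#' Read a multiple-allele-code table
#'
#' CSV columns \code{code}, \code{alleles} (pipe-separated allele names).
#' Codes are case-normalized to upper case.
#'
#' @param table CSV path or data.frame.
#' @return named list: code -> character vector of allele names.
#' @export
readMacTable <- function(table) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  out <- lapply(strsplit(table$alleles, "|", fixed = TRUE), trimws)
  names(out) <- toupper(trimws(table$code))
  if (any(vapply(out, length, 0L) == 0L))
    stop("MAC table contains an empty expansion")
  out
}

#' Read a serologic-equivalent map
#'
#' CSV columns \code{allele}, \code{antigen} (e.g. A*01:01 -> A1).
#'
#' @param table CSV path or data.frame.
#' @return data.frame with columns allele, antigen.
#' @export
readSerologyMap <- function(table) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  data.frame(allele = trimws(table$allele),
             antigen = toupper(trimws(table$antigen)),
             stringsAsFactors = FALSE)
}

#' Read a haplotype frequency table
#'
#' CSV with one column per locus plus \code{frequency}; frequencies must
#' be positive and sum to at most 1 (plus tolerance).
#'
#' @param table CSV path or data.frame.
#' @return data.frame, attribute \code{"loci"} naming the locus columns.
#' @export
readHaplotypeTable <- function(table) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  if (!"frequency" %in% names(table))
    stop("haplotype table needs a frequency column")
  if (any(table$frequency <= 0))
    stop("haplotype frequencies must be positive")
  if (sum(table$frequency) > 1 + 1e-6)
    stop("haplotype frequencies sum above 1")
  attr(table, "loci") <- setdiff(names(table), "frequency")
  table
}

#' Expand one typing token to its candidate allele list
#'
#' Three token forms are supported: an explicit two-field allele
#' (\code{"A*01:01"} -> itself), a multiple-allele code
#' (\code{"A*01:XX"} -> the code's list restricted to the A*01 antigen
#' group), and a serologic antigen (\code{"A1"} -> every allele mapping
#' to it in the serology table).
#'
#' @param token typing token string.
#' @param mac MAC table from \code{\link{readMacTable}}.
#' @param serology serology map from \code{\link{readSerologyMap}}.
#' @return character vector of candidate allele names.
#' @export
expandMac <- function(token, mac = list(), serology = NULL) {
  token <- trimws(token)
  if (grepl("\\*", token) && grepl(":", token)) {
    field2 <- sub("^[^:]*:", "", token)
    group <- sub(":.*$", "", token)
    if (grepl("^[0-9]+$", field2))
      return(token)  # explicit allele
    code <- toupper(field2)
    cand <- mac[[code]]
    if (is.null(cand))
      stop("unresolved-typing: unknown multiple-allele code in ", token)
    cand <- cand[startsWith(cand, paste0(group, ":"))]
    if (!length(cand))
      stop("unresolved-typing: code ", code, " has no candidate in group ",
           group)
    return(cand)
  }
  if (is.null(serology))
    stop("unresolved-typing: ", token, " (no serology table supplied)")
  cand <- serology$allele[serology$antigen == toupper(token)]
  if (!length(cand))
    stop("unresolved-typing: unknown token ", token)
  cand
}

#' Weighted high-resolution genotype candidates for one typing
#'
#' Enumerates haplotype pairs from the frequency table whose alleles are
#' compatible, locus by locus, with the typing's candidate lists. A
#' pair's raw weight is f(h1) * f(h2), doubled for heterozygous pairs
#' (Hardy-Weinberg pair probability); weights are normalized over all
#' matching pairs, pairs whose normalized weight does not strictly
#' exceed \code{minNormFreq} are dropped, and the retained weights are
#' renormalized to sum to 1.
#'
#' @param typing named list: locus -> character(2) typing tokens.
#' @param haplotypes haplotype frequency table
#'   (\code{\link{readHaplotypeTable}}).
#' @param mac,serology lookup tables for \code{\link{expandMac}}.
#' @param minNormFreq normalized-frequency cut (default 0.01; the cut is
#'   strict: kept only if weight > minNormFreq).
#' @return list of candidates, each \code{list(genotype = Genotype,
#'   weight, h1, h2)}; weights sum to 1.
#' @export
genotypeCandidates <- function(typing, haplotypes, mac = list(),
                               serology = NULL, minNormFreq = 0.01) {
  loci <- attr(haplotypes, "loci")
  if (is.null(loci)) loci <- setdiff(names(haplotypes), "frequency")
  if (!all(loci %in% names(typing)))
    stop("typing must cover loci: ", paste(loci, collapse = ", "))
  cand <- lapply(stats::setNames(loci, loci), function(L)
    lapply(typing[[L]], expandMac, mac = mac, serology = serology))

  nh <- nrow(haplotypes)
  # per haplotype and locus: does its allele satisfy token 1 / token 2?
  okTok <- lapply(stats::setNames(loci, loci), function(L) {
    al <- haplotypes[[L]]
    cbind(al %in% cand[[L]][[1]], al %in% cand[[L]][[2]])
  })
  pairOk <- function(i, j) {
    for (L in loci) {
      m <- okTok[[L]]
      if (!((m[i, 1] && m[j, 2]) || (m[i, 2] && m[j, 1]))) return(FALSE)
    }
    TRUE
  }
  idx <- which(upper.tri(matrix(0, nh, nh), diag = TRUE), arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(idx)), function(r)
    pairOk(idx[r, 1], idx[r, 2]), FALSE)
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0L)
    stop("imputation-failure: typing matches no haplotype pair")
  f <- haplotypes$frequency
  w <- as.numeric(f[idx[, 1]] * f[idx[, 2]] *
                  ifelse(idx[, 1] == idx[, 2], 1, 2))
  w <- w / sum(w)
  keep <- w > minNormFreq
  if (!any(keep))
    stop("imputation-failure: no haplotype pair above the frequency cut")
  idx <- idx[keep, , drop = FALSE]
  w <- w[keep] / sum(w[keep])
  lapply(seq_along(w), function(r) {
    i <- unname(idx[r, 1]); j <- unname(idx[r, 2])
    g <- lapply(stats::setNames(loci, loci), function(L)
      c(haplotypes[[L]][i], haplotypes[[L]][j]))
    list(genotype = genotype(g), weight = w[r], h1 = i, h2 = j)
  })
}

#' Frequency-weighted score expectation over imputed genotypes
#'
#' Applies the scorer to every donor x recipient candidate combination
#' and sums the score vectors weighted by the product of the two
#' candidate weights. With unambiguous typings on both sides this
#' reduces to direct scoring.
#'
#' @param donorCandidates,recipientCandidates candidate lists from
#'   \code{\link{genotypeCandidates}} (donor and recipient imputations
#'   are treated as independent).
#' @param scorer function(donorGenotype, recipientGenotype) -> named
#'   numeric score vector.
#' @return the weighted score vector.
#' @export
imputedScore <- function(donorCandidates, recipientCandidates, scorer) {
  wd <- vapply(donorCandidates, `[[`, 0, "weight")
  wr <- vapply(recipientCandidates, `[[`, 0, "weight")
  if (abs(sum(wd) - 1) > 1e-9 || abs(sum(wr) - 1) > 1e-9)
    stop("candidate weights must each sum to 1")
  total <- NULL
  for (i in seq_along(donorCandidates)) {
    for (j in seq_along(recipientCandidates)) {
      s <- tryCatch(
        scorer(donorCandidates[[i]]$genotype,
               recipientCandidates[[j]]$genotype),
        error = function(e) stop(
          "scorer failed on donor candidate ", i, " x recipient candidate ",
          j, ": ", conditionMessage(e)))
      contrib <- wd[i] * wr[j] * s
      total <- if (is.null(total)) contrib else total + contrib
    }
  }
  total
}
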