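# Donor-recipient mismatch scoring: Snowflake (solvent-accessible
# amino-acid mismatches), eplet counts, and the surrogate mismatched-
# peptide count per presenter locus.

#' Snowflake score for one donor locus
#'
#' For each donor allele, its own surface positions (RSA at or above the
#' threshold on the donor profile — the immunogen's surface) are scanned;
#' a (position, donor residue) pair is mismatched when no allele in the
#' recipient comparison set carries that residue at that position. The
#' locus score is the size of the union of mismatched pairs over the
#' locus's donor alleles, so a mismatch shared by both donor alleles is
#' counted once. A donor allele also present in the recipient set
#' contributes nothing by construction.
#'
#' @param donorAlleles allele name(s) of the donor at one locus.
#' @param recipientAlleles recipient allele names; in interlocus mode the
#'   full Class I set (up to six), in intralocus mode only same-locus
#'   names are used.
#' @param db the \linkS4class{AlleleDb} resolving every allele.
#' @param threshold surface RSA cutoff (default 0.3717, the reference-
#'   panel median).
#' @param mode \code{"interlocus"} (compare against the whole recipient
#'   Class I repertoire) or \code{"intralocus"} (same locus only).
#' @return integer mismatch count.
#' @export
snowflakeScore <- function(donorAlleles, recipientAlleles, db,
                           threshold = 0.3717,
                           mode = c("interlocus", "intralocus")) {
  mode <- match.arg(mode)
  donorAlleles <- unique(donorAlleles)
  if (mode == "intralocus") {
    loc <- unique(locusOf(donorAlleles))
    if (length(loc) != 1L)
      stop("intralocus mode needs donor alleles from a single locus")
    recipientAlleles <- recipientAlleles[locusOf(recipientAlleles) == loc]
  }
  recipientAlleles <- unique(recipientAlleles)
  recSeqs <- lapply(recipientAlleles, function(a)
    strsplit(getProfile(db, a)@alignedSeq, "")[[1]])
  mismPairs <- character()
  for (d in donorAlleles) {
    if (d %in% recipientAlleles) next
    prof <- getProfile(db, d)
    dseq <- strsplit(prof@alignedSeq, "")[[1]]
    for (p in surfacePositions(prof, threshold)) {
      res <- dseq[p]
      carried <- any(vapply(recSeqs, function(s) s[p] == res, FALSE))
      if (!carried) mismPairs <- c(mismPairs, paste0(p, res))
    }
  }
  length(unique(mismPairs))
}

#' Parse an eplet registry table
#'
#' Expected columns: \code{name}, \code{verified} (logical/0-1), and
#' \code{pattern} — space-separated position+residue tokens such as
#' \code{"62G 63E"}. Duplicate names, empty patterns and malformed tokens
#' are rejected with the offending row number.
#'
#' @param table CSV path or data.frame.
#' @return an \linkS4class{EpletRegistry}.
#' @export
loadEpletRegistry <- function(table) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  need <- c("name", "verified", "pattern")
  if (!all(need %in% names(table)))
    stop("registry needs columns name, verified, pattern")
  if (anyDuplicated(table$name))
    stop("duplicate eplet names: ",
         paste(unique(table$name[duplicated(table$name)]), collapse = ", "))
  pats <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    raw <- trimws(table$pattern[i])
    if (is.na(raw) || raw == "")
      stop("empty pattern at registry row ", i)
    toks <- strsplit(raw, "[[:space:]]+")[[1]]
    ok <- grepl("^[0-9]+[A-Z]$", toks)
    if (!all(ok))
      stop("malformed pattern token '", toks[!ok][1], "' at registry row ", i)
    pats[[i]] <- data.frame(
      position = as.integer(sub("[A-Z]$", "", toks)),
      residue = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
  }
  df <- data.frame(name = table$name,
                   verified = as.logical(table$verified),
                   stringsAsFactors = FALSE)
  df$pattern <- pats
  new("EpletRegistry", eplets = df)
}

setMethod("show", "EpletRegistry", function(object) {
  cat(sprintf("EpletRegistry: %d eplets (%d antibody-verified)\n",
              nrow(object@eplets), sum(object@eplets$verified)))
})

# is the eplet (all pattern residues) present on this aligned sequence?
.epletOn <- function(seqChars, pattern, nGrid) {
  if (any(pattern$position < 1L | pattern$position > nGrid))
    stop("registry error: eplet pattern position off the grid")
  all(seqChars[pattern$position] == pattern$residue)
}

#' Mismatched-eplet count for one donor locus
#'
#' An eplet counts when it is present on at least one donor allele of the
#' locus and on none of the recipient's Class I alleles (interlocus
#' comparison). Presence requires every (position, residue) pair of the
#' pattern; distinct eplet names count once.
#'
#' @param donorAlleles donor allele name(s) at one locus.
#' @param recipientAlleles recipient Class I allele names (up to six).
#' @param registry an \linkS4class{EpletRegistry}.
#' @param db the \linkS4class{AlleleDb} providing aligned sequences.
#' @param verifiedOnly restrict to antibody-verified eplets (AbvEPS);
#'   default counts all (AllEPS).
#' @return integer eplet mismatch count.
#' @export
epletMismatchCount <- function(donorAlleles, recipientAlleles, registry,
                               db, verifiedOnly = FALSE) {
  eps <- registry@eplets
  if (verifiedOnly) eps <- eps[eps$verified, , drop = FALSE]
  if (nrow(eps) == 0L) return(0L)
  n <- nPositions(db)
  dSeqs <- lapply(unique(donorAlleles), function(a)
    strsplit(getProfile(db, a)@alignedSeq, "")[[1]])
  rSeqs <- lapply(unique(recipientAlleles), function(a)
    strsplit(getProfile(db, a)@alignedSeq, "")[[1]])
  count <- 0L
  for (i in seq_len(nrow(eps))) {
    pat <- eps$pattern[[i]]
    onDonor <- any(vapply(dSeqs, .epletOn, FALSE, pattern = pat, nGrid = n))
    if (!onDonor) next
    onRec <- any(vapply(rSeqs, .epletOn, FALSE, pattern = pat, nGrid = n))
    if (!onRec) count <- count + 1L
  }
  count
}

#' Surrogate mismatched-peptide count per presenter locus
#'
#' A stand-in for indirect T-cell epitope counting: all core-length
#' windows of the donor allele's (ungapped) sequence that contain at
#' least one residue absent, at that aligned position, from every
#' recipient Class I allele are enumerated, and those accepted by the
#' presentation predicate are counted per presenter locus. The default
#' predicate accepts everything; a real peptide-MHC binding predictor can
#' be plugged in via \code{predicate(peptide, presenterAllele)}.
#'
#' @param donorAllele one donor allele name.
#' @param recipientAlleles recipient Class I allele names.
#' @param presenterAlleles named list: presenter locus -> allele names
#'   (the recipient's Class II repertoire).
#' @param db the \linkS4class{AlleleDb}.
#' @param predicate function(peptide, presenterAllele) -> logical, or
#'   NULL for accept-all.
#' @param coreLength peptide window length (default 9).
#' @return named integer vector, one count per presenter locus (a window
#'   counts for a locus when at least one of its alleles accepts it).
#' @export
pircheLikeCount <- function(donorAllele, recipientAlleles,
                            presenterAlleles, db, predicate = NULL,
                            coreLength = 9) {
  prof <- getProfile(db, donorAllele)
  dseq <- strsplit(prof@alignedSeq, "")[[1]]
  present <- which(dseq != "-")
  pep <- dseq[present]
  rSeqs <- lapply(unique(recipientAlleles), function(a)
    strsplit(getProfile(db, a)@alignedSeq, "")[[1]])
  mism <- vapply(seq_along(present), function(i) {
    p <- present[i]
    !any(vapply(rSeqs, function(s) s[p] == pep[i], FALSE))
  }, FALSE)
  out <- stats::setNames(integer(length(presenterAlleles)),
                         names(presenterAlleles))
  L <- length(pep)
  if (coreLength > L) {
    warning("coreLength exceeds donor sequence length; count is 0")
    return(out)
  }
  starts <- seq_len(L - coreLength + 1L)
  hasMism <- vapply(starts, function(s)
    any(mism[s:(s + coreLength - 1L)]), FALSE)
  starts <- starts[hasMism]
  if (!length(starts)) return(out)
  peps <- vapply(starts, function(s)
    paste(pep[s:(s + coreLength - 1L)], collapse = ""), "")
  for (loc in names(presenterAlleles)) {
    if (is.null(predicate)) {
      out[loc] <- length(peps)
    } else {
      acc <- vapply(peps, function(pp)
        any(vapply(unique(presenterAlleles[[loc]]),
                   function(al) isTRUE(predicate(pp, al)), FALSE)),
        FALSE)
      out[loc] <- sum(acc)
    }
  }
  out
}

#' Per-locus score set for one donor-recipient pair
#'
#' Computes, for each Class I locus of the donor, the Snowflake score,
#' both eplet counts (all and antibody-verified), and the surrogate
#' peptide count per presenter locus, together with matched/homozygous
#' flags used by the cohort pooling rules.
#'
#' @param donor,recipient \code{\link{genotype}} objects; the donor (or
#'   child) is the immunizer, the recipient (or mother) supplies the
#'   comparison repertoire and the presenter loci.
#' @param db the \linkS4class{AlleleDb}.
#' @param registry an \linkS4class{EpletRegistry}, or NULL to skip eplet
#'   counts.
#' @param threshold surface RSA cutoff.
#' @param mode Snowflake comparison mode (see
#'   \code{\link{snowflakeScore}}).
#' @param predicate,coreLength passed to \code{\link{pircheLikeCount}}.
#' @param caseId identifier copied into the output.
#' @return data.frame, one row per locus (A, B, C): case_id, locus,
#'   snowflake, all_eps, abv_eps, one \code{pirche_<locus>} column per
#'   presenter locus, matched, homozygous.
#' @export
locusScores <- function(donor, recipient, db, registry = NULL,
                        threshold = 0.3717,
                        mode = c("interlocus", "intralocus"),
                        predicate = NULL, coreLength = 9,
                        caseId = NA_character_) {
  mode <- match.arg(mode)
  loci <- intersect(CLASS_I_LOCI, names(donor))
  if (!all(CLASS_I_LOCI %in% names(donor)) ||
      !all(CLASS_I_LOCI %in% names(recipient)))
    stop("genotypes must cover loci A, B and C")
  recI <- classIAlleles(recipient)
  pres <- lapply(stats::setNames(presenterLoci(recipient),
                                 presenterLoci(recipient)),
                 function(L) recipient[[L]])
  rows <- lapply(loci, function(L) {
    dAl <- donor[[L]]
    snow <- snowflakeScore(dAl, recI, db, threshold = threshold,
                           mode = mode)
    allE <- abvE <- 0L
    if (!is.null(registry)) {
      allE <- epletMismatchCount(dAl, recI, registry, db,
                                 verifiedOnly = FALSE)
      abvE <- epletMismatchCount(dAl, recI, registry, db,
                                 verifiedOnly = TRUE)
    }
    row <- data.frame(case_id = caseId, locus = L, snowflake = snow,
                      all_eps = allE, abv_eps = abvE,
                      stringsAsFactors = FALSE)
    if (length(pres)) {
      tot <- stats::setNames(integer(length(pres)), names(pres))
      for (d in unique(dAl))
        tot <- tot + pircheLikeCount(d, recI, pres, db,
                                     predicate = predicate,
                                     coreLength = coreLength)
      for (pl in names(tot))
        row[[paste0("pirche_", pl)]] <- as.integer(tot[[pl]])
    }
    row$matched <- all(donor[[L]] %in% recipient[[L]])
    row$homozygous <- length(unique(donor[[L]])) == 1L
    row
  })
  do.call(rbind, rows)
}

#' Batch-score donor-recipient pairs from a table
#'
#' Mirrors the CSV-in/CSV-out batch interface: one row per case with
#' columns \code{case_id}, \code{donor_A1}, \code{donor_A2}, ...,
#' \code{recipient_C2} (plus optional presenter columns such as
#' \code{recipient_DRB1_1}).
#'
#' @param pairs CSV path or data.frame.
#' @param db,registry,threshold,mode,predicate,coreLength see
#'   \code{\link{locusScores}}.
#' @return data.frame of per-locus scores for all cases.
#' @export
scorePairs <- function(pairs, db, registry = NULL, threshold = 0.3717,
                       mode = "interlocus", predicate = NULL,
                       coreLength = 9) {
  if (is.character(pairs)) pairs <- read.csv(pairs, stringsAsFactors = FALSE)
  # columns are <side>_<locus>1 and <side>_<locus>2, e.g. donor_A1
  .sideGenotype <- function(row, side) {
    cols <- grep(paste0("^", side, "_[A-Za-z0-9]+[12]$"), names(row),
                 value = TRUE)
    loci <- unique(sub("[12]$", "", sub(paste0("^", side, "_"), "", cols)))
    args <- lapply(stats::setNames(loci, loci), function(L) {
      v <- unlist(row[paste0(side, "_", L, c("1", "2"))], use.names = FALSE)
      v <- v[!is.na(v) & v != ""]
      v
    })
    genotype(args)
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    row <- pairs[i, , drop = FALSE]
    locusScores(.sideGenotype(row, "donor"), .sideGenotype(row, "recipient"),
                db, registry = registry, threshold = threshold, mode = mode,
                predicate = predicate, coreLength = coreLength,
                caseId = as.character(row$case_id))
  })
  do.call(rbind, out)
}
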