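# Alignment grid construction and projection of sequences onto it.

#' Create an alignment grid
#'
#' @param consensus 1-letter consensus sequence defining the mature
#'   position coordinates.
#' @param locusGroup label for the locus group the grid serves.
#' @return an \linkS4class{AlignmentGrid}.
#' @export
alignmentGrid <- function(consensus, locusGroup = "ClassI") {
  new("AlignmentGrid", locusGroup = locusGroup,
      consensus = toupper(consensus))
}

#' @describeIn nPositions grid size of an AlignmentGrid.
#' @export
setMethod("nPositions", "AlignmentGrid",
          function(x) nchar(x@consensus))

setMethod("show", "AlignmentGrid", function(object) {
  cat(sprintf("AlignmentGrid (%s): %d positions\n",
              object@locusGroup, nchar(object@consensus)))
})

# Needleman-Wunsch via Biostrings; returns aligned strings split to chars.
.globalAlign <- function(pattern, subject) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 4, type = "global")
  list(pattern = strsplit(as.character(Biostrings::alignedPattern(aln)),
                          "")[[1]],
       subject = strsplit(as.character(Biostrings::alignedSubject(aln)),
                          "")[[1]])
}

#' Project a protein sequence onto a grid
#'
#' Globally aligns the sequence against the grid consensus and reads off
#' one residue (or gap) per consensus column; insertions relative to the
#' consensus are dropped. Sequences too unlike the consensus — below 70
#' percent identity over their aligned residues — are rejected, which
#' catches wrong-locus-group input.
#'
#' @param sequence 1-letter amino-acid string.
#' @param grid an \linkS4class{AlignmentGrid}.
#' @param minIdentity rejection threshold on aligned identity.
#' @return list with \code{aligned} (string of grid length, gaps as
#'   \code{"-"}) and \code{identity} (fraction in \[0, 1\]).
#' @export
alignToGrid <- function(sequence, grid, minIdentity = 0.70) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence))
    stop("sequence contains non-standard amino-acid letters")
  aln <- .globalAlign(sequence, grid@consensus)
  n <- nPositions(grid)
  out <- character(n)
  i <- 0L
  matches <- 0L; present <- 0L
  for (col in seq_along(aln$subject)) {
    if (aln$subject[col] == "-") next  # insertion relative to consensus
    i <- i + 1L
    out[i] <- aln$pattern[col]
    if (out[i] != "-") {
      present <- present + 1L
      if (out[i] == aln$subject[col]) matches <- matches + 1L
    }
  }
  identity <- if (present > 0L) matches / present else 0
  if (identity < minIdentity)
    stop(sprintf(
      "alignment-rejected: identity %.2f to consensus below %.2f (wrong locus group?)",
      identity, minIdentity))
  list(aligned = paste(out, collapse = ""), identity = identity)
}
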