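#' Alignment grid for one locus group
#'
#' A fixed coordinate system (mature-protein positions, 1-based) shared by
#' every allele profile in a database. The consensus sequence defines the
#' number of positions; alleles are projected onto it by global alignment,
#' so cross-allele and interlocus position-wise comparison is well defined.
#'
#' @slot locusGroup identifier of the locus group (e.g. \code{"ClassI"}).
#' @slot consensus 1-letter consensus sequence; its length is the grid size.
#' @export
setClass("AlignmentGrid",
  representation(locusGroup = "character", consensus = "character"))

setValidity("AlignmentGrid", function(object) {
  msg <- character()
  if (length(object@consensus) != 1L || nchar(object@consensus) < 1L)
    msg <- c(msg, "consensus must be a single non-empty string")
  if (grepl("-", object@consensus, fixed = TRUE))
    msg <- c(msg, "consensus may not contain gap characters")
  if (length(msg)) msg else TRUE
})

#' One allele's aligned sequence and accessibility profile
#'
#' Holds an allele's sequence on the database grid together with its
#' per-position relative solvent accessibility (RSA = SASA / maximal ASA of
#' the residue type). RSA is \code{NA} where the allele has an alignment
#' gap or the structure lacked density — never 0, which means genuinely
#' buried.
#'
#' @slot allele WHO-style allele name, e.g. \code{"A*01:01"}.
#' @slot alignedSeq 1-letter sequence of grid length, \code{"-"} for gaps.
#' @slot rsa numeric vector of grid length; values in \[0, 1.5\] or NA.
#' @slot provenance \code{"experimental"} (from a structure) or
#'   \code{"predicted"} (from the sequence-to-surface predictor).
#' @export
setClass("AlleleProfile",
  representation(allele = "character", alignedSeq = "character",
                 rsa = "numeric", provenance = "character"))

setValidity("AlleleProfile", function(object) {
  msg <- character()
  n <- nchar(object@alignedSeq)
  if (length(object@rsa) != n)
    msg <- c(msg, "rsa length must equal alignedSeq length")
  ok <- is.na(object@rsa) | (object@rsa >= 0 & object@rsa <= 1.5)
  if (!all(ok))
    msg <- c(msg, "rsa values must lie in [0, 1.5] or be NA")
  gaps <- strsplit(object@alignedSeq, "")[[1]] == "-"
  if (any(gaps & !is.na(object@rsa)))
    msg <- c(msg, "rsa must be NA at gap positions")
  if (!object@provenance %in% c("experimental", "predicted"))
    msg <- c(msg, "provenance must be 'experimental' or 'predicted'")
  if (length(msg)) msg else TRUE
})

#' Database of allele accessibility profiles on a common grid
#'
#' @slot grid the shared \linkS4class{AlignmentGrid}.
#' @slot profiles named list of \linkS4class{AlleleProfile}, keyed by
#'   allele name; duplicate names are rejected.
#' @export
setClass("AlleleDb",
  representation(grid = "AlignmentGrid", profiles = "list"))

setValidity("AlleleDb", function(object) {
  msg <- character()
  nm <- names(object@profiles)
  if (length(object@profiles) &&
      (is.null(nm) || any(nm == "") || anyDuplicated(nm)))
    msg <- c(msg, "profiles must be uniquely named by allele")
  n <- nchar(object@grid@consensus)
  for (p in object@profiles) {
    if (!is(p, "AlleleProfile")) {
      msg <- c(msg, "profiles must all be AlleleProfile objects"); break
    }
    if (nchar(p@alignedSeq) != n) {
      msg <- c(msg, sprintf("profile %s is not on the database grid", p@allele))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Sequence-to-surface predictor contract
#'
#' Virtual parent for accessibility predictors: anything that, once
#' fitted, deterministically maps an aligned sequence to a per-position
#' RSA profile may be plugged into \code{\link{predictProfile}}.
#' @export
setClass("SurfacePredictor", representation("VIRTUAL"))

#' k-nearest-allele accessibility predictor
#'
#' Reference implementation of the \linkS4class{SurfacePredictor} contract:
#' the k training alleles most similar to the query by position-wise
#' sequence identity contribute a position-wise mean RSA. Ties in
#' similarity are broken by lexicographic allele name, so prediction is
#' deterministic. Predicting a sequence identical to a training allele
#' returns that allele's profile.
#'
#' @slot grid the training grid.
#' @slot training named list of training \linkS4class{AlleleProfile}s.
#' @slot k number of neighbours averaged.
#' @export
setClass("KnnSurfacePredictor", contains = "SurfacePredictor",
  representation(grid = "AlignmentGrid", training = "list", k = "integer"))

setValidity("KnnSurfacePredictor", function(object) {
  msg <- character()
  if (length(object@training) < 1L)
    msg <- c(msg, "training set must be non-empty")
  if (object@k < 1L)
    msg <- c(msg, "k must be >= 1")
  n <- nchar(object@grid@consensus)
  if (any(vapply(object@training, function(p) nchar(p@alignedSeq), 0L) != n))
    msg <- c(msg, "training profiles are on mismatched grids")
  if (length(msg)) msg else TRUE
})

#' Registry of eplet definitions
#'
#' Each eplet is a named configuration of (mature position, residue) pairs
#' with an antibody-verified flag. An eplet is present on an allele only
#' if every pair of its pattern matches the allele's aligned sequence.
#'
#' @slot eplets data.frame with columns \code{name}, \code{verified}
#'   (logical) and the list column \code{pattern} (each element a
#'   data.frame with \code{position}, \code{residue}).
#' @export
setClass("EpletRegistry", representation(eplets = "data.frame"))

setValidity("EpletRegistry", function(object) {
  df <- object@eplets
  msg <- character()
  need <- c("name", "verified", "pattern")
  if (!all(need %in% names(df)))
    msg <- c(msg, "eplets needs columns name, verified, pattern")
  else {
    if (anyDuplicated(df$name))
      msg <- c(msg, "duplicate eplet names")
    if (any(vapply(df$pattern, nrow, 0L) == 0L))
      msg <- c(msg, "empty eplet pattern")
  }
  if (length(msg)) msg else TRUE
})
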