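# Allele profile database, accessors, and the k-nearest-allele
# sequence-to-surface predictor.

#' Construct an allele profile
#'
#' @param allele allele name (e.g. \code{"A*02:01"}).
#' @param alignedSeq grid-length 1-letter sequence (gaps \code{"-"}).
#' @param rsa per-position relative accessibility; values are clipped to
#'   \[0, 1.5\], gaps forced to NA.
#' @param provenance \code{"experimental"} or \code{"predicted"}.
#' @return an \linkS4class{AlleleProfile}.
#' @export
alleleProfile <- function(allele, alignedSeq, rsa,
                          provenance = "experimental") {
  alignedSeq <- toupper(alignedSeq)
  gaps <- strsplit(alignedSeq, "")[[1]] == "-"
  rsa <- pmin(pmax(rsa, 0), 1.5)
  rsa[gaps] <- NA_real_
  new("AlleleProfile", allele = allele, alignedSeq = alignedSeq,
      rsa = as.numeric(rsa), provenance = provenance)
}

#' Build an allele database
#'
#' @param grid the shared \linkS4class{AlignmentGrid}.
#' @param profiles list of \linkS4class{AlleleProfile}s; profiles of the
#'   same allele name are averaged position-wise (multiple structures of
#'   one allele), different alleles must be unique.
#' @return an \linkS4class{AlleleDb}.
#' @export
buildAlleleDb <- function(grid, profiles) {
  nm <- vapply(profiles, function(p) p@allele, "")
  merged <- list()
  for (a in unique(nm)) {
    ps <- profiles[nm == a]
    if (length(ps) == 1L) {
      merged[[a]] <- ps[[1]]
    } else {
      # average per-position rsa across structures of one allele
      m <- do.call(rbind, lapply(ps, function(p) p@rsa))
      rsa <- colMeans(m, na.rm = TRUE)
      rsa[is.nan(rsa)] <- NA_real_
      merged[[a]] <- alleleProfile(a, ps[[1]]@alignedSeq, rsa,
                                   provenance = ps[[1]]@provenance)
    }
  }
  new("AlleleDb", grid = grid, profiles = merged)
}

#' Allele names in a database
#' @param x an \linkS4class{AlleleDb} or predictor.
#' @return character vector of allele names.
#' @rdname alleleNames
#' @export
setMethod("alleleNames", "AlleleDb", function(x) names(x@profiles))

#' Look up one allele's profile
#' @param x an \linkS4class{AlleleDb}.
#' @param allele allele name; unknown names raise an error naming the
#'   allele.
#' @return an \linkS4class{AlleleProfile}.
#' @rdname getProfile
#' @export
setMethod("getProfile", "AlleleDb", function(x, allele) {
  p <- x@profiles[[allele]]
  if (is.null(p))
    stop("allele not in database: ", allele)
  p
})

#' @describeIn nPositions grid size of the database.
#' @export
setMethod("nPositions", "AlleleDb", function(x) nPositions(x@grid))

setMethod("show", "AlleleDb", function(object) {
  prov <- table(vapply(object@profiles, function(p) p@provenance, ""))
  cat(sprintf("AlleleDb: %d alleles on a %d-position %s grid\n",
              length(object@profiles), nPositions(object@grid),
              object@grid@locusGroup))
  if (length(prov))
    cat("  provenance:",
        paste(sprintf("%s=%d", names(prov), prov), collapse = ", "), "\n")
})

setMethod("show", "AlleleProfile", function(object) {
  cat(sprintf("AlleleProfile %s (%s): %d positions, %d with rsa\n",
              object@allele, object@provenance, nchar(object@alignedSeq),
              sum(!is.na(object@rsa))))
})

#' Fit the k-nearest-allele accessibility predictor
#'
#' The reference implementation of the sequence-to-surface contract:
#' training profiles are memorized and a query is answered by the
#' position-wise mean RSA of its k most sequence-similar training
#' alleles. Any predictor honouring \code{\link{predictProfile}} can be
#' swapped in.
#'
#' @param training an \linkS4class{AlleleDb} or list of
#'   \linkS4class{AlleleProfile}s on one grid.
#' @param k neighbours to average (default 3).
#' @param grid required when \code{training} is a bare list.
#' @return a \linkS4class{KnnSurfacePredictor}.
#' @export
fitPredictor <- function(training, k = 3, grid = NULL) {
  if (is(training, "AlleleDb")) {
    grid <- training@grid
    training <- training@profiles
  }
  if (length(training) == 0L) stop("training set must be non-empty")
  if (is.null(grid)) stop("grid required when training is a list")
  names(training) <- vapply(training, function(p) p@allele, "")
  n <- nPositions(grid)
  if (any(vapply(training, function(p) nchar(p@alignedSeq), 0L) != n))
    stop("grid-mismatch: training profiles on different grids")
  new("KnnSurfacePredictor", grid = grid, training = training,
      k = as.integer(k))
}

# fraction of positions, where both sequences have a residue, that agree
.seqIdentity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  both <- va != "-" & vb != "-"
  if (!any(both)) return(0)
  mean(va[both] == vb[both])
}

#' @rdname predictProfile
#' @export
setMethod("predictProfile", "KnnSurfacePredictor",
  function(object, alignedSeq, allele = "predicted") {
    alignedSeq <- toupper(alignedSeq)
    n <- nPositions(object@grid)
    if (nchar(alignedSeq) != n)
      stop("grid-mismatch: sequence length ", nchar(alignedSeq),
           " != grid size ", n)
    trainSeqs <- vapply(object@training, function(p) p@alignedSeq, "")
    exact <- which(trainSeqs == alignedSeq)
    if (length(exact)) {
      nb <- exact[order(names(object@training)[exact])]
    } else {
      ident <- vapply(trainSeqs, .seqIdentity, 0, a = alignedSeq)
      ord <- order(-ident, names(object@training))
      nb <- ord[seq_len(min(object@k, length(ord)))]
    }
    m <- do.call(rbind, lapply(object@training[nb], function(p) p@rsa))
    rsa <- colMeans(m, na.rm = TRUE)
    rsa[is.nan(rsa)] <- NA_real_
    gaps <- strsplit(alignedSeq, "")[[1]] == "-"
    rsa[gaps] <- NA_real_
    # non-gap positions must carry a value: fall back on the grid mean
    hole <- !gaps & is.na(rsa)
    if (any(hole)) {
      allm <- do.call(rbind, lapply(object@training, function(p) p@rsa))
      fill <- colMeans(allm, na.rm = TRUE)
      fill[is.nan(fill)] <- 0
      rsa[hole] <- fill[hole]
    }
    alleleProfile(allele, alignedSeq, rsa, provenance = "predicted")
  })

setMethod("show", "KnnSurfacePredictor", function(object) {
  cat(sprintf("KnnSurfacePredictor: k=%d, %d training alleles, %d positions\n",
              object@k, length(object@training), nPositions(object@grid)))
})

#' Solvent-accessible positions of a profile
#'
#' @param profile an \linkS4class{AlleleProfile}.
#' @param threshold RSA cutoff; positions with \code{rsa >= threshold}
#'   count as surface. The packaged default 0.3717 is the reference-panel
#'   median accessibility score.
#' @return integer vector of mature positions (gaps and absent positions
#'   never included).
#' @export
surfacePositions <- function(profile, threshold = 0.3717) {
  if (threshold < 0) stop("threshold must be >= 0")
  which(!is.na(profile@rsa) & profile@rsa >= threshold)
}

#' Persist an allele database as CSV
#'
#' Long format: allele, position, residue, rsa, provenance. Gap positions
#' are omitted; absent rsa at a present residue is written as NA.
#'
#' @param db an \linkS4class{AlleleDb}.
#' @param file output CSV path.
#' @export
writeProfileDb <- function(db, file) {
  rows <- lapply(db@profiles, function(p) {
    aa <- strsplit(p@alignedSeq, "")[[1]]
    keep <- aa != "-"
    data.frame(allele = p@allele, position = which(keep),
               residue = aa[keep], rsa = p@rsa[keep],
               provenance = p@provenance, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read an allele database written by \code{writeProfileDb}
#'
#' @param file CSV path.
#' @param grid the \linkS4class{AlignmentGrid} the profiles live on.
#' @return an \linkS4class{AlleleDb}.
#' @export
readProfileDb <- function(file, grid) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  n <- nPositions(grid)
  profs <- lapply(split(tab, tab$allele), function(d) {
    aa <- rep("-", n); rsa <- rep(NA_real_, n)
    aa[d$position] <- d$residue
    rsa[d$position] <- d$rsa
    alleleProfile(d$allele[1], paste(aa, collapse = ""), rsa,
                  provenance = d$provenance[1])
  })
  buildAlleleDb(grid, unname(profs))
}
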