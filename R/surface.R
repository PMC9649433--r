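# Shrake-Rupley solvent-accessible surface area and per-residue profiles.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) construction: point k of n gets latitude
#' z = 1 - (2k-1)/n and longitude k times the golden angle. No randomness
#' is involved, so the quadrature is identical across calls — a fixed
#' point set makes the whole SASA pipeline bit-reproducible.
#'
#' @param n number of points (>= 1).
#' @return an n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Load the van der Waals radius table
#'
#' NACCESS-style element radii (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom)
#' shipped with the package; a custom CSV with columns element,radius may
#' be supplied instead.
#'
#' @param path CSV path; default = packaged table.
#' @return named numeric vector, element symbol -> radius (Angstrom).
#' @export
readVdwRadii <- function(path = system.file("extdata", "vdw_radii.csv",
                                            package = "snowmatch")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, toupper(tab$element))
}

#' Load the maximal accessible surface area table
#'
#' Theoretical per-residue maxima (Tien et al. values) used to normalize
#' SASA to relative solvent accessibility.
#'
#' @param path CSV path; default = packaged table.
#' @return named numeric vector, 1-letter amino acid -> max ASA (Angstrom^2).
#' @export
readMaxAsa <- function(path = system.file("extdata", "maxasa_tien2013.csv",
                                          package = "snowmatch")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$maxasa, toupper(tab$aa))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is inflated by the probe radius and covered with a fixed
#' quasi-uniform test-point set; a point is buried when it falls inside
#' any neighbouring atom's inflated sphere. SASA = exposed fraction times
#' the inflated sphere area 4*pi*(r_vdw + probe)^2.
#'
#' @param atoms data.frame with columns \code{x,y,z} (Angstrom) and
#'   \code{radius} (van der Waals, Angstrom).
#' @param probeRadius solvent probe radius, Angstrom (water: 1.4).
#' @param nPoints test points per atom; 960 keeps the isolated-sphere
#'   error well under 0.5\%.
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
computeSasa <- function(atoms, probeRadius = 1.4, nPoints = 960) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L)
    stop("atoms must be a non-empty data.frame")
  need <- c("x", "y", "z", "radius")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns x, y, z, radius")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("non-finite atom coordinate")
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0))
    stop("vdw radii must be positive and finite")
  if (probeRadius < 0) stop("probeRadius must be >= 0")
  if (anyDuplicated(coords))
    warning("duplicate atom coordinates present")

  S <- spherePoints(nPoints)
  R <- atoms$radius + probeRadius
  n <- nrow(atoms)
  D2 <- as.matrix(stats::dist(coords))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- R[i]
    nb <- which(D2[i, ] < (Ri + R)^2)
    nb <- nb[nb != i]
    pts <- S * Ri
    pts[, 1] <- pts[, 1] + coords[i, 1]
    pts[, 2] <- pts[, 2] + coords[i, 2]
    pts[, 3] <- pts[, 3] + coords[i, 3]
    exposed <- rep(TRUE, nrow(S))
    for (j in nb) {
      if (!any(exposed)) break
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
            (pts[, 3] - coords[j, 3])^2
      exposed <- exposed & (d2 >= R[j]^2)
    }
    sasa[i] <- sum(exposed) / nrow(S) * 4 * pi * Ri^2
  }
  sasa
}

#' Aggregate per-atom SASA to per-residue SASA and RSA
#'
#' Residue SASA is the sum over the residue's atoms; RSA divides by the
#' residue type's maximal ASA. Residues whose 3-letter name is not a
#' standard amino acid are skipped with a warning (or rejected when
#' \code{strict = TRUE}).
#'
#' @param atoms data.frame with \code{chain}, \code{resno}, \code{resid}
#'   (3-letter residue name) identifying each atom's residue.
#' @param sasa per-atom SASA as returned by \code{\link{computeSasa}}.
#' @param maxAsa named max-ASA vector (see \code{\link{readMaxAsa}}).
#' @param strict fail instead of skipping unknown residue names.
#' @return data.frame: chain, resno, aa (1-letter), sasa, rsa; ordered by
#'   (chain, resno).
#' @export
residueSurfaces <- function(atoms, sasa, maxAsa = readMaxAsa(),
                            strict = FALSE) {
  if (nrow(atoms) != length(sasa))
    stop("sasa must have one value per atom")
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  resTot <- tapply(sasa, key, sum)
  first <- !duplicated(key)
  info <- atoms[first, c("chain", "resno", "resid")]
  info <- info[order(info$chain, info$resno), ]
  aa <- AA3TO1[toupper(info$resid)]
  unknown <- is.na(aa)
  if (any(unknown)) {
    msg <- sprintf("unknown residue name(s): %s",
                   paste(unique(info$resid[unknown]), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; skipped")
  }
  info <- info[!unknown, , drop = FALSE]
  aa <- aa[!unknown]
  if (!all(aa %in% names(maxAsa)))
    stop("amino acid missing from maxAsa table")
  s <- as.numeric(resTot[paste(info$chain, info$resno, sep = "\r")])
  data.frame(chain = info$chain, resno = info$resno, aa = unname(aa),
             sasa = s, rsa = s / unname(maxAsa[aa]),
             stringsAsFactors = FALSE)
}

# Extract ATOM records from a bio3d pdb object: first altloc only,
# HETATM/waters/ions dropped; attach vdw radii by element symbol.
.atomTable <- function(pdb, radii) {
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in structure")
  ele <- toupper(at$elesy)
  miss <- is.na(ele) | ele == ""
  if (any(miss)) {
    # fall back on the first letter of the atom name
    nm <- gsub("[0-9 ]", "", at$elety[miss])
    ele[miss] <- substr(nm, 1, 1)
  }
  r <- radii[ele]
  r[is.na(r)] <- radii[["X"]]
  data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
             elety = at$elety, x = at$x, y = at$y, z = at$z,
             radius = as.numeric(r), stringsAsFactors = FALSE)
}

# 1-letter sequence of one chain, residues ordered by author numbering.
.chainSequence <- function(atoms, chainId) {
  sel <- atoms[atoms$chain == chainId, , drop = FALSE]
  first <- !duplicated(sel$resno)
  res <- sel[first, , drop = FALSE]
  res <- res[order(res$resno), , drop = FALSE]
  aa <- AA3TO1[toupper(res$resid)]
  keep <- !is.na(aa)
  list(resno = res$resno[keep], seq = paste(aa[keep], collapse = ""))
}

#' Allele accessibility profile from a structure
#'
#' Computes SASA over all chains of the structure (bound peptide and any
#' light chain act as occluders), then reports per-residue RSA for the
#' heavy chain only, mapped onto the mature-protein positions of a
#' reference sequence by global alignment. Positions missing from the
#' coordinates (no density, or alignment gap) come back as \code{NA} —
#' absent, not buried.
#'
#' @param pdb path to a PDB file or a \code{bio3d} pdb object.
#' @param referenceSeq mature-protein reference sequence (1-letter).
#' @param heavyChain chain id, or \code{"auto"} to take the longest chain
#'   (which must have at least 80 residues).
#' @param allele name for the returned profile.
#' @param probeRadius,nPoints passed to \code{\link{computeSasa}}.
#' @param radii,maxAsa lookup tables (packaged defaults).
#' @param minIdentity minimum alignment identity between the chain and
#'   the reference over aligned columns (default 0.95).
#' @return an \linkS4class{AlleleProfile} on the grid defined by
#'   \code{referenceSeq} (provenance \code{"experimental"}).
#' @export
profileFromStructure <- function(pdb, referenceSeq, heavyChain = "auto",
                                 allele = "structure",
                                 probeRadius = 1.4, nPoints = 960,
                                 radii = readVdwRadii(),
                                 maxAsa = readMaxAsa(),
                                 minIdentity = 0.95) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  atoms <- .atomTable(pdb, radii)
  chains <- unique(atoms$chain)
  if (identical(heavyChain, "auto")) {
    sizes <- vapply(chains, function(ch)
      length(unique(atoms$resno[atoms$chain == ch])), 0L)
    heavyChain <- chains[which.max(sizes)]
    if (max(sizes) < 80L)
      stop("chain-selection error: no chain with >= 80 residues; ",
           "pass heavyChain explicitly")
  }
  if (!heavyChain %in% chains)
    stop("chain ", heavyChain, " not present in structure")

  sasa <- computeSasa(atoms, probeRadius = probeRadius, nPoints = nPoints)
  surf <- residueSurfaces(atoms[atoms$chain == heavyChain, , drop = FALSE],
                          sasa[atoms$chain == heavyChain], maxAsa = maxAsa)

  cs <- .chainSequence(atoms, heavyChain)
  aln <- .globalAlign(cs$seq, referenceSeq)
  # columns of the reference (subject); identity over aligned columns
  both <- aln$pattern != "-" & aln$subject != "-"
  ident <- sum(aln$pattern == aln$subject & both) / sum(both)
  if (ident < minIdentity)
    stop(sprintf(
      "structure-sequence-mismatch: identity %.2f below %.2f",
      ident, minIdentity))

  nref <- nchar(referenceSeq)
  rsa <- rep(NA_real_, nref)
  seqOut <- strsplit(referenceSeq, "")[[1]]
  rsaByResno <- stats::setNames(surf$rsa, surf$resno)
  ip <- 0L; iref <- 0L
  for (col in seq_along(aln$pattern)) {
    pc <- aln$pattern[col]; sc <- aln$subject[col]
    if (pc != "-") ip <- ip + 1L
    if (sc != "-") iref <- iref + 1L
    if (pc != "-" && sc != "-") {
      v <- rsaByResno[as.character(cs$resno[ip])]
      if (!is.na(v)) rsa[iref] <- min(max(v, 0), 1.5)
    }
  }
  new("AlleleProfile", allele = allele,
      alignedSeq = paste(seqOut, collapse = ""),
      rsa = rsa, provenance = "experimental")
}

#' Write a per-residue surface table as CSV
#'
#' @param profile an \linkS4class{AlleleProfile}.
#' @param file output CSV path.
#' @param structureId identifier written in the first column.
#' @param chain chain id column value.
#' @param maxAsa max-ASA table used to recover absolute areas from RSA.
#' @return the written data.frame, invisibly.
#' @export
writeSurfaceTable <- function(profile, file, structureId = profile@allele,
                              chain = "A", maxAsa = readMaxAsa()) {
  aa <- strsplit(profile@alignedSeq, "")[[1]]
  keep <- !is.na(profile@rsa)
  rsa <- profile@rsa[keep]
  df <- data.frame(structure_id = structureId, chain = chain,
                   mature_position = which(keep), amino_acid = aa[keep],
                   sasa = rsa * unname(maxAsa[aa[keep]]), rsa = rsa)
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}
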