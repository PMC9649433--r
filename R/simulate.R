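# Synthetic fixtures: toy structures, allele pools with true
# accessibility, eplet registries, haplotype/MAC/serology tables, and
# pregnancy / kidney-transplant cohorts with outcome models.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators. Defaults encode the
#' emulated study conditions: a pregnancy-cohort-sized case count, a CSA
#' base rate near the observed pooled positive fraction, a true
#' Snowflake effect of OR 1.63 per SD on the logit scale (the pregnancy
#' design) and HR 1.32 per SD on the log-hazard scale (the transplant
#' design).
#'
#' @param seed integer master seed; identical config + seed give
#'   bit-identical output.
#' @param allelesPerLocus Class I alleles generated per locus.
#' @param gridLength alignment grid length (mature positions).
#' @param surfaceFraction fraction of positions that are true surface in
#'   sequence-designed profiles.
#' @param nStructures alleles (of locus A) that get a toy 3D structure;
#'   their truth profile is the structure-computed one.
#' @param nHaplotypes rows of the haplotype frequency table.
#' @param nCases cases per simulated cohort.
#' @param beta0 logit-scale intercept of the CSA outcome model.
#' @param betaSnowflake logit-scale effect per SD of true Snowflake.
#' @param betaKtc log-hazard effect per SD of true Snowflake (KTC).
#' @param baselineHazard exponential DSA hazard at z = 0, per year.
#' @param maxFollowUp upper bound of uniform censoring, years.
#' @param mfiNoiseSd log-scale SD of single-antigen-bead noise.
#' @param threshold surface RSA cutoff used for true scores.
#' @param nEplets registry size.
#' @param macRate probability an intermediate-resolution Class I token is
#'   a multiple-allele code rather than a serologic antigen.
#' @param crossLocusCoupling logit-scale coefficient coupling a locus's
#'   CSA risk to the other loci's z-scores (0 = no coupling).
#' @param coreLength surrogate peptide window length.
#' @return validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, allelesPerLocus = 6L,
                             gridLength = 50L, surfaceFraction = 0.4,
                             nStructures = 2L, nHaplotypes = 12L,
                             nCases = 231L, beta0 = stats::qlogis(0.21),
                             betaSnowflake = log(1.63),
                             betaKtc = log(1.32), baselineHazard = 0.025,
                             maxFollowUp = 10, mfiNoiseSd = 0.3,
                             threshold = 0.3717, nEplets = 60L,
                             macRate = 0.3, crossLocusCoupling = 0,
                             coreLength = 9L) {
  cfg <- list(seed = as.integer(seed),
              allelesPerLocus = as.integer(allelesPerLocus),
              gridLength = as.integer(gridLength),
              surfaceFraction = surfaceFraction,
              nStructures = as.integer(nStructures),
              nHaplotypes = as.integer(nHaplotypes),
              nCases = as.integer(nCases), beta0 = beta0,
              betaSnowflake = betaSnowflake, betaKtc = betaKtc,
              baselineHazard = baselineHazard, maxFollowUp = maxFollowUp,
              mfiNoiseSd = mfiNoiseSd, threshold = threshold,
              nEplets = as.integer(nEplets), macRate = macRate,
              crossLocusCoupling = crossLocusCoupling,
              coreLength = as.integer(coreLength))
  with(cfg, {
    stopifnot(allelesPerLocus >= 2, gridLength >= 10,
              surfaceFraction > 0, surfaceFraction < 1,
              nStructures >= 0, nHaplotypes >= 2, nCases >= 1,
              baselineHazard > 0, maxFollowUp > 0, mfiNoiseSd > 0,
              macRate >= 0, macRate <= 1, coreLength >= 1)
  })
  structure(cfg, class = "SimulationConfig")
}

#' Toy alpha-helix structure for a sequence
#'
#' Builds an idealized helical backbone (N, CA, C, O per residue, 100
#' degrees twist and 1.5 Angstrom rise per residue) with one dummy
#' side-chain sphere per non-glycine residue, pointing outward and
#' coarsely sized by residue bulk. Enough geometry to exercise the SASA
#' machinery; no claim to a real fold.
#'
#' @param sequence 1-letter amino-acid string.
#' @param chain chain identifier.
#' @return character vector of PDB-format lines.
#' @export
makeHelixStructure <- function(sequence, chain = "A") {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% AA20)) stop("non-standard amino acid in sequence")
  aa3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))
  small <- c("G", "A", "S", "C", "T", "P", "V", "N", "D")
  large <- c("W", "Y", "F", "R", "K", "H", "M")
  lines <- character(); serial <- 0L
  emit <- function(name, resIdx, resName, x, y, z, ele) {
    serial <<- serial + 1L
    # standard ATOM record columns (name 13-16, resName 18-20, chain 22,
    # resSeq 23-26, x/y/z 31-54, element 77-78)
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), "", resName, chain, resIdx, "",
            x, y, z, 1.0, 0.0, ele)
  }
  for (i in seq_along(aa)) {
    th <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    r3 <- aa3[[aa[i]]]
    lines <- c(lines,
      emit("N",  i, r3, 2.3 * cos(th - 0.45), 2.3 * sin(th - 0.45), z0 - 0.9, "N"),
      emit("CA", i, r3, 2.3 * cos(th),        2.3 * sin(th),        z0,       "C"),
      emit("C",  i, r3, 2.3 * cos(th + 0.45), 2.3 * sin(th + 0.45), z0 + 0.7, "C"),
      emit("O",  i, r3, 2.9 * cos(th + 0.55), 2.9 * sin(th + 0.55), z0 + 1.2, "O"))
    if (aa[i] != "G") {
      ele <- if (aa[i] %in% small) "O" else if (aa[i] %in% large) "S" else "C"
      lines <- c(lines,
        emit("CB", i, r3, 3.6 * cos(th), 3.6 * sin(th), z0 + 0.2, ele))
    }
  }
  c(lines, "END")
}

# deterministic presenter-dependent presentation predicate used by the
# generators to exercise the pluggable surrogate interface
.simPredicate <- function(peptide, presenter) {
  s <- paste0(peptide, "|", presenter)
  h <- sum(utf8ToInt(s) * seq_len(nchar(s)))
  (h %% 10L) < 3L  # ~30% presented: binding predictors accept a minority
}

#' Generate a synthetic allele pool
#'
#' Produces everything downstream modules consume: a Class I alignment
#' grid with allele sequences and true RSA profiles (surface positions
#' carry RSA above the threshold, buried ones below), toy helix
#' structures for a subset of alleles (their truth is the
#' structure-computed profile, so structure-module round-trips are exact
#' by construction), an eplet registry derived from polymorphic surface
#' positions (so eplet and Snowflake scores correlate by construction),
#' a haplotype frequency table summing to 1, a MAC table and a serology
#' map.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list of class \code{"AllelePool"}: \code{grid}, \code{db},
#'   \code{registry}, \code{haplotypes}, \code{mac}, \code{serology},
#'   \code{structureText} (named list of PDB lines), \code{predicate},
#'   \code{config}.
#' @export
makeAllelePool <- function(config = simulationConfig()) {
  set.seed(config$seed)
  L <- config$gridLength
  nSurf <- round(L * config$surfaceFraction)
  consensus <- paste(sample(AA20, L, replace = TRUE), collapse = "")
  grid <- alignmentGrid(consensus)

  surfCand <- sort(sample(L, min(L, nSurf + 4L)))
  # buried polymorphism (the peptide-groove positions of real Class I):
  # invisible to the surface mismatch count but a source of mismatched
  # peptides, so the two score families decouple realistically
  nBuriedPoly <- max(2L, round(L * 0.2))
  buriedPool <- setdiff(seq_len(L), surfCand)
  polyBuried <- sort(sample(buriedPool, min(nBuriedPoly, length(buriedPool))))
  polyPos <- sort(c(surfCand, polyBuried))
  consChars <- strsplit(consensus, "")[[1]]
  alphabets <- lapply(polyPos, function(p)
    unique(c(consChars[p], sample(setdiff(AA20, consChars[p]), 2))))
  names(alphabets) <- as.character(polyPos)

  nGroups <- ceiling(config$allelesPerLocus / 2)
  profiles <- list(); serRows <- list(); macGroups <- list()
  for (loc in CLASS_I_LOCI) {
    for (i in seq_len(config$allelesPerLocus)) {
      grp <- (i - 1L) %/% 2L + 1L
      within <- (i - 1L) %% 2L + 1L
      allele <- sprintf("%s*%02d:%02d", loc, grp, within)
      sq <- consChars
      for (k in seq_along(polyPos))
        sq[polyPos[k]] <- sample(alphabets[[k]], 1)
      mySurf <- sort(sample(surfCand, nSurf))
      rsa <- stats::runif(L, 0, 0.25)
      rsa[mySurf] <- stats::runif(nSurf, 0.45, 1.0)
      profiles[[allele]] <- alleleProfile(allele, paste(sq, collapse = ""),
                                          rsa, provenance = "predicted")
      serRows[[allele]] <- data.frame(
        allele = allele, antigen = sprintf("%s%d", loc, grp),
        stringsAsFactors = FALSE)
      key <- sprintf("%s*%02d", loc, grp)
      macGroups[[key]] <- c(macGroups[[key]], allele)
    }
  }

  # toy structures for the first nStructures alleles of locus A: their
  # computed profile replaces the designed truth
  structureText <- list()
  if (config$nStructures > 0) {
    structAlleles <- utils::head(grep("^A\\*", names(profiles), value = TRUE),
                                 config$nStructures)
    for (a in structAlleles) {
      sq <- gsub("-", "", profiles[[a]]@alignedSeq)
      pdbLines <- makeHelixStructure(sq)
      structureText[[a]] <- pdbLines
      pf <- tempfile(fileext = ".pdb")
      writeLines(pdbLines, pf)
      prof <- profileFromStructure(pf, referenceSeq = sq, heavyChain = "A",
                                   allele = a)
      unlink(pf)
      profiles[[a]] <- prof
    }
  }
  db <- buildAlleleDb(grid, unname(profiles))

  # eplet registry derived from the polymorphic surface positions: one
  # single-residue eplet per non-consensus configuration actually
  # carried at a surface candidate position, so the registry covers the
  # surface mismatch repertoire densely (that is what ties eplet counts
  # to the surface mismatch count by construction)
  allAlleles <- names(profiles)
  if (length(surfCand) < 1L) stop("grid too short for requested eplets")
  seqMat <- do.call(rbind, lapply(profiles, function(p)
    strsplit(p@alignedSeq, "")[[1]]))
  pats <- character()
  for (p in surfCand)
    for (res in setdiff(unique(seqMat[, p]), consChars[p]))
      pats <- c(pats, sprintf("%d%s", p, res))
  if (length(pats) > config$nEplets)
    pats <- sort(sample(pats, config$nEplets))
  eplets <- data.frame(
    name = sprintf("EP%03d", seq_along(pats)),
    verified = stats::runif(length(pats)) < 0.6,
    pattern = pats, stringsAsFactors = FALSE)
  registry <- loadEpletRegistry(eplets)

  # haplotype table over A, B, C + presenter loci DRB1, DQB1
  drb1 <- sprintf("DRB1*%02d:01", 1:4)
  dqb1 <- sprintf("DQB1*%02d:01", 1:3)
  hap <- NULL
  tries <- 0L
  while (is.null(hap) || nrow(hap) < config$nHaplotypes) {
    add <- data.frame(
      A = sample(grep("^A\\*", allAlleles, value = TRUE),
                 config$nHaplotypes, replace = TRUE),
      B = sample(grep("^B\\*", allAlleles, value = TRUE),
                 config$nHaplotypes, replace = TRUE),
      C = sample(grep("^C\\*", allAlleles, value = TRUE),
                 config$nHaplotypes, replace = TRUE),
      DRB1 = sample(drb1, config$nHaplotypes, replace = TRUE),
      DQB1 = sample(dqb1, config$nHaplotypes, replace = TRUE),
      stringsAsFactors = FALSE)
    hap <- unique(rbind(hap, add))
    tries <- tries + 1L
    if (tries > 20L) stop("could not generate distinct haplotypes")
  }
  hap <- hap[seq_len(config$nHaplotypes), ]
  w <- stats::rgamma(config$nHaplotypes, shape = 1.5)
  hap$frequency <- w / sum(w)
  rownames(hap) <- NULL
  attr(hap, "loci") <- c("A", "B", "C", "DRB1", "DQB1")

  # MAC codes: one alphabetic code per antigen group
  codePool <- apply(expand.grid(LETTERS[2:26], LETTERS[2:26]), 1,
                    function(x) paste0(x[2], x[1]))
  mac <- stats::setNames(unname(macGroups),
                         codePool[seq_along(macGroups)])
  macKeyByGroup <- stats::setNames(names(mac),
                                   names(macGroups))

  structure(list(grid = grid, db = db, registry = registry,
                 haplotypes = hap, mac = mac,
                 macKeyByGroup = macKeyByGroup,
                 serology = do.call(rbind, unname(serRows)),
                 structureText = structureText,
                 predicate = .simPredicate,
                 scoreCache = new.env(parent = emptyenv()),
                 config = config),
            class = "AllelePool")
}

#' @export
print.AllelePool <- function(x, ...) {
  cat(sprintf(
    "AllelePool: %d alleles, %d-position grid, %d eplets, %d haplotypes, %d structures\n",
    length(alleleNames(x$db)), nPositions(x$grid),
    nrow(x$registry@eplets), nrow(x$haplotypes),
    length(x$structureText)))
  invisible(x)
}

# genotype built from haplotype-table rows i and j
.hapGenotype <- function(hap, i, j) {
  loci <- attr(hap, "loci")
  genotype(lapply(stats::setNames(loci, loci),
                  function(L) c(hap[[L]][i], hap[[L]][j])))
}

# cached per-pair locus scores; the cache lives in the pool so repeated
# cohort draws from one pool reuse computed pairs
.pairScores <- function(pool, donorHaps, recipientHaps, caseId) {
  key <- paste(c(donorHaps, recipientHaps), collapse = "_")
  sc <- pool$scoreCache[[key]]
  if (is.null(sc)) {
    donor <- .hapGenotype(pool$haplotypes, donorHaps[1], donorHaps[2])
    recipient <- .hapGenotype(pool$haplotypes, recipientHaps[1],
                              recipientHaps[2])
    sc <- locusScores(donor, recipient, pool$db, registry = pool$registry,
                      threshold = pool$config$threshold,
                      predicate = pool$predicate,
                      coreLength = pool$config$coreLength)
    pool$scoreCache[[key]] <- sc
  }
  sc$case_id <- caseId
  sc
}

# z-scores of true snowflake within locus over selected rows
.snowflakeZ <- function(scores, rows) {
  z <- rep(NA_real_, nrow(scores))
  for (L in unique(scores$locus)) {
    sel <- rows & scores$locus == L
    if (!any(sel)) next
    x <- scores$snowflake[sel]
    s <- stats::sd(x)
    z[sel] <- if (is.na(s) || s == 0) 0 else (x - mean(x)) / s
  }
  z
}

#' Simulate a pregnancy cohort
#'
#' Mothers receive two haplotypes drawn from the pool's frequency table;
#' each child inherits one maternal haplotype plus an independently
#' drawn (paternal) one. Per-locus true Snowflake scores of the child
#' against the mother drive a Bernoulli CSA outcome with
#' logit p = beta0 + betaSnowflake * z(snowflake) (z within locus over
#' the mismatched, non-homozygous records). Matched or homozygous loci
#' never develop CSA. With \code{crossLocusCoupling > 0} the other
#' loci's z-scores enter the logit as well.
#'
#' @param pool an \code{"AllelePool"}.
#' @param config simulation configuration (defaults to the pool's).
#' @param seed RNG seed for this cohort draw (default derived from the
#'   config seed).
#' @return list: \code{cases} (per-case haplotype draws and genotypes),
#'   \code{scores} (per-locus table with \code{outcome}), \code{config}.
#' @export
simulatePregnancy <- function(pool, config = pool$config,
                              seed = config$seed + 1L) {
  set.seed(seed)
  nH <- nrow(pool$haplotypes)
  f <- pool$haplotypes$frequency
  cases <- vector("list", config$nCases)
  scoreRows <- vector("list", config$nCases)
  for (i in seq_len(config$nCases)) {
    mh <- sample.int(nH, 2, replace = TRUE, prob = f)
    transmitted <- mh[sample.int(2, 1)]
    paternal <- sample.int(nH, 1, prob = f)
    ch <- c(transmitted, paternal)
    cases[[i]] <- list(id = sprintf("PC%04d", i), motherHaps = mh,
                       childHaps = ch, transmitted = transmitted,
                       mother = .hapGenotype(pool$haplotypes, mh[1], mh[2]),
                       child = .hapGenotype(pool$haplotypes, ch[1], ch[2]))
    scoreRows[[i]] <- .pairScores(pool, ch, mh, cases[[i]]$id)
  }
  scores <- do.call(rbind, scoreRows)
  eligible <- !scores$matched & !scores$homozygous
  z <- .snowflakeZ(scores, eligible)

  lin <- config$beta0 + config$betaSnowflake * z
  if (config$crossLocusCoupling != 0) {
    zmat <- tapply(ifelse(eligible, z, NA_real_),
                   list(scores$case_id, scores$locus), identity)
    other <- vapply(seq_len(nrow(scores)), function(r) {
      zz <- zmat[scores$case_id[r], setdiff(colnames(zmat), scores$locus[r])]
      sum(zz, na.rm = TRUE)
    }, 0)
    lin <- lin + config$crossLocusCoupling * other
  }
  scores$outcome <- FALSE
  sel <- which(eligible)
  scores$outcome[sel] <- stats::rbinom(length(sel), 1,
                                       stats::plogis(lin[sel])) == 1
  list(cases = cases, scores = scores, config = config)
}

#' Simulate a kidney-transplant cohort
#'
#' Donor and recipient genotypes are drawn independently from the
#' haplotype table. Per-locus DSA times are exponential with log-hazard
#' betaKtc * z(true snowflake); censoring is uniform on (0, maxFollowUp).
#' A degraded typing view replaces Class I alleles by serologic antigens
#' or multiple-allele codes, so the imputation module can be exercised
#' against known truth.
#'
#' @inheritParams simulatePregnancy
#' @return list: \code{cases} (genotypes plus \code{donorTyping} /
#'   \code{recipientTyping} token lists), \code{scores} (per-locus table
#'   with \code{outcome} and \code{follow_up}), \code{config}.
#' @export
simulateKtc <- function(pool, config = pool$config,
                        seed = config$seed + 2L) {
  set.seed(seed)
  nH <- nrow(pool$haplotypes)
  f <- pool$haplotypes$frequency
  degrade <- function(g) {
    out <- list()
    for (L in names(g)) {
      if (L %in% CLASS_I_LOCI) {
        out[[L]] <- vapply(g[[L]], function(al) {
          grp <- sub(":.*$", "", al)
          code <- pool$macKeyByGroup[[grp]]
          useMac <- !is.null(code) && length(pool$mac[[code]]) > 1 &&
            stats::runif(1) < config$macRate
          if (useMac) paste0(grp, ":", code)
          else pool$serology$antigen[pool$serology$allele == al][1]
        }, "")
      } else out[[L]] <- g[[L]]
    }
    out
  }
  cases <- vector("list", config$nCases)
  scoreRows <- vector("list", config$nCases)
  for (i in seq_len(config$nCases)) {
    dh <- sample.int(nH, 2, replace = TRUE, prob = f)
    rh <- sample.int(nH, 2, replace = TRUE, prob = f)
    donor <- .hapGenotype(pool$haplotypes, dh[1], dh[2])
    recipient <- .hapGenotype(pool$haplotypes, rh[1], rh[2])
    cases[[i]] <- list(id = sprintf("KTC%04d", i), donorHaps = dh,
                       recipientHaps = rh, donor = donor,
                       recipient = recipient,
                       donorTyping = degrade(donor),
                       recipientTyping = degrade(recipient))
    scoreRows[[i]] <- .pairScores(pool, dh, rh, cases[[i]]$id)
  }
  scores <- do.call(rbind, scoreRows)
  z <- .snowflakeZ(scores, rep(TRUE, nrow(scores)))
  rate <- config$baselineHazard * exp(config$betaKtc * z)
  tEvent <- stats::rexp(nrow(scores), rate)
  tCens <- stats::runif(nrow(scores), 0.01, config$maxFollowUp)
  scores$outcome <- tEvent <= tCens
  scores$follow_up <- pmin(tEvent, tCens)
  list(cases = cases, scores = scores, config = config)
}

#' Simulate a single-antigen-bead panel and antibody calls
#'
#' Self-HLA beads get baseline log-normal MFI, beads of true antibody
#' targets get strongly elevated MFI. The calling rule is the
#' sample-specific biological cutoff: MFI above 100 and exceeding
#' mean(self beads) + 3 SD(self beads).
#'
#' @param selfAlleles the subject's own alleles (>= 2 must be on the
#'   panel, otherwise the cutoff is undefined).
#' @param targetAlleles alleles with a true antibody response.
#' @param panel all bead alleles.
#' @param config a \code{\link{simulationConfig}} (noise SD).
#' @param seed RNG seed.
#' @param baselineMfi,targetMfi log-normal medians of the two bead
#'   classes.
#' @return data.frame: allele, mfi, self, target, called.
#' @export
simulateSab <- function(selfAlleles, targetAlleles, panel,
                        config = simulationConfig(), seed = config$seed,
                        baselineMfi = 30, targetMfi = 3000) {
  set.seed(seed)
  self <- panel %in% selfAlleles
  if (sum(self) < 2)
    stop("cutoff undefined: fewer than 2 self beads on the panel")
  target <- panel %in% targetAlleles & !self
  mfi <- stats::rlnorm(length(panel),
                       meanlog = log(ifelse(target, targetMfi, baselineMfi)),
                       sdlog = config$mfiNoiseSd)
  cut <- mean(mfi[self]) + 3 * stats::sd(mfi[self])
  data.frame(allele = panel, mfi = mfi, self = self, target = target,
             called = mfi > 100 & mfi > cut,
             stringsAsFactors = FALSE)
}
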