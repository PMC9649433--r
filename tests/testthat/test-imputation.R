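test_that("typing tokens expand to their candidate lists", {
  mac <- readMacTable(data.frame(
    code = "XX", alleles = "A*01:01|A*01:02|B*01:01"))
  ser <- readSerologyMap(data.frame(
    allele = c("A*01:01", "A*01:02", "A*02:01"),
    antigen = c("A1", "A1", "A2")))
  expect_identical(expandMac("A*01:01", mac, ser), "A*01:01")
  # MAC expansion is restricted to the token's antigen group
  expect_setequal(expandMac("A*01:XX", mac, ser),
                  c("A*01:01", "A*01:02"))
  expect_error(expandMac("A*99:ZZ", mac, ser), "unresolved-typing")
  expect_setequal(expandMac("A1", mac, ser), c("A*01:01", "A*01:02"))
  expect_error(expandMac("A9", mac, ser), "unresolved-typing")
})

.freqFixture <- function() {
  hap <- data.frame(A = c("A*01:01", "A*01:02", "A*01:03", "A*02:01"),
                    frequency = c(0.6, 0.3, 0.005, 0.095),
                    stringsAsFactors = FALSE)
  hap <- readHaplotypeTable(hap)
  ser <- readSerologyMap(data.frame(
    allele = c("A*01:01", "A*01:02", "A*01:03", "A*02:01"),
    antigen = c("A1", "A1", "A1", "A2")))
  list(hap = hap, ser = ser)
}

test_that("candidate weights follow frequencies, the 1 percent cut and renormalization", {
  fx <- .freqFixture()
  # heterozygous A1/A2 typing: three matching pairs with raw weights
  # 2*0.6*0.095, 2*0.3*0.095, 2*0.005*0.095 -> normalized 0.663/0.331/0.0055;
  # the third is cut, survivors renormalize to 2/3 and 1/3
  cand <- genotypeCandidates(list(A = c("A1", "A2")), fx$hap,
                             serology = fx$ser)
  expect_length(cand, 2)
  w <- vapply(cand, `[[`, 0, "weight")
  expect_equal(sort(w, decreasing = TRUE), c(2 / 3, 1 / 3))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # unambiguous typing: one candidate with weight 1
  one <- genotypeCandidates(list(A = c("A*01:01", "A*02:01")), fx$hap,
                            serology = fx$ser)
  expect_length(one, 1)
  expect_equal(one[[1]]$weight, 1)
  expect_setequal(one[[1]]$genotype$A, c("A*01:01", "A*02:01"))

  expect_error(genotypeCandidates(list(A = c("A*03:01", "A*03:01")),
                                  fx$hap, serology = fx$ser),
               "imputation-failure")
})

test_that("the frequency cut is strict: exactly 1 percent is dropped", {
  hap <- readHaplotypeTable(data.frame(
    A = c("A*01:01", "A*01:02", "A*02:01"),
    frequency = c(0.495, 0.005, 0.5), stringsAsFactors = FALSE))
  ser <- readSerologyMap(data.frame(
    allele = c("A*01:01", "A*01:02", "A*02:01"),
    antigen = c("A1", "A1", "A2")))
  # normalized weights are exactly 0.99 and 0.01; "exceeds 1%" must
  # discard the 0.01 candidate
  cand <- genotypeCandidates(list(A = c("A1", "A2")), hap, serology = ser)
  expect_length(cand, 1)
  expect_equal(cand[[1]]$weight, 1)
  expect_true("A*01:01" %in% cand[[1]]$genotype$A)
})

test_that("raising the frequency cut never adds candidates", {
  fx <- .freqFixture()
  typ <- list(A = c("A1", "A1"))
  sizes <- vapply(c(0, 0.01, 0.05, 0.2), function(cut)
    length(genotypeCandidates(typ, fx$hap, serology = fx$ser,
                              minNormFreq = cut)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("imputed scores are candidate-weighted expectations", {
  # two donor candidates at weight 1/2 scoring 10 and 2 -> 6
  mkCand <- function(allele, w)
    list(genotype = genotype(A = allele), weight = w)
  donor <- list(mkCand("A*01:01", 0.5), mkCand("A*01:02", 0.5))
  recip <- list(mkCand("A*02:01", 1))
  scorer <- function(d, r) c(score = if (d$A[1] == "A*01:01") 10 else 2)
  expect_equal(imputedScore(donor, recip, scorer), c(score = 6))
  # degenerate: unambiguous candidates reproduce the direct score
  expect_equal(imputedScore(donor[1] |> lapply(\(x) { x$weight <- 1; x }),
                            recip, scorer), c(score = 10))
  badW <- list(mkCand("A*01:01", 0.7), mkCand("A*01:02", 0.7))
  expect_error(imputedScore(badW, recip, scorer), "sum to 1")
})

test_that("imputed scores stay within the candidate score envelope", {
  pool <- .sharedPool()
  ser <- readSerologyMap(pool$serology)
  ktc <- simulateKtc(pool, simulationConfig(seed = 77, nCases = 25))
  scorer <- function(d, r) {
    s <- locusScores(d, r, pool$db, registry = pool$registry)
    stats::setNames(as.numeric(s$snowflake), s$locus)
  }
  checked <- 0L
  for (cs in ktc$cases) {
    dc <- genotypeCandidates(cs$donorTyping, pool$haplotypes, pool$mac, ser)
    rc <- genotypeCandidates(cs$recipientTyping, pool$haplotypes,
                             pool$mac, ser)
    expect_equal(sum(vapply(dc, `[[`, 0, "weight")), 1, tolerance = 1e-9)
    expect_equal(sum(vapply(rc, `[[`, 0, "weight")), 1, tolerance = 1e-9)
    imp <- imputedScore(dc, rc, scorer)
    combos <- do.call(rbind, lapply(dc, function(d)
      do.call(rbind, lapply(rc, function(r)
        scorer(d$genotype, r$genotype)))))
    for (L in colnames(combos)) {
      expect_gte(imp[[L]], min(combos[, L]) - 1e-9)
      expect_lte(imp[[L]], max(combos[, L]) + 1e-9)
    }
    # unique resolution must reproduce the truth bit-identically
    if (length(dc) == 1L && length(rc) == 1L) {
      truth <- scorer(cs$donor, cs$recipient)
      expect_identical(imp, truth)
    }
    checked <- checked + 1L
  }
  expect_equal(checked, 25L)
})
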