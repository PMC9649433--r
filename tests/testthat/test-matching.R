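test_that("snowflake scoring counts uncovered surface residues", {
  db <- toyDb()
  # donor W at surface position 1; recipients carry {A,G} there -> 1
  expect_identical(
    snowflakeScore("A*01:01", c("A*02:01", "A*03:01"), db), 1L)
  # donor consensus: every surface residue covered by some recipient
  expect_identical(
    snowflakeScore("B*01:01", c("A*02:01", "A*03:01"), db), 0L)
  # a donor allele present in the recipient set contributes nothing
  expect_identical(
    snowflakeScore("A*01:01", c("A*01:01", "A*03:01"), db), 0L)
  expect_error(snowflakeScore("A*09:09", "A*01:01", db), "A\\*09:09")
})

test_that("snowflake agrees with the position-scan oracle on random pairs", {
  pool <- .sharedPool()
  hap <- pool$haplotypes
  set.seed(11)
  for (i in 1:40) {
    d <- sample(nrow(hap), 2, replace = TRUE)
    r <- sample(nrow(hap), 2, replace = TRUE)
    recI <- c(hap$A[r], hap$B[r], hap$C[r])
    for (L in c("A", "B", "C")) {
      donor <- hap[[L]][d]
      expect_identical(
        snowflakeScore(donor, recI, pool$db),
        oracleSnowflake(donor, recI, pool$db))
    }
  }
})

test_that("interlocus scores never exceed intralocus scores", {
  pool <- .sharedPool()
  hap <- pool$haplotypes
  set.seed(12)
  for (i in 1:25) {
    d <- sample(nrow(hap), 2, replace = TRUE)
    r <- sample(nrow(hap), 2, replace = TRUE)
    recI <- c(hap$A[r], hap$B[r], hap$C[r])
    for (L in c("A", "B", "C")) {
      donor <- hap[[L]][d]
      inter <- snowflakeScore(donor, recI, pool$db, mode = "interlocus")
      intra <- snowflakeScore(donor, recI, pool$db, mode = "intralocus")
      expect_lte(inter, intra)
      # growing the recipient set can only remove mismatches
      fewer <- snowflakeScore(donor, recI[1:2], pool$db)
      expect_gte(fewer, inter)
    }
  }
})

test_that("eplet registry parsing enforces the table contract", {
  reg <- loadEpletRegistry(data.frame(
    name = "E1", verified = TRUE, pattern = "62G 63E"))
  expect_equal(reg@eplets$pattern[[1]],
               data.frame(position = c(62L, 63L), residue = c("G", "E")))
  expect_true(reg@eplets$verified[1])
  expect_error(loadEpletRegistry(data.frame(
    name = c("E1", "E1"), verified = TRUE, pattern = "1A")), "duplicate")
  expect_error(loadEpletRegistry(data.frame(
    name = "E1", verified = TRUE, pattern = "")), "row 1")
  expect_error(loadEpletRegistry(data.frame(
    name = c("E1", "E2"), verified = TRUE,
    pattern = c("1A", "G63"))), "row 2")
})

test_that("eplet mismatch counting requires full patterns and absence from self", {
  db <- toyDb()
  reg <- loadEpletRegistry(data.frame(
    name = c("E1", "E2", "E3"),
    verified = c(TRUE, FALSE, TRUE),
    pattern = c("1W", "1W 2G", "1W 3A")))
  donor <- "A*01:01"   # WGGGG
  rec <- c("A*02:01", "A*03:01")  # AGGGG, GAGGG
  # E1 and E2 present on donor, absent from recipients; E3 fails at pos 3
  expect_identical(epletMismatchCount(donor, rec, reg, db), 2L)
  expect_identical(epletMismatchCount(donor, rec, reg, db,
                                      verifiedOnly = TRUE), 1L)
  # self vs self is always zero
  expect_identical(epletMismatchCount(donor, donor, reg, db), 0L)
  # off-grid pattern positions are a registry error
  regBad <- loadEpletRegistry(data.frame(
    name = "E9", verified = TRUE, pattern = "99W"))
  expect_error(epletMismatchCount(donor, rec, regBad, db), "off the grid")
})

test_that("surrogate peptide windows cover each mismatch core-length times", {
  g <- alignmentGrid(paste(rep("A", 30), collapse = ""))
  s1 <- paste(rep("A", 30), collapse = "")
  s2 <- paste0(substr(s1, 1, 14), "W", substr(s1, 16, 30))
  db <- buildAlleleDb(g, list(
    alleleProfile("A*01:01", s1, rep(0.5, 30)),
    alleleProfile("A*02:01", s2, rep(0.5, 30))))
  pres <- list(DRB1 = "DRB1*01:01", DQB1 = "DQB1*01:01")
  # interior substitution, accept-all: 9 windows, per presenter locus
  out <- pircheLikeCount("A*02:01", c("A*01:01", "A*01:01"), pres, db)
  expect_equal(out, c(DRB1 = 9L, DQB1 = 9L))
  # identical to a recipient allele: nothing to present
  expect_equal(pircheLikeCount("A*01:01", "A*01:01", pres, db),
               c(DRB1 = 0L, DQB1 = 0L))
  # reject-all predicate silences everything
  expect_equal(pircheLikeCount("A*02:01", "A*01:01", pres, db,
                               predicate = function(p, a) FALSE),
               c(DRB1 = 0L, DQB1 = 0L))
  expect_warning(
    out <- pircheLikeCount("A*02:01", "A*01:01", pres, db, coreLength = 31),
    "exceeds")
  expect_equal(out, c(DRB1 = 0L, DQB1 = 0L))
})

test_that("locus score sets honour the matched-pair zero law", {
  pool <- .sharedPool()
  hap <- pool$haplotypes
  g1 <- snowmatch:::.hapGenotype(hap, 1, 2)
  self <- locusScores(g1, g1, pool$db, registry = pool$registry)
  expect_equal(self$snowflake, c(0L, 0L, 0L))
  expect_equal(self$all_eps, c(0L, 0L, 0L))
  expect_equal(self$abv_eps, c(0L, 0L, 0L))
  expect_true(all(as.matrix(
    self[, grep("^pirche_", names(self))]) == 0))
  expect_true(all(self$matched))

  # a full score table matches per-locus brute-force recomputation
  g2 <- snowmatch:::.hapGenotype(hap, 3, 4)
  sc <- locusScores(g2, g1, pool$db, registry = pool$registry)
  recI <- unlist(g1[c("A", "B", "C")], use.names = FALSE)
  for (k in seq_len(nrow(sc))) {
    L <- sc$locus[k]
    expect_identical(sc$snowflake[k],
                     oracleSnowflake(g2[[L]], recI, pool$db))
  }
  expect_true(all(sc$abv_eps <= sc$all_eps))
})

test_that("batch CSV scoring mirrors single-pair scoring", {
  db <- toyDb()
  pairs <- data.frame(
    case_id = "c1",
    donor_A1 = "A*01:01", donor_A2 = "A*01:01",
    donor_B1 = "B*01:01", donor_B2 = "B*01:01",
    donor_C1 = "A*02:01", donor_C2 = "A*02:01",
    recipient_A1 = "A*02:01", recipient_A2 = "A*03:01",
    recipient_B1 = "B*01:01", recipient_B2 = "B*01:01",
    recipient_C1 = "A*02:01", recipient_C2 = "A*02:01",
    stringsAsFactors = FALSE)
  out <- scorePairs(pairs, db)
  expect_equal(nrow(out), 3)
  expect_equal(out$snowflake[out$locus == "A"], 1L)
  expect_equal(out$snowflake[out$locus == "B"], 0L)
  expect_true(out$matched[out$locus == "C"])
})
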