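# Alignment core: Gotoh scores vs an independent DP, variant extraction,
# spliced mapping, translation.

test_that("identity alignment has full match score and empty diff", {
  set.seed(3)
  for (n in c(1, 5, 40)) {
    x <- randomDna(n)
    aln <- globalAlign(x, x)
    expect_equal(alignmentScore(aln), 2 * n)
    expect_equal(aln@aGapped, x)
    d <- diffAlignment(aln)
    expect_equal(nrow(d$substitutions), 0)
    expect_equal(nrow(d$indels), 0)
  }
})

test_that("alignment scores equal the independent DP oracle on small pairs", {
  set.seed(21)
  for (i in 1:200) {
    a <- randomDna(sample(1:12, 1))
    b <- randomDna(sample(1:12, 1))
    expect_equal(alignmentScore(globalAlign(a, b)), oracleAlignScore(a, b),
                 label = paste(a, b))
  }
  # non-default scoring too
  for (i in 1:30) {
    a <- randomDna(sample(1:10, 1)); b <- randomDna(sample(1:10, 1))
    expect_equal(alignmentScore(globalAlign(a, b, match = 1, mismatch = -1,
                                            gapOpen = -3, gapExtend = -1)),
                 oracleAlignScore(a, b, 1, -1, -3, -1))
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  set.seed(9)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:20) {
    a <- randomDna(sample(20:60, 1))
    b <- randomDna(sample(20:60, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(alignmentScore(globalAlign(a, b)), Biostrings::score(ref))
  }
})

test_that("gapped sequences reconstruct the inputs and tie-breaking is stable", {
  set.seed(13)
  for (i in 1:40) {
    a <- randomDna(sample(1:30, 1)); b <- randomDna(sample(1:30, 1))
    aln <- globalAlign(a, b)
    expect_equal(gsub("-", "", aln@aGapped), a)
    expect_equal(gsub("-", "", aln@bGapped), b)
    aln2 <- globalAlign(a, b)
    expect_identical(aln@aGapped, aln2@aGapped)
    expect_identical(aln@bGapped, aln2@bGapped)
  }
  d <- diffAlignment(globalAlign("ACGT", "ACT"))
  expect_equal(nrow(d$substitutions), 0)
  expect_equal(nrow(d$indels), 1)
  expect_equal(d$indels$length, 1)
  expect_error(globalAlign("", "ACGT"), "non-empty")
})

test_that("female vs male AG CDS shows one clean 15-bp indel; AG2 vs AG3 nine substitutions", {
  ag <- fx("models")$ag
  d <- diffAlignment(globalAlign(cdsSeq(ag$female), cdsSeq(ag$male_ag2)))
  expect_equal(nrow(d$substitutions), 0)
  expect_equal(nrow(d$indels), 1)
  expect_equal(d$indels$length, 15)
  expect_equal(d$indels$inserted_in, "b")
  expect_equal(d$indels$sequence, "CAGGAGGAGGAAGCT")
  d2 <- diffAlignment(globalAlign(cdsSeq(ag$male_ag2), cdsSeq(ag$male_ag3)))
  expect_equal(nrow(d2$substitutions), 9)
  expect_equal(nrow(d2$indels), 0)
})

test_that("spliceMap recovers the generated exon structures and the trivial case", {
  m <- fx("models")
  for (model in list(m$ag$female, m$ag$male_ag2, m$ag$male_ag3, m$ran1$gene)) {
    got <- spliceMap(cdsSeq(model), genomicSeq(model), name = geneName(model))
    expect_equal(exonCount(got), exonCount(model), label = geneName(model))
    expect_equal(as.vector(IRanges::start(exonRanges(got))),
                 as.vector(IRanges::start(exonRanges(model))),
                 label = geneName(model))
    expect_equal(as.character(cdsSeq(got)), as.character(cdsSeq(model)))
  }
  # cds == genomic: one exon spanning everything
  cds <- "ATGAAACCCTAA"
  one <- spliceMap(cds, cds)
  expect_equal(exonCount(one), 1)
  expect_equal(as.vector(IRanges::width(exonRanges(one))), nchar(cds))
  # inconsistent CDS (the assembly-error situation) raises
  g <- as.character(genomicSeq(m$ag$female))
  badCds <- paste0("ATGCTCGAG", substr(as.character(cdsSeq(m$ag$female)), 10, 744))
  expect_error(spliceMap(badCds, g), "chain")
})

test_that("translateCds follows the standard code and rejects bad input", {
  expect_equal(translateCds("ATGTAA"), "M")
  expect_equal(translateCds("ATGGCGTGA"), "MA")
  expect_error(translateCds("ATGAA"), "divisible")
  expect_error(translateCds("ATGTAAGGGTAA"), "internal stop")
  m <- fx("models")
  expect_equal(nchar(translateCds(cdsSeq(m$ag$male_ag2))), 252)
  expect_equal(nchar(translateCds(cdsSeq(m$ran1$gene))), 1004)
})

test_that("diffAlignment of self-alignment is empty for random sequences", {
  set.seed(31)
  for (i in 1:25) {
    x <- randomDna(sample(1:60, 1))
    d <- diffAlignment(globalAlign(x, x))
    expect_equal(nrow(d$substitutions) + nrow(d$indels), 0)
  }
})
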