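# Generator: the synthetic loci must carry exactly the documented structure.

test_that("AG models have the published lengths, structure and marker geometry", {
  ag <- fx("models")$ag
  expect_equal(length(genomicSeq(ag$female)), 5230)
  expect_equal(exonCount(ag$female), 7)
  expect_equal(length(cdsSeq(ag$female)), 744)
  expect_equal(length(cdsSeq(ag$male_ag2)), 759)
  expect_equal(length(cdsSeq(ag$male_ag3)), 759)
  expect_equal(exonCount(ag$male_ag2), 7)

  cdsF <- as.character(cdsSeq(ag$female))
  cds2 <- as.character(cdsSeq(ag$male_ag2))
  # male CDS = female CDS with the 15-bp marker insertion restored
  expect_equal(nchar(cds2) - nchar(cdsF), 15)
  expect_equal(substr(cds2, 614, 628), "CAGGAGGAGGAAGCT")
  expect_equal(paste0(substr(cds2, 1, 613), substr(cds2, 629, 759)), cdsF)
  expect_false(grepl("CAGGAGGAGGAAGCT", cdsF, fixed = TRUE))
  # reverse-marker footprint: last 20 bp of the CDS, ending at the stop codon
  expect_equal(substr(cds2, 740, 759),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("TTACACTAATTGGAGGGCCA"))))
  # insertion lies in exon 7
  ex7 <- exonRanges(ag$male_ag2)[7]
  cds7start <- sum(IRanges::width(exonRanges(ag$male_ag2))[1:6]) + 1L
  expect_true(614 >= cds7start)
})

test_that("AG2 and AG3 differ at 9 bases, exactly 2 of them non-synonymous", {
  ag <- fx("models")$ag
  c2 <- strsplit(as.character(cdsSeq(ag$male_ag2)), "")[[1]]
  c3 <- strsplit(as.character(cdsSeq(ag$male_ag3)), "")[[1]]
  expect_equal(sum(c2 != c3), 9)
  p2 <- strsplit(translateCds(cdsSeq(ag$male_ag2)), "")[[1]]
  p3 <- strsplit(translateCds(cdsSeq(ag$male_ag3)), "")[[1]]
  expect_equal(length(p2), 252)
  expect_equal(sum(p2 != p3), 2)
  expect_equal(nchar(translateCds(cdsSeq(ag$female))), 247)
})

test_that("RAN1 model carries 15 labelled sites, 12 discriminating, with honest effects", {
  ran1 <- fx("models")$ran1
  expect_equal(length(cdsSeq(ran1$gene)), 3015)
  expect_equal(exonCount(ran1$gene), 9)
  sites <- ran1$sites
  expect_equal(nrow(sites), 15)
  expect_equal(sum(sites$validity == "discriminating"), 12)
  expect_setequal(sites$label[sites$validity == "invalid"],
                  paste0("seq000259_", c("9823", "9855", "10377")))
  expect_equal(sum(sites$label == "seq000259_12722"), 2)
  expect_false(anyDuplicated(sites$cds_pos) > 0)
  # the het code is the unique IUPAC code for the two bases at each site
  for (i in seq_len(nrow(sites))) {
    pair <- paste(sort(c(sites$female_base[i], sites$male_alt_base[i])),
                  collapse = "")
    expect_equal(Biostrings::IUPAC_CODE_MAP[[sites$het_code[i]]], pair)
  }
  # effect flags verified by translation of female vs male-substituted CDS
  cdsF <- as.character(cdsSeq(ran1$gene))
  for (i in seq_len(nrow(sites))) {
    mut <- cdsF
    substr(mut, sites$cds_pos[i], sites$cds_pos[i]) <- sites$male_alt_base[i]
    same <- translateCds(mut) == translateCds(cdsF)
    expect_equal(sites$effect[i] == "synonymous", same, label = sites$snp_id[i])
  }
  # 6 discriminating sites inside the marker window, in exon 2
  w <- ran1$marker_window
  expect_equal(w[2] - w[1] + 1L, 608)
  disc <- sites[sites$validity == "discriminating", ]
  expect_equal(sum(disc$genomic_pos >= w[1] & disc$genomic_pos <= w[2]), 6)
  ex2 <- exonRanges(ran1$gene)[2]
  expect_true(w[1] >= IRanges::start(ex2) && w[2] <= IRanges::end(ex2))
  # male consensus is het at every site; male haplotype carries the alt base
  cons <- ran1$male_consensus
  hap <- as.character(genomicSeq(ran1$male_haplotype))
  for (i in seq_len(nrow(sites))) {
    expect_equal(substr(cons, sites$genomic_pos[i], sites$genomic_pos[i]),
                 sites$het_code[i])
    expect_equal(substr(hap, sites$genomic_pos[i], sites$genomic_pos[i]),
                 sites$male_alt_base[i])
  }
})

test_that("the single-site reading of the 12722 duplicate is available", {
  ran1 <- buildRan1Model(seed = 1, site12722 = "missense")
  expect_equal(nrow(ran1$sites), 14)
  expect_equal(sum(ran1$sites$label == "seq000259_12722"), 1)
  expect_equal(ran1$sites$effect[ran1$sites$label == "seq000259_12722"],
               "missense")
})

test_that("no published primer matches any generated sequence at an unintended site", {
  m <- fx("models")
  oligos <- figsex:::figPrimerOligos()
  expected <- list(
    AGf = list(seq = as.character(genomicSeq(m$ag$female)),
               hits = c(`AG-F` = 1, `AG-R` = 1, `AG-Marker-R` = 1)),
    AG2 = list(seq = as.character(genomicSeq(m$ag$male_ag2)),
               hits = c(`AG-F` = 1, `AG-R` = 1, `AG-Marker-F` = 1, `AG-Marker-R` = 1)),
    AG3 = list(seq = as.character(genomicSeq(m$ag$male_ag3)),
               hits = c(`AG-F` = 1, `AG-R` = 1, `AG-Marker-F` = 1, `AG-Marker-R` = 1)),
    RAN1 = list(seq = as.character(genomicSeq(m$ran1$gene)),
                hits = c(`FcRAN1-F` = 1, `FcRAN1-R` = 1, `RAN1-Marker-F` = 1,
                         `RAN1-Marker-R` = 1, `1-SNP-F` = 1, `1-SNP-R` = 1,
                         `2-SNP-F` = 1, `2-SNP-R` = 1, `6SNP-2-F` = 1,
                         `6SNP-2-R` = 1, `qPCR-F` = 1, `qPCR-R` = 1)),
    cons = list(seq = m$ran1$male_consensus,
                hits = c(`FcRAN1-F` = 1, `FcRAN1-R` = 1, `RAN1-Marker-F` = 1,
                         `RAN1-Marker-R` = 1, `1-SNP-F` = 1, `1-SNP-R` = 1,
                         `2-SNP-F` = 1, `2-SNP-R` = 1, `6SNP-2-F` = 1,
                         `6SNP-2-R` = 1, `qPCR-F` = 1, `qPCR-R` = 1)),
    actin = list(seq = m$actin, hits = c(`Actin-F` = 1, `Actin-R` = 1)))
  for (nm in names(expected)) {
    e <- expected[[nm]]
    for (oligo in names(oligos)) {
      want <- if (oligo %in% names(e$hits)) e$hits[[oligo]] else 0L
      got <- nrow(findPrimerSites(e$seq, oligos[[oligo]]))
      expect_equal(got, want, label = paste(nm, oligo))
    }
  }
})

test_that("generation is deterministic and seed-sensitive", {
  a <- buildAgModels(seed = 7)
  b <- buildAgModels(seed = 7)
  expect_identical(as.character(genomicSeq(a$female)),
                   as.character(genomicSeq(b$female)))
  expect_identical(as.character(genomicSeq(a$male_ag3)),
                   as.character(genomicSeq(b$male_ag3)))
  c <- buildAgModels(seed = 8)
  expect_false(identical(as.character(genomicSeq(a$female)),
                         as.character(genomicSeq(c$female))))
})

test_that("cultivar panel has the documented composition and planted violations", {
  panel <- fx("cultivar")
  info <- panelInfo(panel)
  expect_equal(nrow(info), 51)
  expect_equal(sum(info$true_sex == "male"), 27)
  expect_equal(sum(info$true_sex == "female"), 24)
  sites <- fx("models")$ran1$sites
  seqs <- vapply(sampleIds(panel), function(id) sampleSeqs(panel, id)[["RAN1"]], "")
  for (i in which(sites$validity == "invalid")) {
    obs <- substr(seqs, sites$genomic_pos[i], sites$genomic_pos[i])
    het <- obs == sites$het_code[i]
    expect_true(any(!het[info$true_sex == "male"]), label = sites$label[i])
    expect_true(any(het[info$true_sex == "female"]), label = sites$label[i])
  }
  # females carry no male-specific AG sequence at any locus
  for (id in info$sample_id[info$true_sex == "female"]) {
    s <- sampleSeqs(panel, id)
    expect_false(any(grepl("CAGGAGGAGGAAGCT", s, fixed = TRUE)))
    expect_false(any(c("AG2", "AG3") %in% names(s)))
  }
})

test_that("F1 builder honours fixed counts, errors on bad counts, and is fair otherwise", {
  expect_equal(nrow(panelInfo(fx("pop1"))), 242)
  expect_equal(sum(panelInfo(fx("pop1"))$true_sex == "male"), 132)
  expect_equal(nrow(panelInfo(fx("pop2"))), 85)
  expect_equal(sum(panelInfo(fx("pop2"))$true_sex == "female"), 49)
  expect_error(buildF1Population(10, seed = 1, fixedCounts = c(4, 5),
                                 models = fx("models")),
               "sum to n")
  # free segregation: male fraction inside the binomial 99% interval of 0.5
  pop <- buildF1Population(200, seed = 7, models = fx("models"))
  nm <- sum(panelInfo(pop)$true_sex == "male")
  expect_true(nm >= qbinom(0.005, 200, 0.5) && nm <= qbinom(0.995, 200, 0.5))
})

test_that("fixture round trip is exact and deterministic", {
  m <- fx("models")
  panel <- fx("cultivar")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writePanelFixtures(panel, d1, models = m, sites = m$ran1$sites, seed = 1)
  writePanelFixtures(panel, d2, models = m, sites = m$ran1$sites, seed = 1)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  fxr <- readPanelFixtures(d1)
  expect_identical(panelInfo(fxr$panel), panelInfo(panel))
  expect_identical(fxr$panel@seqs, panel@seqs)
  expect_equal(nrow(fxr$sites), 15)
  expect_equal(exonCount(fxr$models[["FcAG"]]), 7)
  expect_identical(as.character(genomicSeq(fxr$models[["FcRAN1"]])),
                   as.character(genomicSeq(m$ran1$gene)))
})
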