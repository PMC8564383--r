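# Discovery stage: diagnostic indels, marker design, the SNP screen.

test_that("the 15-bp insertion is rediscovered as the unique diagnostic AG indel", {
  ind <- findDiagnosticIndels(fx("cultivar"), "AG_cds")
  expect_equal(nrow(ind), 1)
  expect_equal(ind$length, 15)
  expect_equal(ind$sequence, "CAGGAGGAGGAAGCT")
  expect_equal(ind$present_in, "male")
  expect_equal(ind$position, 614)
})

test_that("identical loci and shuffled labels both yield no diagnostic indel", {
  m <- fx("models")
  same <- as.character(cdsSeq(m$ag$female))
  p <- miniPanel(c(AG_cds = same), c(AG_cds = same))
  expect_equal(nrow(findDiagnosticIndels(p, "AG_cds")), 0)
  # label shuffles destroy the perfect partition (subset panel for speed)
  panel <- fx("cultivar")
  info <- panelInfo(panel)
  ids <- c(info$sample_id[info$true_sex == "male"][1:4],
           info$sample_id[info$true_sex == "female"][1:4])
  sub <- new("SamplePanel", info = info[match(ids, info$sample_id), ],
             seqs = panel@seqs[ids])
  set.seed(17)
  for (i in 1:20) {
    shuf <- sub
    shuf@info$true_sex <- sample(shuf@info$true_sex)
    if (identical(shuf@info$true_sex, sub@info$true_sex)) next
    expect_equal(nrow(findDiagnosticIndels(shuf, "AG_cds")), 0)
  }
  expect_error(findDiagnosticIndels(miniPanel(c(X = "ATG"), c(AG_cds = "ATG")),
                                    "AG_cds"),
               "missing")
})

test_that("a planted indel of another length is found and measured correctly", {
  m <- fx("models")
  fem <- as.character(cdsSeq(m$ag$female))
  # plant a 7-bp in-frame-agnostic insertion mid-CDS in the 'male' allele
  ins7 <- "GATCCGA"
  male <- paste0(substr(fem, 1, 300), ins7, substr(fem, 301, nchar(fem)))
  p <- miniPanel(c(AG_cds = male), c(AG_cds = fem))
  ind <- findDiagnosticIndels(p, "AG_cds")
  expect_equal(nrow(ind), 1)
  expect_equal(ind$length, 7)
  expect_equal(ind$sequence, ins7)
})

test_that("designPresenceMarker reproduces the published AG-Marker and its geometry", {
  m <- fx("models")
  ind <- findDiagnosticIndels(fx("cultivar"), "AG_cds")[1, ]
  pair <- designPresenceMarker(ind, m$ag$male_ag2)
  expect_equal(pair@fwd, "CAGGAGGAGGAAGCT")
  expect_equal(pair@rev, "TTACACTAATTGGAGGGCCA")  # the published AG-Marker-R
  expect_equal(pair@expectedLength, 146L)
  # expected length equals what amplify() returns on the same template
  expect_equal(amplify(genomicSeq(m$ag$male_ag2), pair)$length, 146)
  expect_equal(amplify(cdsSeq(m$ag$male_ag2), pair)$length, 146)
  # absent indel on the female template is a precondition error
  expect_error(designPresenceMarker(ind, m$ag$female), "absent")
})

test_that("designPresenceMarker handles a planted indel by coordinate arithmetic", {
  # toy model: CDS of 99 bp with a known 7-bp 'insertion' at position 31
  set.seed(23)
  repeat {
    cds <- paste0("ATG", randomDna(87), "CTTGAGTAA")
    ok <- tryCatch({ translateCds(cds); TRUE }, error = function(e) FALSE)
    if (ok) break
  }
  gm <- new("GeneModel", name = "toy", genomic = Biostrings::DNAString(cds),
            exons = IRanges::IRanges(1, nchar(cds)), strand = "+")
  ind <- list(sequence = substr(cds, 31, 37), position = 31)
  pair <- tryCatch(designPresenceMarker(ind, gm), error = function(e) e)
  if (is(pair, "PrimerPair")) {
    expect_equal(pair@expectedLength, nchar(cds) - 31L + 1L)
  } else {
    # random 7-mer happened to recur; the uniqueness guard must say so
    expect_match(conditionMessage(pair), "sites|absent")
  }
})

test_that("the SNP screen gives the published verdicts with counterexamples", {
  m <- fx("models")
  v <- screenSnpSites(fx("cultivar"), m$ran1$sites)
  expect_equal(nrow(v), 15)
  expect_equal(sum(v$verdict == "discriminating"), 12)
  expect_setequal(v$label[v$verdict == "invalid"],
                  paste0("seq000259_", c("9823", "9855", "10377")))
  expect_true(all(v$n_counterexamples[v$verdict == "discriminating"] == 0))
  expect_true(all(v$n_counterexamples[v$verdict == "invalid"] >= 2))
  # counterexamples name real samples with the violating state
  truth <- panelInfo(fx("cultivar"))
  for (i in which(v$verdict == "invalid")) {
    ce <- v$counterexamples[[i]]
    sex <- truth$true_sex[match(ce$sample_id, truth$sample_id)]
    expect_true(all((sex == "male") == grepl("^hom", ce$observed_state)))
  }
})

test_that("screen verdicts are invariant under sample order permutation", {
  m <- fx("models")
  panel <- fx("cultivar")
  set.seed(41)
  ord <- sample(length(panel))
  shuffled <- new("SamplePanel", info = panelInfo(panel)[ord, ],
                  seqs = panel@seqs[ord])
  v1 <- screenSnpSites(panel, m$ran1$sites)
  v2 <- screenSnpSites(shuffled, m$ran1$sites)
  expect_equal(v1$verdict, v2$verdict)
  expect_equal(v1$n_counterexamples, v2$n_counterexamples)
})

test_that("single-sex panels warn about vacuous universality", {
  m <- fx("models")
  # an unmodified male is heterozygous at every catalogued site
  male <- figsex:::maleSampleSeqs(m)
  p <- new("SamplePanel",
           info = data.frame(sample_id = "m1", population = "x", true_sex = "male"),
           seqs = list(m1 = male))
  expect_warning(v <- screenSnpSites(p, m$ran1$sites), "vacuously")
  expect_true(all(v$verdict == "discriminating"))
  # one homozygous male makes a site invalid with that counterexample
  hom <- male
  s1 <- m$ran1$sites[1, ]
  hom["RAN1"] <- figsex:::setSiteBase(hom[["RAN1"]], s1$genomic_pos, s1$female_base)
  p2 <- new("SamplePanel",
            info = data.frame(sample_id = "m2", population = "x", true_sex = "male"),
            seqs = list(m2 = hom))
  expect_warning(v2 <- screenSnpSites(p2, m$ran1$sites), "vacuously")
  expect_equal(v2$verdict[1], "invalid")
  expect_equal(v2$counterexamples[[1]]$sample_id, "m2")
})

test_that("sitesInAmplicon counts covered sites for every published amplicon", {
  m <- fx("models")
  pp <- fx("primers")
  ran1 <- genomicSeq(m$ran1$gene)
  sites <- m$ran1$sites
  counts <- c(`RAN1-Marker` = 6, `1-SNP` = 1, `2-SNP` = 2, `6SNP-2` = 6,
              qPCR = 0)
  for (nm in names(counts)) {
    amp <- amplify(ran1, pp[[nm]])[1, ]
    expect_equal(sitesInAmplicon(sites, amp)$count, unname(counts[nm]),
                 label = nm)
  }
  marker <- amplify(ran1, pp[["RAN1-Marker"]])[1, ]
  expect_equal(sitesInAmplicon(sites, marker, filter = "discriminating")$count, 6)
  expect_equal(sitesInAmplicon(sites, list(start = 5, end = 4))$count, 0)
})
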