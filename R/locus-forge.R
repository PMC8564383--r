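# Synthetic-data stage: seeded construction of the AG and RAN1 loci, the
# amplification-control locus, and the cultivar / F1 panels, carrying every
# sequence feature the discovery and calling stages must rediscover:
#
#  * female AG: 5230 bp genomic, 7 CDS-exons, 744-bp CDS;
#  * male-specific AG2/AG3: 759-bp CDS = female CDS plus the 15-bp
#    AG-Marker-F insertion in exon 7, AG-Marker amplicon of exactly 146 bp
#    ending at the CDS 3' end; AG2 and AG3 differ at exactly 9 CDS positions,
#    2 of them non-synonymous;
#  * RAN1: 3015-bp CDS, 9 CDS-exons, 15 labelled SNP sites (12
#    sex-discriminating, 3 invalid), a 608-bp exon-2 RAN1-Marker amplicon
#    covering 6 discriminating sites, and the 1-SNP/2-SNP/6SNP-2/qPCR
#    amplicons of 371/444/766/156 bp;
#  * Actin control with a 250-bp product.
#
# Every fixed motif (primer footprints, SNP codons, splice dinucleotides) is
# embedded at hand-chosen in-frame positions; the random background is
# resampled until the models translate cleanly, splice-map back to their own
# exon structure, and no published assay primer matches anywhere unintended.

DNA_BASES <- c("A", "C", "G", "T")

AG_MARKER_INSERT <- "CAGGAGGAGGAAGCT"          # AG-Marker-F, the 15-bp insertion
AG_INS_AFTER <- 613L                           # inserted after this female CDS position

# concrete expansions of the degenerate full-CDS AG primers, used as the
# embedded CDS ends (K->G, W->A; Y->T, S->G on the reverse footprint)
AG_CDS_START <- "ATGGCGTACCAAAACAAGGAGAAGA"    # AG-F expansion, CDS 1..25
AG_CDS_END   <- "TTCCATGGCCCTCCAATTAGTGTAA"    # revcomp(AG-R) expansion, last 25 bp

AG_EXON_LENS_F  <- c(181L, 67L, 62L, 100L, 42L, 45L, 247L)   # sum 744
AG_INTRON_LENS  <- c(900L, 800L, 748L, 700L, 678L, 660L)     # sum 4486 -> gene 5230

RAN1_EXON_LENS   <- c(150L, 700L, 100L, 420L, 90L, 500L, 180L, 800L, 75L)  # sum 3015
RAN1_INTRON_LENS <- c(120L, 95L, 110L, 80L, 100L, 90L, 130L, 85L)

# fixed primer footprints in the RAN1 CDS (1-based start, plus-strand text)
RAN1_CDS_MOTIFS <- list(
  list(start = 1L,    seq = "ATGGCGGCGAGCGTCCGACA"),        # FcRAN1-F
  list(start = 181L,  seq = "ATATCAAGAATGCAATCGAGGA"),      # RAN1-Marker-F
  list(start = 767L,  seq = "CATCTCTAGTCTATTTCTCAGC"),      # revcomp(RAN1-Marker-R)
  list(start = 975L,  seq = "TCCTGTCTTTCTCATACGAGTAGTT"),   # 1-SNP-F
  list(start = 1326L, seq = "GGGGAAAACATCTGACGCCA"),        # revcomp(1-SNP-R)
  list(start = 1470L, seq = "TCACGATGTAAGGGCAGAGG"),        # 2-SNP-F
  list(start = 1893L, seq = "CAGAAAACCAAGGCTGACCAC"),       # revcomp(2-SNP-R)
  list(start = 1966L, seq = "CCACTGGCAAAGGCAATAGT"),        # qPCR-F
  list(start = 2102L, seq = "TTCCCGGCAGAGGAGTTCAA"),        # revcomp(qPCR-R)
  list(start = 2150L, seq = "CTGGAGCTCTTCGTGCTTAC"),        # 6SNP-2-F
  list(start = 2895L, seq = "CGGCAGAGGAGTTCAATGCTT"),       # revcomp(6SNP-2-R)
  list(start = 2991L, seq = "TATACTAGAAATAACTGTAGAATAG"))   # revcomp(FcRAN1-R)

RAN1_MARKER_CDS_WINDOW <- c(181L, 788L)   # the 608-bp RAN1-Marker amplicon

# SNP catalogue: scaffold labels are identifiers taken from the published
# site names; CDS placement is generator-chosen. seq000259_12722 is listed
# with both a missense and a synonymous change and the SNP1..SNP15 numbering
# only closes if it occupies two slots, so two sites carry that label.
ran1SiteSpec <- function(site12722 = c("both", "missense")) {
  site12722 <- match.arg(site12722)
  spec <- data.frame(
    snp_id  = c("SNP15", "SNP14", "SNP11", "SNP10", "SNP8", "SNP7",
                "SNP6", "SNP5", "SNP4",
                "SNP13", "SNP12", "SNP9", "SNP3", "SNP2", "SNP1"),
    label   = paste0("seq000259_",
                c("8998", "9166", "9876", "9900", "10431", "11760",
                  "12314", "12388", "12646",
                  "9823", "9855", "10377", "12722", "12722", "12743")),
    codon   = c(70L, 110L, 140L, 170L, 200L, 245L,
                387L, 520L, 590L,
                730L, 770L, 820L, 870L, 910L, 950L),
    offset  = c(3L, 3L, 2L, 2L, 3L, 3L,
                3L, 3L, 3L,
                3L, 1L, 3L, 3L, 2L, 2L),
    female_codon = c("GCT", "GGT", "GAG", "CGG", "CCT", "ACT",
                     "GAG", "GTT", "CTT",
                     "TCT", "GAC", "GGT", "GCT", "CTT", "TTC"),
    male_alt_base = c("C", "A", "T", "C", "G", "C",
                      "T", "A", "G",
                      "C", "A", "C", "A", "A", "C"),
    effect  = c("synonymous", "synonymous", "missense", "missense",
                "synonymous", "synonymous", "missense", "synonymous",
                "synonymous", "synonymous", "missense", "synonymous",
                "synonymous", "missense", "missense"),
    validity = "discriminating")
  spec$validity[spec$label %in% paste0("seq000259_", c("9823", "9855", "10377"))] <-
    "invalid"
  if (site12722 == "missense")           # single-site reading of the duplicate
    spec <- spec[spec$snp_id != "SNP3", , drop = FALSE]
  spec$cds_pos <- 3L * spec$codon - 3L + spec$offset
  spec$female_base <- substr(spec$female_codon, spec$offset, spec$offset)
  spec$het_code <- mapply(iupacHetCode, spec$female_base, spec$male_alt_base,
                          USE.NAMES = FALSE)
  rownames(spec) <- NULL
  spec
}

iupacHetCode <- function(b1, b2) {
  stopifnot(b1 %in% DNA_BASES, b2 %in% DNA_BASES, b1 != b2)
  key <- paste(sort(c(b1, b2)), collapse = "")
  codes <- Biostrings::IUPAC_CODE_MAP
  names(codes)[match(key, codes)]
}

randBases <- function(n) sample(DNA_BASES, n, replace = TRUE)

withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# resample free bases of internal stop codons until the frame is clean
repairStops <- function(cdsVec, freeMask) {
  n <- length(cdsVec)
  repeat {
    codStart <- seq(1L, n - 5L, 3L)           # internal codons only
    cods <- paste0(cdsVec[codStart], cdsVec[codStart + 1L], cdsVec[codStart + 2L])
    bad <- codStart[cods %in% STOP_CODONS]
    if (!length(bad)) return(cdsVec)
    for (s in bad) {
      idx <- s:(s + 2L)
      free <- idx[freeMask[idx]]
      if (!length(free))
        stop("fixed motifs force an internal stop codon; design error")
      repeat {
        cdsVec[free] <- randBases(length(free))
        if (!paste(cdsVec[idx], collapse = "") %in% STOP_CODONS) break
      }
    }
  }
}

makeIntron <- function(len) {
  stopifnot(len >= 60L)
  c("G", "T", randBases(len - 4L), "A", "G")
}

assembleGene <- function(name, cdsVec, exonLens, intronList) {
  stopifnot(sum(exonLens) == length(cdsVec), length(intronList) == length(exonLens) - 1L)
  pieces <- character(0)
  exStart <- integer(length(exonLens))
  gpos <- 0L
  cdsOff <- cumsum(c(0L, exonLens[-length(exonLens)]))
  for (i in seq_along(exonLens)) {
    exStart[i] <- gpos + 1L
    pieces <- c(pieces, paste(cdsVec[(cdsOff[i] + 1L):(cdsOff[i] + exonLens[i])],
                              collapse = ""))
    gpos <- gpos + exonLens[i]
    if (i < length(exonLens)) {
      pieces <- c(pieces, paste(intronList[[i]], collapse = ""))
      gpos <- gpos + length(intronList[[i]])
    }
  }
  new("GeneModel", name = name, genomic = DNAString(paste(pieces, collapse = "")),
      exons = IRanges(exStart, exStart + exonLens - 1L), strand = "+")
}

# map CDS positions to genomic positions for a model built by assembleGene
cdsToGenomic <- function(model, cdsPos) {
  ex <- exonRanges(model)
  cdsEnd <- cumsum(width(ex))
  cdsStart <- cdsEnd - width(ex) + 1L
  vapply(cdsPos, function(p) {
    i <- which(p >= cdsStart & p <= cdsEnd)[1]
    start(ex)[i] + (p - cdsStart[i])
  }, integer(1))
}

# count hits of every published assay oligo against a sequence, compare to whitelist
primerHitsOk <- function(seqChr, expected) {
  oligos <- figPrimerOligos()
  for (nm in names(oligos)) {
    want <- if (nm %in% names(expected)) expected[[nm]] else 0L
    got <- nrow(findPrimerSites(seqChr, oligos[[nm]]))
    if (got != want) return(FALSE)
  }
  TRUE
}

agExpectedHits <- function(male) {
  hits <- list(`AG-F` = 1L, `AG-R` = 1L, `AG-Marker-R` = 1L)
  if (male) hits$`AG-Marker-F` <- 1L
  hits
}

ran1ExpectedHits <- function() {
  list(`FcRAN1-F` = 1L, `FcRAN1-R` = 1L, `RAN1-Marker-F` = 1L,
       `RAN1-Marker-R` = 1L, `1-SNP-F` = 1L, `1-SNP-R` = 1L,
       `2-SNP-F` = 1L, `2-SNP-R` = 1L, `6SNP-2-F` = 1L, `6SNP-2-R` = 1L,
       `qPCR-F` = 1L, `qPCR-R` = 1L)
}

spliceIdentity <- function(model) {
  got <- tryCatch(spliceMap(cdsSeq(model), genomicSeq(model), name = geneName(model)),
                  error = function(e) NULL)
  !is.null(got) && identical(as.vector(start(exonRanges(got))),
                             as.vector(start(exonRanges(model)))) &&
    identical(as.vector(end(exonRanges(got))), as.vector(end(exonRanges(model))))
}

#' Build the synthetic AGAMOUS gene models
#'
#' Constructs the female AG gene (5230 bp genomic, 7 CDS-exons, 744-bp CDS)
#' and the two male-specific alleles AG2/AG3 (759-bp CDS): identical to the
#' female CDS except for the 15-bp AG-Marker-F insertion in exon 7, placed so
#' that the AG-Marker amplicon (insertion start through the reverse-primer
#' footprint, which ends at the stop codon) is exactly 146 bp. AG2 and AG3
#' differ at exactly 9 CDS positions, exactly 2 of which change the protein.
#'
#' The random background is regenerated (never silently accepted) until all
#' three models translate without internal stops, [spliceMap()] recovers
#' their exon structure exactly, and no published assay primer matches anywhere
#' unintended on either strand.
#'
#' @param seed integer seed; identical seeds give byte-identical models.
#' @param maxAttempts background regenerations allowed before giving up.
#' @return list with [GeneModel-class] elements `female`, `male_ag2`,
#'   `male_ag3`.
#' @examples
#' ag <- buildAgModels(seed = 1)
#' length(cdsSeq(ag$female))    # 744
#' length(cdsSeq(ag$male_ag2))  # 759
#' @export
buildAgModels <- function(seed = 1L, maxAttempts = 50L) {
  withLocalSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      cdsF <- randBases(744L)
      fixed <- rep(FALSE, 744L)
      put <- function(vec, mask, start, s) {
        idx <- start:(start + nchar(s) - 1L)
        vec[idx] <- strsplit(s, "")[[1]]
        mask[idx] <- TRUE
        list(vec, mask)
      }
      r <- put(cdsF, fixed, 1L, AG_CDS_START); cdsF <- r[[1]]; fixed <- r[[2]]
      r <- put(cdsF, fixed, 720L, AG_CDS_END); cdsF <- r[[1]]; fixed <- r[[2]]
      # insertion junction: forbid indel sliding and junction stop codons
      cdsF[613L] <- sample(c("A", "C", "G"), 1L)
      cdsF[614L] <- "T"
      fixed[c(613L, 614L)] <- TRUE
      # AG2/AG3 difference positions: 7 synonymous + 2 missense codons
      diffCodons <- sort(sample(30:195, 9L))
      synCodons <- diffCodons[1:7]
      misCodons <- diffCodons[8:9]
      fourfold <- c("GCT", "GGT", "CCT", "ACT", "GTT", "CTT", "TCT", "CGT")
      synFrom <- sample(fourfold, 7L, replace = TRUE)
      ag3Sub <- data.frame(pos = integer(), base = character())
      for (k in seq_along(synCodons)) {
        cod <- synCodons[k]
        idx <- (3L * cod - 2L):(3L * cod)
        cdsF[idx] <- strsplit(synFrom[k], "")[[1]]
        fixed[idx] <- TRUE
        ag3Sub <- rbind(ag3Sub, data.frame(pos = 3L * cod, base = "C"))
      }
      misFrom <- c("GAG", "CGG"); misTo <- c("T", "C")  # -> GTG (E>V), CCG (R>P)
      for (k in 1:2) {
        cod <- misCodons[k]
        idx <- (3L * cod - 2L):(3L * cod)
        cdsF[idx] <- strsplit(misFrom[k], "")[[1]]
        fixed[idx] <- TRUE
        ag3Sub <- rbind(ag3Sub, data.frame(pos = 3L * cod - 1L, base = misTo[k]))
      }
      cdsF <- repairStops(cdsF, !fixed)

      ins <- strsplit(AG_MARKER_INSERT, "")[[1]]
      cdsM2 <- c(cdsF[1:AG_INS_AFTER], ins, cdsF[(AG_INS_AFTER + 1L):744L])
      cdsM3 <- cdsM2
      cdsM3[ag3Sub$pos] <- ag3Sub$base

      introns <- lapply(AG_INTRON_LENS, makeIntron)
      exonLensM <- AG_EXON_LENS_F
      exonLensM[7] <- exonLensM[7] + 15L
      female <- assembleGene("FcAG", cdsF, AG_EXON_LENS_F, introns)
      maleAg2 <- assembleGene("FcAG2-Gall_Stamen", cdsM2, exonLensM, introns)
      maleAg3 <- assembleGene("FcAG3-Gall_Stamen", cdsM3, exonLensM, introns)

      ok <- tryCatch({
        translateCds(paste(cdsF, collapse = ""))
        translateCds(paste(cdsM2, collapse = ""))
        translateCds(paste(cdsM3, collapse = ""))
        TRUE
      }, error = function(e) FALSE)
      ok <- ok &&
        primerHitsOk(as.character(genomicSeq(female)), agExpectedHits(FALSE)) &&
        primerHitsOk(as.character(genomicSeq(maleAg2)), agExpectedHits(TRUE)) &&
        primerHitsOk(as.character(genomicSeq(maleAg3)), agExpectedHits(TRUE)) &&
        spliceIdentity(female) && spliceIdentity(maleAg2) && spliceIdentity(maleAg3)
      if (ok)
        return(list(female = female, male_ag2 = maleAg2, male_ag3 = maleAg3))
    }
    stop("could not satisfy AG model constraints after ", maxAttempts, " attempts")
  })
}

#' Build the synthetic RAN1 gene model and SNP catalogue
#'
#' Constructs the RAN1 locus (3015-bp CDS, 9 CDS-exons) with the 15 labelled
#' SNP sites embedded at distinct in-frame CDS positions, the 608-bp
#' RAN1-Marker amplicon inside exon 2 covering 6 discriminating sites, and
#' the 1-SNP / 2-SNP / 6SNP-2 / qPCR amplicons (371 / 444 / 766 / 156 bp)
#' covering 1 / 2 / 6 / 0 sites. The male haplotype carries the alternative
#' base at every site; the male consensus carries the IUPAC heterozygote code.
#'
#' @param seed integer seed.
#' @param site12722 how to treat the published site seq000259_12722, which is
#'   reported with both a missense and a synonymous change: `"both"`
#'   (default) models two distinct sites under that label, which is the only
#'   reading compatible with 15 sites / 12 discriminating; `"missense"`
#'   models a single missense site (14 sites in total).
#' @param maxAttempts background regenerations allowed before giving up.
#' @return list with elements `gene` (female [GeneModel-class]),
#'   `male_haplotype` (male-haplotype `GeneModel`), `male_consensus`
#'   (character; genomic consensus of a heterozygous male with IUPAC codes at
#'   every site), `sites` (data.frame: `snp_id`, `label`, `codon`, `cds_pos`,
#'   `genomic_pos`, `female_base`, `male_alt_base`, `het_code`, `validity`,
#'   `effect`) and `marker_window` (genomic start/end of the RAN1-Marker
#'   amplicon).
#' @examples
#' ran1 <- buildRan1Model(seed = 1)
#' length(cdsSeq(ran1$gene))  # 3015
#' table(ran1$sites$validity)
#' @export
buildRan1Model <- function(seed = 1L, site12722 = c("both", "missense"),
                           maxAttempts = 50L) {
  site12722 <- match.arg(site12722)
  sites <- ran1SiteSpec(site12722)
  withLocalSeed(seed + 1L, {
    for (attempt in seq_len(maxAttempts)) {
      cdsF <- randBases(3015L)
      fixed <- rep(FALSE, 3015L)
      for (mt in RAN1_CDS_MOTIFS) {
        idx <- mt$start:(mt$start + nchar(mt$seq) - 1L)
        cdsF[idx] <- strsplit(mt$seq, "")[[1]]
        fixed[idx] <- TRUE
      }
      for (i in seq_len(nrow(sites))) {
        idx <- (3L * sites$codon[i] - 2L):(3L * sites$codon[i])
        cdsF[idx] <- strsplit(sites$female_codon[i], "")[[1]]
        fixed[idx] <- TRUE
      }
      cdsF <- repairStops(cdsF, !fixed)
      cdsM <- cdsF
      cdsM[sites$cds_pos] <- sites$male_alt_base

      introns <- lapply(RAN1_INTRON_LENS, makeIntron)
      gene <- assembleGene("FcRAN1", cdsF, RAN1_EXON_LENS, introns)
      maleHap <- assembleGene("FcRAN1-male", cdsM, RAN1_EXON_LENS, introns)
      gpos <- cdsToGenomic(gene, sites$cds_pos)
      consensus <- strsplit(as.character(genomicSeq(gene)), "")[[1]]
      consensus[gpos] <- sites$het_code
      consensus <- paste(consensus, collapse = "")

      ok <- tryCatch({
        translateCds(paste(cdsF, collapse = ""))
        translateCds(paste(cdsM, collapse = ""))
        TRUE
      }, error = function(e) FALSE)
      ok <- ok &&
        primerHitsOk(as.character(genomicSeq(gene)), ran1ExpectedHits()) &&
        primerHitsOk(as.character(genomicSeq(maleHap)), ran1ExpectedHits()) &&
        primerHitsOk(consensus, ran1ExpectedHits()) &&
        spliceIdentity(gene) && spliceIdentity(maleHap)
      if (ok) {
        sites$genomic_pos <- gpos
        sites <- sites[, c("snp_id", "label", "codon", "cds_pos", "genomic_pos",
                           "female_base", "male_alt_base", "het_code",
                           "validity", "effect")]
        window <- cdsToGenomic(gene, RAN1_MARKER_CDS_WINDOW)
        return(list(gene = gene, male_haplotype = maleHap,
                    male_consensus = consensus, sites = sites,
                    marker_window = window))
      }
    }
    stop("could not satisfy RAN1 model constraints after ", maxAttempts, " attempts")
  })
}

buildActinLocus <- function(seed = 1L, maxAttempts = 50L) {
  pf <- "GAACCACCAGACAGGACGATG"                 # Actin-F
  prc <- revComp("CTACCACTGCTGAACGGGAAA")       # revcomp(Actin-R)
  withLocalSeed(seed + 2L, {
    for (attempt in seq_len(maxAttempts)) {
      s <- c(randBases(50L), strsplit(pf, "")[[1]], randBases(208L),
             strsplit(prc, "")[[1]], randBases(50L))
      s <- paste(s, collapse = "")
      if (primerHitsOk(s, list(`Actin-F` = 1L, `Actin-R` = 1L))) return(s)
    }
    stop("could not satisfy Actin locus constraints")
  })
}

#' Build all synthetic loci in one call
#'
#' @param seed integer seed.
#' @param site12722 passed to [buildRan1Model()].
#' @return list with elements `ag` ([buildAgModels()] output), `ran1`
#'   ([buildRan1Model()] output) and `actin` (control locus sequence).
#' @export
buildLocusModels <- function(seed = 1L, site12722 = "both") {
  list(ag = buildAgModels(seed), ran1 = buildRan1Model(seed, site12722),
       actin = buildActinLocus(seed))
}

femaleSampleSeqs <- function(models) {
  c(AG = as.character(genomicSeq(models$ag$female)),
    AG_cds = as.character(cdsSeq(models$ag$female)),
    RAN1 = as.character(genomicSeq(models$ran1$gene)),
    Actin = models$actin)
}

maleSampleSeqs <- function(models) {
  c(AG = as.character(genomicSeq(models$ag$female)),   # conserved allele
    AG2 = as.character(genomicSeq(models$ag$male_ag2)),
    AG3 = as.character(genomicSeq(models$ag$male_ag3)),
    AG_cds = as.character(cdsSeq(models$ag$male_ag2)),
    RAN1 = models$ran1$male_consensus,
    Actin = models$actin)
}

setSiteBase <- function(seqChr, pos, base) {
  substr(seqChr, pos, pos) <- base
  seqChr
}

#' Build the known-sex cultivar panel
#'
#' 27 male and 24 female cultivars. Males carry the male-specific AG alleles
#' and the heterozygote code at all 12 discriminating RAN1 sites; females are
#' homozygous everywhere and carry no male-specific AG sequence. At each of
#' the 3 invalid sites one seed-chosen male is made homozygous and one
#' seed-chosen female heterozygous, so the site fails the universal
#' discrimination rule in both directions.
#'
#' @param nMale,nFemale panel composition.
#' @param seed integer seed.
#' @param models loci from [buildLocusModels()]; built from `seed` if omitted.
#' @return a [SamplePanel-class] (samples in seed-shuffled order).
#' @examples
#' \donttest{
#' panel <- buildCultivarPanel(seed = 1)
#' length(panel)  # 51
#' }
#' @export
buildCultivarPanel <- function(nMale = 27L, nFemale = 24L, seed = 1L,
                               models = buildLocusModels(seed)) {
  withLocalSeed(seed + 3L, {
    maleSeqs <- maleSampleSeqs(models)
    femSeqs <- femaleSampleSeqs(models)
    ids <- c(sprintf("cv_M%02d", seq_len(nMale)), sprintf("cv_F%02d", seq_len(nFemale)))
    sex <- c(rep("male", nMale), rep("female", nFemale))
    seqs <- c(rep(list(maleSeqs), nMale), rep(list(femSeqs), nFemale))
    # invalid sites: plant one hom male and one het female per site
    inv <- models$ran1$sites[models$ran1$sites$validity == "invalid", , drop = FALSE]
    for (i in seq_len(nrow(inv))) {
      vm <- sample(seq_len(nMale), 1L)
      vf <- nMale + sample(seq_len(nFemale), 1L)
      seqs[[vm]]["RAN1"] <- setSiteBase(seqs[[vm]]["RAN1"], inv$genomic_pos[i],
                                        inv$female_base[i])
      seqs[[vf]]["RAN1"] <- setSiteBase(seqs[[vf]]["RAN1"], inv$genomic_pos[i],
                                        inv$het_code[i])
    }
    ord <- sample(length(ids))
    info <- data.frame(sample_id = ids[ord], population = "cultivar",
                       true_sex = sex[ord])
    seqs <- seqs[ord]
    names(seqs) <- info$sample_id
    new("SamplePanel", info = info, seqs = seqs)
  })
}

#' Build an F1 seedling population
#'
#' Emulates the female (ga/ga) x male (GA/ga) cross: each seedling inherits
#' the male-determining haplotype with probability 0.5. With `fixedCounts`
#' the fixture reproduces an observed segregation exactly, in a
#' seed-determined order.
#'
#' @param n population size.
#' @param seed integer seed.
#' @param fixedCounts optional `c(female, male)` counts summing to `n`.
#' @param models loci from [buildLocusModels()]; built from `seed` if omitted.
#' @param population population label used in sample ids.
#' @return a [SamplePanel-class].
#' @examples
#' \donttest{
#' pop <- buildF1Population(242, seed = 1, fixedCounts = c(110, 132))
#' table(panelInfo(pop)$true_sex)
#' }
#' @export
buildF1Population <- function(n, seed = 1L, fixedCounts = NULL,
                              models = buildLocusModels(seed),
                              population = "F1") {
  withLocalSeed(seed + 4L, {
    if (!is.null(fixedCounts)) {
      if (sum(fixedCounts) != n)
        stop("fixedCounts must sum to n")
      sex <- sample(c(rep("female", fixedCounts[1]), rep("male", fixedCounts[2])))
    } else {
      sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "male", "female")
    }
    maleSeqs <- maleSampleSeqs(models)
    femSeqs <- femaleSampleSeqs(models)
    info <- data.frame(sample_id = sprintf("%s_%03d", population, seq_len(n)),
                       population = population, true_sex = sex)
    seqs <- lapply(sex, function(s) if (s == "male") maleSeqs else femSeqs)
    names(seqs) <- info$sample_id
    new("SamplePanel", info = info, seqs = seqs)
  })
}
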