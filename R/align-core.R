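# Global alignment, variant extraction, spliced CDS-to-genome mapping and
# translation: the computations behind the gene-structure claims (7 AG exons,
# 9 RAN1 exons, the 15-bp exon-7 indel, the 9-base AG2/AG3 difference).

#' Optimal global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment. A gap of length L costs
#' `gapOpen + L * gapExtend`. The defaults keep a contiguous 15-bp indel
#' cheaper than scattered gaps or mismatch runs, so a clean biological indel
#' is reported as one event. Tie-breaking is deterministic: substitution is
#' preferred over gaps, and a gap in `b` over a gap in `a`, so identical
#' inputs always give byte-identical alignments.
#'
#' IUPAC ambiguity codes are allowed and score as a match when the two base
#' sets intersect.
#'
#' @param a,b DNA strings (character or `DNAString`).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters.
#' @return a [GappedAlignment-class].
#' @examples
#' globalAlign("ACGT", "ACT")
#' @export
globalAlign <- function(a, b, match = 2, mismatch = -3,
                        gapOpen = -5, gapExtend = -2) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  res <- .gotoh_align(a, b, match, mismatch, gapOpen, gapExtend)
  new("GappedAlignment", aGapped = res$a_gapped, bGapped = res$b_gapped,
      score = res$score)
}

#' Extract substitutions and indels from a global alignment
#'
#' Maximal runs of gap columns are merged into single indel records. All
#' coordinates are 1-based positions in the respective ungapped input; for an
#' indel, `pos` is the first inserted base in the sequence carrying the extra
#' bases.
#'
#' @param aln a [GappedAlignment-class].
#' @return list with two data.frames: `substitutions` (`a_pos`, `b_pos`,
#'   `a_base`, `b_base`) and `indels` (`pos`, `length`, `inserted_in`
#'   (`"a"` or `"b"`), `sequence`).
#' @examples
#' diffAlignment(globalAlign("ACGT", "ACT"))
#' @export
diffAlignment <- function(aln) {
  stopifnot(is(aln, "GappedAlignment"))
  av <- strsplit(aln@aGapped, "")[[1]]
  bv <- strsplit(aln@bGapped, "")[[1]]
  apos <- cumsum(av != "-")
  bpos <- cumsum(bv != "-")
  sub <- which(av != "-" & bv != "-" & av != bv)
  substitutions <- data.frame(a_pos = apos[sub], b_pos = bpos[sub],
                              a_base = av[sub], b_base = bv[sub])
  gap <- av == "-" | bv == "-"
  indels <- data.frame(pos = integer(), length = integer(),
                       inserted_in = character(), sequence = character())
  if (any(gap)) {
    r <- rle(gap)
    colEnd <- cumsum(r$lengths)
    colStart <- colEnd - r$lengths + 1L
    for (k in which(r$values)) {
      cols <- colStart[k]:colEnd[k]
      inA <- bv[cols[1]] == "-"   # extra bases live in a
      seqv <- if (inA) av[cols] else bv[cols]
      # a run may mix gap-in-a and gap-in-b columns (adjacent indels): split
      isA <- bv[cols] == "-"
      for (part in split(cols, cumsum(c(TRUE, diff(isA) != 0)))) {
        pInA <- bv[part[1]] == "-"
        indels <- rbind(indels, data.frame(
          pos = if (pInA) apos[part[1]] else bpos[part[1]],
          length = length(part),
          inserted_in = if (pInA) "a" else "b",
          sequence = paste(if (pInA) av[part] else bv[part], collapse = "")))
      }
    }
  }
  indels <- indels[order(indels$pos), , drop = FALSE]
  rownames(indels) <- NULL
  list(substitutions = substitutions, indels = indels)
}

#' Map a CDS onto its genomic sequence (spliced alignment)
#'
#' Finds exon intervals whose concatenation reproduces the CDS exactly, with
#' every intervening intron starting GT and ending AG. The search is
#' greedy-longest-exon-first with backtracking, so the maximal consistent
#' exon chain is preferred and alternative spurious chains are only visited
#' if the greedy chain fails. Exact matching only: a CDS that is not a clean
#' spliced subsequence of the genomic sequence (e.g. an assembly error)
#' raises an error.
#'
#' @param cds coding sequence (character or `DNAString`).
#' @param genomic genomic sequence containing the spliced CDS.
#' @param name gene name for the returned model.
#' @param minIntron minimum intron length in bp.
#' @return a [GeneModel-class] with the recovered exon structure.
#' @examples
#' gm <- spliceMap("ATGAAATAA", "ATGAAGTAAGTTTTTTTTCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCAGATAA",
#'                 name = "toy", minIntron = 60)
#' exonCount(gm)
#' @export
spliceMap <- function(cds, genomic, name = "gene", minIntron = 60L) {
  cds <- toupper(as.character(cds)); genomic <- toupper(as.character(genomic))
  n <- nchar(cds); m <- nchar(genomic)
  if (n == 0L || m == 0L) stop("empty sequence")
  cv <- strsplit(cds, "")[[1]]; gv <- strsplit(genomic, "")[[1]]
  # genomic positions that can start an exon after a GT..AG intron
  afterAG <- which(c(FALSE, FALSE, gv[-m][-(m - 1L)] == "A" & gv[-1][-(m - 1L)] == "G"))
  failed <- new.env(parent = emptyenv())  # memo of dead (gpos, cpos) states
  # CDS must start at genomic position 1 and end at position m (CDS-exon model)
  search <- function(gpos, cpos) {
    key <- paste(gpos, cpos)
    if (!is.null(failed[[key]])) return(NULL)
    # longest common extension from (gpos, cpos)
    maxlen <- 0L
    while (gpos + maxlen <= m && cpos + maxlen <= n &&
           gv[gpos + maxlen] == cv[cpos + maxlen]) maxlen <- maxlen + 1L
    remaining <- n - cpos + 1L
    if (maxlen >= remaining && gpos + remaining - 1L == m)
      return(list(IRanges(gpos, m)))  # final exon must end the genomic seq
    maxExon <- min(maxlen, remaining - 1L)
    if (maxExon >= 1L) for (len in maxExon:1L) {
      intronStart <- gpos + len
      if (intronStart + 1L > m || gv[intronStart] != "G" || gv[intronStart + 1L] != "T")
        next
      nextC <- cpos + len
      # candidate next exon starts: intron >= minIntron, ends with AG
      g2lo <- intronStart + minIntron
      if (g2lo > m) next
      for (g2 in afterAG[afterAG >= g2lo & gv[afterAG] == cv[nextC]]) {
        rest <- search(g2, nextC)
        if (!is.null(rest)) return(c(list(IRanges(gpos, gpos + len - 1L)), rest))
      }
    }
    failed[[key]] <- TRUE
    NULL
  }
  if (gv[1] != cv[1])
    stop("no consistent exon chain: CDS does not start the genomic sequence")
  chain <- search(1L, 1L)
  if (is.null(chain))
    stop("no consistent GT..AG exon chain reproduces the CDS (possible assembly inconsistency)")
  exons <- do.call(c, chain)
  new("GeneModel", name = name, genomic = DNAString(genomic), exons = exons,
      strand = "+")
}

#' Translate a coding sequence
#'
#' Standard genetic code. The terminal stop codon is required and not
#' reported; an internal stop is an error.
#'
#' @param cds coding sequence, length divisible by 3.
#' @return protein string of length `nchar(cds)/3 - 1`.
#' @examples
#' translateCds("ATGTAA")  # "M"
#' @export
translateCds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1L, nchar(cds) - 2L, 3L), seq(3L, nchar(cds), 3L))
  if (!codons[length(codons)] %in% STOP_CODONS)
    stop("CDS does not end with a stop codon")
  aa <- Biostrings::GENETIC_CODE[codons[-length(codons)]]
  if (anyNA(aa)) stop("CDS contains an invalid codon")
  if (any(aa == "*"))
    stop(sprintf("internal stop codon at codon %d", which(aa == "*")[1]))
  paste(aa, collapse = "")
}
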