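# In-silico PCR with IUPAC-degenerate primers.
#
# Matching semantics are intersection-based on both sides: a primer base
# matches a template base iff their IUPAC base sets intersect, so degenerate
# primers match concrete templates and concrete primers match heterozygous
# consensus bases (e.g. primer C matches template Y). The heavy lifting is
# done by Biostrings::matchPattern(fixed = FALSE).

#' Expand a degenerate oligo into its concrete sequences
#'
#' @param seq an IUPAC DNA string (a character scalar or the `fwd`/`rev` slot
#'   of a [PrimerPair-class]).
#' @return character vector of all concrete A/C/G/T sequences the oligo
#'   represents; its length is the product of the per-position degeneracies.
#' @examples
#' expandDegenerate("ACGT")
#' length(expandDegenerate("ATGKCGTWCCAAAACAAGGWGAWGA"))  # 16
#' @export
expandDegenerate <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d", chars[bad[1]], bad[1]))
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[chars], "")
  do.call(paste0, expand.grid(rev(sets), stringsAsFactors = FALSE)[rev(seq_along(sets))])
}

revComp <- function(x) as.character(reverseComplement(DNAString(x)))

#' Locate primer binding sites on a template
#'
#' Scans both strands. A site is reported at its plus-strand coordinates
#' (1-based, inclusive). `strand == "+"` means the primer matches the plus
#' strand as written (it would extend rightwards); `strand == "-"` means the
#' reverse complement of the primer matches the plus strand (the primer binds
#' the plus strand and extends leftwards).
#'
#' @param template template sequence (character or `DNAString`), IUPAC codes
#'   allowed (heterozygous consensus positions match permissively).
#' @param primer an IUPAC DNA string.
#' @param maxMismatch maximum number of mismatching positions (default 0).
#' @param anchor3p if `TRUE`, reject sites with any mismatch in the 3
#'   3'-terminal primer bases (only relevant when `maxMismatch > 0`).
#' @return data.frame with columns `start`, `end`, `strand`, `mismatches`,
#'   sorted by `start`.
#' @examples
#' findPrimerSites("AAACAGGAGGAGGAAGCTTT", "CAGGAGGAGGAAGCT")
#' @export
findPrimerSites <- function(template, primer, maxMismatch = 0L, anchor3p = FALSE) {
  template <- if (is(template, "DNAString")) template else DNAString(toupper(as.character(template)))
  primer <- toupper(primer)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", primer)) {
    chars <- strsplit(primer, "")[[1]]
    bad <- which(!chars %in% names(Biostrings::IUPAC_CODE_MAP))[1]
    stop(sprintf("invalid IUPAC character '%s' at primer position %d", chars[bad], bad))
  }
  if (length(template) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  scan1 <- function(pat, strand) {
    if (nchar(pat) > length(template))
      return(NULL)
    m <- matchPattern(DNAString(pat), template, max.mismatch = maxMismatch,
                      fixed = FALSE)
    if (length(m) == 0L) return(NULL)
    mm <- vapply(seq_along(m), function(i) {
      countMismatchesIupac(pat, as.character(m[[i]]))
    }, integer(1))
    df <- data.frame(start = start(m), end = end(m), strand = strand,
                     mismatches = mm)
    if (anchor3p && maxMismatch > 0L) {
      keep <- vapply(seq_along(m), function(i) {
        hit <- as.character(m[[i]])
        if (strand == "-") hit <- revComp(hit)  # read in primer orientation
        tail3 <- substring(hit, nchar(hit) - 2L, nchar(hit))
        countMismatchesIupac(substring(pat2primer(pat, strand), nchar(pat) - 2L, nchar(pat)),
                             tail3) == 0L
      }, logical(1))
      df <- df[keep, , drop = FALSE]
    }
    df
  }
  pat2primer <- function(pat, strand) if (strand == "-") revComp(pat) else pat
  hits <- rbind(scan1(primer, "+"), scan1(revComp(primer), "-"))
  if (is.null(hits))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# mismatches under intersection semantics between two equal-length IUPAC strings
countMismatchesIupac <- function(a, b) {
  av <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(a, "")[[1]]], "")
  bv <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(b, "")[[1]]], "")
  sum(!mapply(function(x, y) length(intersect(x, y)) > 0L, av, bv))
}

#' Predict PCR products for a primer pair
#'
#' Enumerates every combination of a plus-strand forward-primer site and a
#' downstream minus-strand reverse-primer site whose implied product is at
#' most `maxLen` bp. Products include both primer footprints. Coordinates are
#' 1-based inclusive on the plus strand of the template.
#'
#' @param template template sequence (character or `DNAString`).
#' @param pair a [PrimerPair-class].
#' @param maxLen maximum product length (default 5000).
#' @param maxMismatch,anchor3p passed to [findPrimerSites()].
#' @param templateId template name used in the `template` column.
#' @return data.frame with columns `template`, `start`, `end`, `length`,
#'   `product`, `fwd_mismatches`, `rev_mismatches`, ordered by
#'   (`start`, `length`). The forward primer may also prime off the minus
#'   strand (paired with a plus-strand reverse-primer site); such products are
#'   reported in plus-strand coordinates as well.
#' @examples
#' pp <- primerPair("demo", "ACGTACGT", "TTTTACGT", NA)
#' amplify("ACGTACGTGGGGACGTAAAA", pp)
#' @export
amplify <- function(template, pair, maxLen = 5000L, maxMismatch = 0L,
                    anchor3p = FALSE, templateId = "template") {
  stopifnot(is(pair, "PrimerPair"))
  templateChr <- toupper(as.character(template))
  fhits <- findPrimerSites(templateChr, pair@fwd, maxMismatch, anchor3p)
  rhits <- findPrimerSites(templateChr, pair@rev, maxMismatch, anchor3p)
  out <- data.frame(template = character(), start = integer(), end = integer(),
                    length = integer(), product = character(),
                    fwd_mismatches = integer(), rev_mismatches = integer())
  # orientation 1: fwd on plus strand, rev on minus strand, fwd left of rev
  combine <- function(lhits, rhits2, lmm = "fwd", swap = FALSE) {
    res <- NULL
    for (i in seq_len(nrow(lhits))) {
      for (j in seq_len(nrow(rhits2))) {
        s <- lhits$start[i]; e <- rhits2$end[j]
        len <- e - s + 1L
        if (s <= rhits2$start[j] && len >= 1L && len <= maxLen &&
            e >= lhits$end[i]) {
          res <- rbind(res, data.frame(
            template = templateId, start = s, end = e, length = len,
            product = substr(templateChr, s, e),
            fwd_mismatches = if (swap) rhits2$mismatches[j] else lhits$mismatches[i],
            rev_mismatches = if (swap) lhits$mismatches[i] else rhits2$mismatches[j]))
        }
      }
    }
    res
  }
  res <- rbind(
    combine(fhits[fhits$strand == "+", , drop = FALSE],
            rhits[rhits$strand == "-", , drop = FALSE]),
    # orientation 2: rev primes the plus strand, fwd the minus strand
    combine(rhits[rhits$strand == "+", , drop = FALSE],
            fhits[fhits$strand == "-", , drop = FALSE], swap = TRUE))
  if (!is.null(res)) {
    res <- res[order(res$start, res$length), , drop = FALSE]
    rownames(res) <- NULL
    out <- res
  }
  out
}

#' Scan for restriction-enzyme motifs (CAPS emulation)
#'
#' Reports plus-strand occurrences of a concrete recognition motif.
#' Template positions carrying IUPAC ambiguity codes match if any expansion
#' of the code is compatible with the motif; such hits are flagged
#' `conditional` (a CAPS digest of a heterozygote cuts only one allele).
#'
#' @param seq template sequence (character or `DNAString`).
#' @param enzyme enzyme name from [restrictionMotifs()] or a concrete motif
#'   (e.g. `"ACATGT"` for PciI, `"ACGT"` for HpyCH4IV).
#' @return data.frame with columns `pos` (1-based start of the motif) and
#'   `conditional`.
#' @examples
#' restrictionScan("AAACGTAA", "HpyCH4IV")  # cuts at position 3
#' @export
restrictionScan <- function(seq, enzyme) {
  motifs <- restrictionMotifs()
  motif <- if (enzyme %in% names(motifs)) motifs[[enzyme]] else toupper(enzyme)
  stopifnot(grepl("^[ACGT]+$", motif))
  template <- if (is(seq, "DNAString")) seq else DNAString(toupper(as.character(seq)))
  if (length(template) < nchar(motif))
    return(data.frame(pos = integer(), conditional = logical()))
  m <- matchPattern(DNAString(motif), template, fixed = FALSE)
  if (length(m) == 0L)
    return(data.frame(pos = integer(), conditional = logical()))
  cond <- vapply(seq_along(m), function(i)
    !identical(as.character(m[[i]]), motif), logical(1))
  data.frame(pos = start(m), conditional = cond)
}

#' Built-in restriction enzyme motif table
#'
#' The two enzymes used for CAPS-based fig sex identification: PciI gives
#' 100% discrimination on the RAN1 CAPS product, HpyCH4IV is the
#' false-positive-prone alternative.
#'
#' @return named character vector of recognition motifs.
#' @export
restrictionMotifs <- function() {
  c(PciI = "ACATGT", HpyCH4IV = "ACGT")
}
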