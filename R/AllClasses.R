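#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet subseq reverseComplement
#'   matchPattern GENETIC_CODE IUPAC_CODE_MAP readDNAStringSet writeXStringSet
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols
#' @importFrom stats pchisq runif rbinom
#' @importFrom utils read.delim write.table
#' @useDynLib figsex, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Gene model with CDS-exon structure
#'
#' A `GeneModel` ties a genomic sequence to an ordered set of CDS-exon
#' intervals. Exons here are coding exons only (UTRs are not modelled), so the
#' concatenation of the exon subsequences is exactly the coding sequence: it
#' must begin with ATG, end with a stop codon, contain no internal in-frame
#' stop, and every intron must use canonical GT..AG splice sites.
#'
#' @slot name gene name.
#' @slot genomic genomic sequence ([Biostrings::DNAString]).
#' @slot exons exon intervals in genomic coordinates (1-based, inclusive).
#' @slot strand `"+"` or `"-"` (models are generated on `"+"`).
#' @export
setClass("GeneModel",
  representation(name = "character", genomic = "DNAString",
                 exons = "IRanges", strand = "character"))

setValidity("GeneModel", function(object) {
  msgs <- character()
  ex <- object@exons
  glen <- length(object@genomic)
  if (length(ex) == 0L) msgs <- c(msgs, "at least one exon is required")
  if (!object@strand %in% c("+", "-")) msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(ex) > 0L) {
    if (min(start(ex)) < 1L || max(end(ex)) > glen)
      msgs <- c(msgs, "exons extend beyond the genomic sequence")
    if (is.unsorted(start(ex), strictly = TRUE) ||
        any(start(ex)[-1] <= end(ex)[-length(ex)]))
      msgs <- c(msgs, "exons must be ascending and non-overlapping")
    cds <- paste(vapply(seq_along(ex), function(i)
      as.character(subseq(object@genomic, start(ex)[i], end(ex)[i])), ""),
      collapse = "")
    if (nchar(cds) %% 3L != 0L)
      msgs <- c(msgs, "CDS length must be divisible by 3")
    else {
      codons <- substring(cds, seq(1L, nchar(cds) - 2L, 3L),
                          seq(3L, nchar(cds), 3L))
      if (codons[1] != "ATG") msgs <- c(msgs, "CDS must begin with ATG")
      if (!codons[length(codons)] %in% STOP_CODONS)
        msgs <- c(msgs, "CDS must end with a stop codon")
      if (any(codons[-length(codons)] %in% STOP_CODONS))
        msgs <- c(msgs, "CDS contains an internal stop codon")
    }
    if (length(ex) > 1L) {
      g <- as.character(object@genomic)
      for (i in seq_len(length(ex) - 1L)) {
        is <- end(ex)[i] + 1L; ie <- start(ex)[i + 1L] - 1L
        if (substr(g, is, is + 1L) != "GT" || substr(g, ie - 1L, ie) != "AG")
          msgs <- c(msgs, sprintf("intron %d lacks GT..AG splice sites", i))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Primer pair for in-silico PCR
#'
#' Both oligos are written 5'->3' and may contain IUPAC degenerate bases.
#' `expectedLength` is the advertised product length in bp (`NA` if the pair
#' has no single expected product).
#'
#' @slot name pair name (e.g. `"AG-Marker"`).
#' @slot fwd,rev forward / reverse primer sequences.
#' @slot expectedLength expected product length in bp.
#' @export
setClass("PrimerPair",
  representation(name = "character", fwd = "character", rev = "character",
                 expectedLength = "integer"))

setValidity("PrimerPair", function(object) {
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", c(object@fwd, object@rev))
  if (!all(ok)) return("primer sequences must be non-empty IUPAC DNA")
  TRUE
})

#' Pairwise global alignment result
#'
#' Gapped versions of the two input sequences (equal length, `-` for gaps,
#' never gap-over-gap) plus the affine-gap alignment score.
#'
#' @slot aGapped,bGapped gapped sequences.
#' @slot score alignment score.
#' @export
setClass("GappedAlignment",
  representation(aGapped = "character", bGapped = "character",
                 score = "numeric"))

setValidity("GappedAlignment", function(object) {
  if (nchar(object@aGapped) != nchar(object@bGapped))
    return("gapped sequences must have equal length")
  a <- strsplit(object@aGapped, "")[[1]]
  b <- strsplit(object@bGapped, "")[[1]]
  if (any(a == "-" & b == "-")) return("gap-over-gap column")
  TRUE
})

#' Panel of plant samples with per-locus sequences
#'
#' A `SamplePanel` holds, for each sample, a named set of locus sequences
#' (IUPAC consensus strings; heterozygosity is encoded with ambiguity codes)
#' plus the fixture truth table. Loci used by the shipped generator:
#' `AG` (conserved AGAMOUS allele, genomic), `AG2`/`AG3` (male-specific
#' alleles, males only), `AG_cds` (the AG coding sequence cloned from
#' reproductive tissue: the pistil allele in females, the AG2 allele in
#' males), `RAN1` (genomic consensus) and `Actin` (amplification control).
#'
#' @slot info data.frame with columns `sample_id`, `population`, `true_sex`.
#' @slot seqs named list (one element per sample, in `info` order) of named
#'   character vectors of locus sequences.
#' @export
setClass("SamplePanel", representation(info = "data.frame", seqs = "list"))

setValidity("SamplePanel", function(object) {
  msgs <- character()
  need <- c("sample_id", "population", "true_sex")
  if (!all(need %in% names(object@info)))
    msgs <- c(msgs, "info must have sample_id, population, true_sex")
  else {
    if (anyDuplicated(object@info$sample_id))
      msgs <- c(msgs, "duplicate sample ids")
    if (!all(object@info$true_sex %in% c("male", "female", "unknown")))
      msgs <- c(msgs, "true_sex must be male/female/unknown")
    if (!identical(names(object@seqs), object@info$sample_id))
      msgs <- c(msgs, "names(seqs) must equal info$sample_id")
  }
  if (length(msgs)) msgs else TRUE
})
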