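#' @rdname GeneModel-class
#' @param object,x a `GeneModel`.
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))
#' @rdname GeneModel-class
#' @export
setGeneric("genomicSeq", function(x) standardGeneric("genomicSeq"))
#' @rdname GeneModel-class
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname GeneModel-class
#' @export
setGeneric("exonCount", function(x) standardGeneric("exonCount"))
#' @rdname GeneModel-class
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))

#' @rdname SamplePanel-class
#' @param x a `SamplePanel`.
#' @export
setGeneric("panelInfo", function(x) standardGeneric("panelInfo"))
#' @rdname SamplePanel-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname SamplePanel-class
#' @param id a sample identifier.
#' @export
setGeneric("sampleSeqs", function(x, id) standardGeneric("sampleSeqs"))

#' @rdname GappedAlignment-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname GeneModel-class
#' @export
setMethod("geneName", "GeneModel", function(x) x@name)
#' @rdname GeneModel-class
#' @export
setMethod("genomicSeq", "GeneModel", function(x) x@genomic)
#' @rdname GeneModel-class
#' @export
setMethod("exonRanges", "GeneModel", function(x) x@exons)
#' @rdname GeneModel-class
#' @export
setMethod("exonCount", "GeneModel", function(x) length(x@exons))

#' @rdname GeneModel-class
#' @export
setMethod("cdsSeq", "GeneModel", function(x) {
  ex <- x@exons
  DNAString(paste(vapply(seq_along(ex), function(i)
    as.character(subseq(x@genomic, start(ex)[i], end(ex)[i])), ""),
    collapse = ""))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s': %d bp genomic, %d exon(s), %d bp CDS, strand %s\n",
              object@name, length(object@genomic), length(object@exons),
              sum(width(object@exons)), object@strand))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair '%s': F %s / R %s (expected %s bp)\n",
              object@name, object@fwd, object@rev,
              ifelse(is.na(object@expectedLength), "?", object@expectedLength)))
})

setMethod("show", "GappedAlignment", function(object) {
  w <- nchar(object@aGapped)
  cat(sprintf("GappedAlignment: %d columns, score %.1f\n", w, object@score))
  if (w <= 60) {
    cat(" ", object@aGapped, "\n ", object@bGapped, "\n", sep = "")
  } else {
    cat(" ", substr(object@aGapped, 1, 57), "...\n ",
        substr(object@bGapped, 1, 57), "...\n", sep = "")
  }
})

#' @rdname SamplePanel-class
#' @export
setMethod("panelInfo", "SamplePanel", function(x) x@info)
#' @rdname SamplePanel-class
#' @export
setMethod("sampleIds", "SamplePanel", function(x) x@info$sample_id)
#' @rdname SamplePanel-class
#' @export
setMethod("sampleSeqs", "SamplePanel", function(x, id) {
  if (!id %in% x@info$sample_id) stop("unknown sample id: ", id)
  x@seqs[[id]]
})
#' @rdname SamplePanel-class
#' @export
setMethod("length", "SamplePanel", function(x) nrow(x@info))

setMethod("show", "SamplePanel", function(object) {
  tab <- table(factor(object@info$true_sex,
                      levels = c("female", "male", "unknown")))
  cat(sprintf("SamplePanel: %d samples (%d female, %d male, %d unknown), populations: %s\n",
              nrow(object@info), tab[["female"]], tab[["male"]], tab[["unknown"]],
              paste(unique(object@info$population), collapse = ", ")))
})

#' @rdname GappedAlignment-class
#' @export
setMethod("alignmentScore", "GappedAlignment", function(x) x@score)

#' Construct a PrimerPair
#'
#' @param name pair name.
#' @param fwd,rev forward and reverse oligo sequences (5'->3', IUPAC allowed).
#' @param expectedLength expected product length in bp, or `NA`.
#' @return a [PrimerPair-class] object.
#' @examples
#' primerPair("AG-Marker", "CAGGAGGAGGAAGCT", "TTACACTAATTGGAGGGCCA", 146)
#' @export
primerPair <- function(name, fwd, rev, expectedLength = NA_integer_) {
  new("PrimerPair", name = name, fwd = toupper(fwd), rev = toupper(rev),
      expectedLength = as.integer(expectedLength))
}
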