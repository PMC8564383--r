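# Discovery stage: class-diagnostic indels, presence/absence marker design
# by the published rule (indel = forward primer, last 20 CDS bp = reverse
# primer), and the universal het-male / hom-female SNP screen.

#' Find indels that perfectly separate the sexes at a locus
#'
#' Each sample's locus sequence is globally aligned to the designated
#' reference of the opposite class and indels are collected. An indel is
#' diagnostic when its presence/absence partitions the two classes perfectly:
#' every sample of one class carries it (as extra sequence relative to the
#' other class's reference) and no sample of the other class does.
#'
#' @param panel a [SamplePanel-class] with `true_sex` labels.
#' @param locus locus name present in every sample (e.g. `"AG_cds"`).
#' @param refs optional named list `list(male=, female=)` of reference
#'   sequences per class; defaults to the first sample of each class.
#' @return data.frame of diagnostic indels (`sequence`, `length`,
#'   `present_in`, `locus`, `position` (1-based CDS position in a carrier
#'   sequence)), sorted by decreasing length. Zero rows when no indel
#'   separates the classes.
#' @examples
#' \donttest{
#' panel <- buildCultivarPanel(seed = 1)
#' findDiagnosticIndels(panel, "AG_cds")  # the 15-bp CAGGAGGAGGAAGCT insertion
#' }
#' @export
findDiagnosticIndels <- function(panel, locus, refs = NULL) {
  stopifnot(is(panel, "SamplePanel"))
  info <- panelInfo(panel)
  have <- vapply(sampleIds(panel), function(id)
    locus %in% names(sampleSeqs(panel, id)), logical(1))
  if (!all(have))
    stop("locus '", locus, "' missing in sample(s): ",
         paste(sampleIds(panel)[!have], collapse = ", "))
  classes <- c("male", "female")
  if (is.null(refs)) {
    refs <- lapply(classes, function(cl) {
      ids <- info$sample_id[info$true_sex == cl]
      if (!length(ids)) stop("panel has no ", cl, " samples")
      sampleSeqs(panel, ids[1])[[locus]]
    })
    names(refs) <- classes
  }
  # indels each sample shows against the opposite-class reference, keyed by
  # (length, sequence); only extra sequence in the sample counts as carrying
  carried <- function(id, oppRef) {
    aln <- globalAlign(sampleSeqs(panel, id)[[locus]], oppRef)
    d <- diffAlignment(aln)
    ins <- d$indels[d$indels$inserted_in == "a", , drop = FALSE]
    ins
  }
  perClass <- lapply(classes, function(cl) {
    opp <- setdiff(classes, cl)
    ids <- info$sample_id[info$true_sex == cl]
    lapply(ids, carried, oppRef = refs[[opp]])
  })
  names(perClass) <- classes
  out <- data.frame(sequence = character(), length = integer(),
                    present_in = character(), locus = character(),
                    position = integer())
  for (cl in classes) {
    tabs <- perClass[[cl]]
    if (!length(tabs)) next
    cand <- unique(do.call(rbind, tabs)[, c("sequence", "length")])
    for (i in seq_len(nrow(cand))) {
      key <- cand$sequence[i]
      inAll <- all(vapply(tabs, function(t) key %in% t$sequence, logical(1)))
      opp <- setdiff(classes, cl)
      inNone <- !any(vapply(perClass[[opp]], function(t)
        any(vapply(t$sequence, function(s) grepl(key, s, fixed = TRUE) ||
                     grepl(s, key, fixed = TRUE), logical(1))), logical(1)))
      # the other class must also not carry the sequence at all
      oppIds <- info$sample_id[info$true_sex == opp]
      inNone <- inNone && !any(vapply(oppIds, function(id)
        grepl(key, sampleSeqs(panel, id)[[locus]], fixed = TRUE), logical(1)))
      if (inAll && inNone) {
        pos <- tabs[[1]]$pos[match(key, tabs[[1]]$sequence)]
        out <- rbind(out, data.frame(sequence = key, length = nchar(key),
                                     present_in = cl, locus = locus,
                                     position = pos))
      }
    }
  }
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design a presence/absence marker from a diagnostic indel
#'
#' The published AG-Marker rule: the indel sequence itself is the forward
#' primer; the reverse primer is the reverse complement of the last 20 bp of
#' the coding sequence (the footprint ends at the stop codon). The expected
#' product runs from the indel start through the CDS 3' end.
#'
#' @param indel one row of [findDiagnosticIndels()] output (or a list with
#'   `sequence` and `position`).
#' @param template [GeneModel-class] of a carrier allele.
#' @param revLen reverse-primer length (20 bp as published).
#' @return a [PrimerPair-class] with `expectedLength` filled in.
#' @examples
#' \donttest{
#' ag <- buildAgModels(seed = 1)
#' panel <- buildCultivarPanel(seed = 1, models = buildLocusModels(1))
#' ind <- findDiagnosticIndels(panel, "AG_cds")[1, ]
#' designPresenceMarker(ind, ag$male_ag2)  # expected length 146
#' }
#' @export
designPresenceMarker <- function(indel, template, revLen = 20L) {
  stopifnot(is(template, "GeneModel"))
  cds <- as.character(cdsSeq(template))
  fwd <- toupper(indel$sequence)
  start <- as.integer(indel$position)
  if (substr(cds, start, start + nchar(fwd) - 1L) != fwd)
    stop("indel sequence is absent from the template CDS at position ", start)
  if (nchar(cds) - (start + nchar(fwd) - 1L) < revLen)
    stop("fewer than ", revLen, " bp between the indel and the CDS end")
  revSite <- substr(cds, nchar(cds) - revLen + 1L, nchar(cds))
  pair <- primerPair("presence-marker", fwd, revComp(revSite),
                     expectedLength = nchar(cds) - start + 1L)
  # both primers must bind the template exactly once
  for (p in c(fwd = pair@fwd, rev = pair@rev)) {
    hits <- findPrimerSites(cds, p)
    if (nrow(hits) != 1L)
      stop("primer ", p, " matches the template at ", nrow(hits),
           " sites; need exactly 1 (", paste(hits$start, collapse = ", "), ")")
  }
  pair
}

#' Screen SNP sites for sex-discriminating capacity
#'
#' Implements the published all-or-nothing rule: a site discriminates iff
#' every male sample shows the heterozygote ambiguity code (the double-base
#' peak) and every female sample shows a single concrete base. Any violation
#' is recorded as a counterexample.
#'
#' @param panel a [SamplePanel-class].
#' @param sites SNP catalogue data.frame (needs `snp_id`, `label`,
#'   `genomic_pos`, `het_code`).
#' @param locus locus whose consensus carries the sites (default `"RAN1"`).
#' @param tolerance number of violating samples a site may have and still be
#'   called discriminating (0 = the published strict rule).
#' @return data.frame `snp_id`, `label`, `verdict`
#'   (`"discriminating"`/`"invalid"`), `n_counterexamples`, plus a list
#'   column `counterexamples` of data.frames (`sample_id`, `observed_state`).
#'   One row per site, in input order. A panel with an empty sex class
#'   satisfies the rule vacuously; a warning is emitted.
#' @examples
#' \donttest{
#' m <- buildLocusModels(1)
#' panel <- buildCultivarPanel(seed = 1, models = m)
#' v <- screenSnpSites(panel, m$ran1$sites)
#' table(v$verdict)  # 12 discriminating, 3 invalid
#' }
#' @export
screenSnpSites <- function(panel, sites, locus = "RAN1", tolerance = 0L) {
  stopifnot(is(panel, "SamplePanel"))
  info <- panelInfo(panel)
  for (cl in c("male", "female"))
    if (!any(info$true_sex == cl))
      warning("panel has no ", cl,
              " samples; the universal condition for that class holds vacuously")
  seqs <- vapply(sampleIds(panel), function(id) sampleSeqs(panel, id)[[locus]], "")
  maxPos <- max(sites$genomic_pos)
  if (any(nchar(seqs) < maxPos))
    stop("site position ", maxPos, " out of range for locus '", locus, "'")
  verdicts <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pos <- sites$genomic_pos[i]
    obs <- substr(seqs, pos, pos)
    isHet <- obs == sites$het_code[i]
    bad <- (info$true_sex == "male" & !isHet) |
           (info$true_sex == "female" & isHet)
    ce <- data.frame(sample_id = info$sample_id[bad],
                     observed_state = ifelse(isHet[bad], "het", paste0("hom:", obs[bad])))
    verdicts[[i]] <- list(
      verdict = if (nrow(ce) <= tolerance) "discriminating" else "invalid",
      ce = ce)
  }
  out <- data.frame(snp_id = sites$snp_id, label = sites$label,
                    verdict = vapply(verdicts, `[[`, "", "verdict"),
                    n_counterexamples = vapply(verdicts, function(v) nrow(v$ce), 0L))
  out$counterexamples <- lapply(verdicts, `[[`, "ce")
  out
}

#' Count SNP sites inside an amplicon
#'
#' @param sites SNP catalogue data.frame with `genomic_pos` (same coordinate
#'   frame as the amplicon's template).
#' @param amplicon one row of [amplify()] output (or any list with `start`
#'   and `end`, 1-based inclusive).
#' @param filter optional verdict/validity filter: keep only sites whose
#'   `validity` column equals this value (e.g. `"discriminating"`).
#' @return list with `count` and `sites` (the covered subset, input order).
#' @export
sitesInAmplicon <- function(sites, amplicon, filter = NULL) {
  if (!is.null(filter))
    sites <- sites[sites$validity == filter, , drop = FALSE]
  s <- as.integer(amplicon$start); e <- as.integer(amplicon$end)
  inside <- sites$genomic_pos >= s & sites$genomic_pos <= e
  list(count = sum(inside), sites = sites[inside, , drop = FALSE])
}
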