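# Genotyping stage: the AG-Marker presence/absence rule, the RAN1-Marker
# zygosity rule, and the per-sample consensus over markers.

#' Call sex from marker-product presence/absence
#'
#' The AG-Marker rule: a product of the expected length (146 bp) marks a
#' male; no product marks a female, but only when the positive amplification
#' control (Actin, 250 bp) produced its product — absence of a band is the
#' female signal, so a failed control voids the call. Products of unexpected
#' length give `ambiguous`. The marker and control are amplified from every
#' sequence the sample carries and products are pooled.
#'
#' @param seqs named character vector of one sample's locus sequences (from
#'   [sampleSeqs()]).
#' @param marker marker [PrimerPair-class] (needs `expectedLength`).
#' @param control control [PrimerPair-class], or `NULL` to disable the
#'   control requirement.
#' @param sampleId sample identifier for the output row.
#' @param maxLen passed to [amplify()].
#' @return one-row data.frame: `sample_id`, `marker`, `call` (`male`,
#'   `female`, `ambiguous` or `failed`), `evidence` (JSON).
#' @export
callByPresence <- function(seqs, marker, control = figPrimers()[["Actin"]],
                           sampleId = "sample", maxLen = 5000L) {
  stopifnot(is(marker, "PrimerPair"))
  pool <- function(pair) {
    do.call(rbind, lapply(names(seqs), function(nm)
      amplify(seqs[[nm]], pair, maxLen = maxLen, templateId = nm)))
  }
  ev <- list()
  if (!is.null(control)) {
    ctrl <- pool(control)
    ctrlLens <- if (is.null(ctrl)) integer(0) else ctrl$length
    ev$control_lengths <- ctrlLens
    ok <- length(ctrlLens) > 0 &&
      (is.na(control@expectedLength) || control@expectedLength %in% ctrlLens)
    if (!ok)
      return(data.frame(sample_id = sampleId, marker = marker@name,
                        call = "failed",
                        evidence = jsonlite::toJSON(ev, auto_unbox = TRUE)))
  }
  prod <- pool(marker)
  lens <- if (is.null(prod)) integer(0) else prod$length
  ev$marker_lengths <- lens
  call <- if (length(lens) == 0L) "female"
          else if (marker@expectedLength %in% lens) "male"
          else "ambiguous"
  data.frame(sample_id = sampleId, marker = marker@name, call = call,
             evidence = as.character(jsonlite::toJSON(ev, auto_unbox = TRUE)))
}

#' Genotype SNP sites inside a marker amplicon
#'
#' Amplifies the locus consensus with the marker pair and reads the zygosity
#' at each covered site: the site's heterozygote ambiguity code means `het`
#' (the male double-base peak), a concrete A/C/G/T means `hom`, `N` or any
#' other ambiguity means `missing`.
#'
#' @param seqs named character vector of one sample's locus sequences.
#' @param marker [PrimerPair-class] amplifying the locus.
#' @param sites SNP catalogue data.frame (`snp_id`, `genomic_pos`, `het_code`).
#' @param locus locus name (default `"RAN1"`).
#' @return named character vector of zygosities (`het`/`hom`/`missing`) for
#'   the covered sites, or `NULL` when amplification fails.
#' @export
genotypeSnpSites <- function(seqs, marker, sites, locus = "RAN1") {
  if (!locus %in% names(seqs)) return(NULL)
  amp <- amplify(seqs[[locus]], marker, templateId = locus)
  if (nrow(amp) == 0L) return(NULL)
  amp <- amp[1L, ]
  cov <- sitesInAmplicon(sites, amp)$sites
  if (nrow(cov) == 0L) return(character(0))
  obs <- substr(rep(seqs[[locus]], nrow(cov)), cov$genomic_pos, cov$genomic_pos)
  zyg <- ifelse(obs == cov$het_code, "het",
                ifelse(obs %in% DNA_BASES, "hom", "missing"))
  names(zyg) <- cov$snp_id
  zyg
}

#' Call sex from a zygosity vector
#'
#' All non-missing sites heterozygous -> male; all homozygous -> female; a
#' mixture -> ambiguous; nothing informative -> failed.
#'
#' @param zygosity character vector of `het`/`hom`/`missing` (from
#'   [genotypeSnpSites()]), or `NULL` for a failed amplification.
#' @param sampleId sample identifier.
#' @param markerName marker name for the output row.
#' @return one-row data.frame as in [callByPresence()].
#' @export
callBySnp <- function(zygosity, sampleId = "sample", markerName = "RAN1-Marker") {
  ev <- list(zygosity = paste(zygosity, collapse = ","))
  inf <- zygosity[zygosity != "missing"]
  call <- if (is.null(zygosity) || length(inf) == 0L) "failed"
          else if (all(inf == "het")) "male"
          else if (all(inf == "hom")) "female"
          else "ambiguous"
  data.frame(sample_id = sampleId, marker = markerName, call = call,
             evidence = as.character(jsonlite::toJSON(ev, auto_unbox = TRUE)))
}

#' Combine per-marker calls into a consensus call
#'
#' Unanimous non-failed calls give that call; any disagreement gives
#' `ambiguous`; all failed gives `failed`. Evidence of all inputs is kept.
#'
#' @param calls data.frame of per-marker call rows for one sample.
#' @return one-row data.frame with `marker = "consensus"`.
#' @export
consensusCall <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  ok <- calls$call[calls$call != "failed"]
  call <- if (length(ok) == 0L) "failed"
          else if (length(unique(ok)) == 1L) ok[1]
          else "ambiguous"
  data.frame(sample_id = calls$sample_id[1], marker = "consensus", call = call,
             evidence = as.character(jsonlite::toJSON(
               list(per_marker = paste(calls$marker, calls$call, sep = "=",
                                       collapse = ";")), auto_unbox = TRUE)))
}

#' Call sex for every sample of a panel with both markers
#'
#' Runs the AG-Marker presence caller and the RAN1-Marker zygosity caller on
#' each sample and adds the consensus.
#'
#' @param panel a [SamplePanel-class].
#' @param primers named list of [PrimerPair-class] (needs `AG-Marker`,
#'   `RAN1-Marker`, `Actin`), e.g. [figPrimers()].
#' @param sites SNP catalogue (e.g. `buildRan1Model(seed)$sites`).
#' @param controlEnabled require the Actin control for presence calls.
#' @return data.frame of call rows (three per sample: `AG-Marker`,
#'   `RAN1-Marker`, `consensus`).
#' @examples
#' \donttest{
#' m <- buildLocusModels(1)
#' panel <- buildCultivarPanel(seed = 1, models = m)
#' calls <- callPanel(panel, figPrimers(), m$ran1$sites)
#' table(calls$marker, calls$call)
#' }
#' @export
callPanel <- function(panel, primers = figPrimers(), sites,
                      controlEnabled = TRUE) {
  stopifnot(is(panel, "SamplePanel"))
  control <- if (controlEnabled) primers[["Actin"]] else NULL
  # samples sharing an identical sequence profile get identical calls, so
  # amplification is done once per profile (panels contain many clone-mates)
  cacheKeys <- character(0)
  cacheVals <- list()
  rows <- lapply(sampleIds(panel), function(id) {
    seqs <- sampleSeqs(panel, id)
    key <- paste(c(names(seqs), unname(seqs)), collapse = "\1")
    k <- match(key, cacheKeys)
    if (is.na(k)) {
      ag <- callByPresence(seqs, primers[["AG-Marker"]], control, sampleId = id)
      zyg <- genotypeSnpSites(seqs, primers[["RAN1-Marker"]], sites)
      cacheKeys[[length(cacheKeys) + 1L]] <<- key
      cacheVals[[length(cacheVals) + 1L]] <<- list(ag = ag, zyg = zyg)
      k <- length(cacheVals)
    }
    hit <- cacheVals[[k]]
    ag <- hit$ag
    ag$sample_id <- id
    rn <- callBySnp(hit$zyg, sampleId = id)
    rbind(ag, rn, consensusCall(rbind(ag, rn)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
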