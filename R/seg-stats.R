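# Validation stage: population tallies, sex-ratio formatting, the chi-square
# goodness-of-fit test against the 1:1 Mendelian expectation of the
# female (ga/ga) x male (GA/ga) cross, marker concordance, and the
# 2^-ddCt relative-expression helper.

#' Tally sex calls for one population
#'
#' The ratio string is `"1:x"` with `x = n_male/n_female` rounded to 2
#' significant figures (trailing zeros stripped), the formatting that
#' reproduces the published ratios 1:1.2 (110F/132M) and 1:0.73 (49F/36M).
#'
#' @param calls data.frame of call rows for one population (one row per
#'   sample; filter to one marker or to `consensus` first).
#' @param population population label for the output.
#' @return one-row data.frame: `population`, `n_female`, `n_male`,
#'   `n_ambiguous`, `n_failed`, `ratio_text`, `chi2`, `p_value` (chi-square
#'   against 1:1, females and males only).
#' @examples
#' calls <- data.frame(sample_id = 1:242, marker = "consensus",
#'                     call = rep(c("female", "male"), c(110, 132)))
#' tallyPopulation(calls)  # ratio 1:1.2, chi2 = 2
#' @export
tallyPopulation <- function(calls, population = "population") {
  n <- c(female = sum(calls$call == "female"), male = sum(calls$call == "male"),
         ambiguous = sum(calls$call == "ambiguous"),
         failed = sum(calls$call == "failed"))
  ratio <- if (n[["female"]] == 0L) "1:inf" else {
    x <- signif(n[["male"]] / n[["female"]], 2)
    paste0("1:", format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE))
  }
  cs <- if (n[["female"]] + n[["male"]] > 0L)
    chiSquare1to1(n[["female"]], n[["male"]]) else list(chi2 = NA_real_, p = NA_real_)
  data.frame(population = population, n_female = n[["female"]],
             n_male = n[["male"]], n_ambiguous = n[["ambiguous"]],
             n_failed = n[["failed"]], ratio_text = ratio,
             chi2 = cs$chi2, p_value = cs$p)
}

#' Chi-square goodness of fit to a 1:1 sex ratio
#'
#' `chi2 = sum((obs - exp)^2 / exp)` with `exp = n/2` for each sex, df = 1.
#' No continuity correction by default; `yates = TRUE` applies Yates'
#' correction.
#'
#' @param nFemale,nMale observed counts.
#' @param yates apply the continuity correction.
#' @return list with `chi2` and `p` (upper tail, df = 1).
#' @examples
#' chiSquare1to1(110, 132)  # chi2 = 2 exactly
#' @export
chiSquare1to1 <- function(nFemale, nMale, yates = FALSE) {
  n <- nFemale + nMale
  if (n <= 0L) stop("need at least one observation")
  e <- n / 2
  d <- abs(c(nFemale, nMale) - e)
  if (yates) d <- pmax(d - 0.5, 0)
  chi2 <- sum(d^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Concordance between two call sets
#'
#' @param callsA,callsB data.frames with `sample_id` and `call` over the same
#'   samples (e.g. AG-Marker vs RAN1-Marker rows of [callPanel()] output).
#' @return list with `fraction_identical` (over pairs where neither call is
#'   `failed`) and `discordant` (data.frame `sample_id`, `call_a`, `call_b`).
#' @examples
#' a <- data.frame(sample_id = 1:3, call = c("male", "female", "male"))
#' b <- data.frame(sample_id = 1:3, call = c("male", "male", "male"))
#' concordance(a, b)$fraction_identical  # 2/3
#' @export
concordance <- function(callsA, callsB) {
  common <- intersect(callsA$sample_id, callsB$sample_id)
  if (length(common) == 0L) stop("call sets share no samples")
  a <- callsA$call[match(common, callsA$sample_id)]
  b <- callsB$call[match(common, callsB$sample_id)]
  use <- a != "failed" & b != "failed"
  disc <- data.frame(sample_id = common[use & a != b],
                     call_a = a[use & a != b], call_b = b[use & a != b])
  list(fraction_identical = if (any(use)) mean(a[use] == b[use]) else NA_real_,
       discordant = disc)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_gene - Ct_ref` per sample; `ddCt = dCt_sample - dCt_calibrator`;
#' fold change = `2^-ddCt`.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (mean Ct over
#'   technical replicates).
#' @param refGene reference (housekeeping) gene name; required for every
#'   sample.
#' @param calibrator calibrator sample name.
#' @return data.frame `sample`, `gene`, `fold_change` for all non-reference
#'   genes; the calibrator row has fold change 1 by construction.
#' @examples
#' ct <- data.frame(sample = rep(c("cal", "s1"), each = 2),
#'                  gene = rep(c("Actin", "FcAG"), 2), ct = c(20, 25, 20, 24))
#' relativeExpression(ct, "Actin", "cal")  # s1 fold change 2
#' @export
relativeExpression <- function(ct, refGene, calibrator) {
  if (!calibrator %in% ct$sample) stop("calibrator sample not present")
  samples <- unique(ct$sample)
  refCt <- vapply(samples, function(s) {
    v <- ct$ct[ct$sample == s & ct$gene == refGene]
    if (length(v) != 1L) stop("reference gene missing (or duplicated) for sample ", s)
    v
  }, numeric(1))
  rows <- ct[ct$gene != refGene, , drop = FALSE]
  dct <- rows$ct - refCt[rows$sample]
  calib <- rows$sample == calibrator
  out <- do.call(rbind, lapply(unique(rows$gene), function(g) {
    sel <- rows$gene == g
    if (!any(sel & calib)) stop("calibrator lacks gene ", g)
    ddct <- dct[sel] - dct[sel & calib]
    data.frame(sample = rows$sample[sel], gene = g, fold_change = 2^(-ddct))
  }))
  rownames(out) <- NULL
  out
}
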