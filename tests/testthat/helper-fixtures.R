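# Shared fixtures, built once per test run (seed 1 study conditions).

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  if (is.null(.fx_cache[[name]])) {
    .fx_cache[[name]] <- switch(name,
      models = buildLocusModels(seed = 1),
      cultivar = buildCultivarPanel(seed = 1, models = fx("models")),
      pop1 = buildF1Population(242, seed = 1, fixedCounts = c(110, 132),
                               models = fx("models"), population = "pop1"),
      pop2 = buildF1Population(85, seed = 1, fixedCounts = c(49, 36),
                               models = fx("models"), population = "pop2"),
      primers = figPrimers(),
      cultivarCalls = callPanel(fx("cultivar"), fx("primers"),
                                fx("models")$ran1$sites),
      pop1Calls = callPanel(fx("pop1"), fx("primers"), fx("models")$ran1$sites),
      pop2Calls = callPanel(fx("pop2"), fx("primers"), fx("models")$ran1$sites),
      stop("unknown fixture ", name))
  }
  .fx_cache[[name]]
}

# small hand-built two-sample panel (one male, one female) around given seqs
miniPanel <- function(maleSeqs, femaleSeqs) {
  info <- data.frame(sample_id = c("m1", "f1"), population = "mini",
                     true_sex = c("male", "female"))
  new("SamplePanel", info = info,
      seqs = stats::setNames(list(maleSeqs, femaleSeqs), info$sample_id))
}
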