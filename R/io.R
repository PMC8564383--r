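# Readers and writers: IUPAC FASTA, the published-assay primer TSV, and the fixture
# directory (per-sample multi-FASTA + GFF3 gene models + site/truth TSVs +
# a JSON manifest sufficient to regenerate everything from the seed).

#' Read a FASTA file of IUPAC DNA sequences
#'
#' Wrapped or unwrapped lines are accepted; sequences are upper-cased and
#' validated against the IUPAC alphabet. Duplicate record ids and illegal
#' characters are reported with their line number.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaIupac <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop("not a FASTA file: ", path)
  seqLines <- which(!hdr & nzchar(lines))
  bad <- seqLines[grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", lines[seqLines])]
  if (length(bad))
    stop("illegal sequence character at line ", bad[1], " of ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  dup <- which(hdr)[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id '", ids[duplicated(ids)][1], "' at line ", dup[1])
  grp <- cumsum(hdr)
  seqs <- vapply(seq_along(ids), function(i)
    toupper(paste(lines[!hdr & grp == i], collapse = "")), "")
  names(seqs) <- ids
  seqs
}

#' Write IUPAC DNA sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFastaIupac <- function(seqs, path, width = 70L) {
  set <- DNAStringSet(toupper(unname(seqs)))
  names(set) <- names(seqs)
  writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a primer table and assemble primer pairs
#'
#' TSV with columns `name`, `sequence`, `orientation`, `expected_length`.
#' Rows pair by the shared name before the `-F`/`-R` suffix.
#'
#' @param path TSV file.
#' @return named list of [PrimerPair-class] objects.
#' @examples
#' length(figPrimers())  # the 9 published pairs
#' @export
readPrimerTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation", "expected_length")
  if (!all(need %in% names(tab))) stop("primer table needs columns: ",
                                       paste(need, collapse = ", "))
  if (!all(grepl("-(F|R)$", tab$name)))
    stop("primer names must end in -F or -R: ",
         paste(tab$name[!grepl("-(F|R)$", tab$name)], collapse = ", "))
  base <- sub("-(F|R)$", "", tab$name)
  pairs <- list()
  for (nm in unique(base)) {
    rows <- tab[base == nm, , drop = FALSE]
    f <- rows[grepl("-F$", rows$name), , drop = FALSE]
    r <- rows[grepl("-R$", rows$name), , drop = FALSE]
    if (nrow(f) != 1L || nrow(r) != 1L)
      stop("unpaired primer for '", nm, "': need exactly one -F and one -R row")
    len <- unique(rows$expected_length[!is.na(rows$expected_length)])
    if (length(len) > 1L) stop("conflicting expected lengths for '", nm, "'")
    if (length(len) == 1L && (!is.numeric(len) || len <= 0))
      stop("expected length for '", nm, "' must be a positive integer")
    pairs[[nm]] <- primerPair(nm, f$sequence, r$sequence,
                              if (length(len)) len else NA_integer_)
  }
  pairs
}

#' The published assay primer pairs
#'
#' All nine pairs used by the assays: the full-CDS AG and FcRAN1 pairs, the
#' AG-Marker (146 bp), the RAN1-Marker (608 bp), the SNP-screening pairs
#' 1-SNP/6SNP-2/2-SNP (371/766/444 bp), the qPCR pair (156 bp) and the Actin
#' control (250 bp).
#'
#' @return named list of [PrimerPair-class] objects.
#' @export
figPrimers <- function() {
  readPrimerTable(system.file("extdata", "assay_primers.tsv",
                              package = "figsex", mustWork = TRUE))
}

# flat named vector of all published assay oligos (for exhaustive uniqueness scans)
figPrimerOligos <- function() {
  pairs <- figPrimers()
  oligos <- character(0)
  for (p in pairs) {
    oligos[paste0(p@name, "-F")] <- p@fwd
    oligos[paste0(p@name, "-R")] <- p@rev
  }
  oligos
}

geneModelsToGRanges <- function(models) {
  rows <- lapply(models, function(m) {
    ex <- exonRanges(m)
    data.frame(
      seqnames = geneName(m),
      start = c(1L, start(ex)), end = c(length(genomicSeq(m)), end(ex)),
      strand = m@strand,
      type = c("gene", rep("exon", length(ex))),
      ID = c(geneName(m), sprintf("%s:exon%d", geneName(m), seq_along(ex))),
      Parent = c(NA_character_, rep(geneName(m), length(ex))))
  })
  df <- do.call(rbind, unname(rows))
  GenomicRanges::GRanges(
    seqnames = df$seqnames, ranges = IRanges(df$start, df$end),
    strand = df$strand, type = df$type, ID = df$ID, Parent = df$Parent)
}

#' Write panel fixtures to a directory
#'
#' Writes `samples.fasta` (records named `sample|locus`), `truth.tsv`,
#' optionally `snp_sites.tsv` and the gene models (`gene_models.gff3` +
#' `gene_models.fasta`), and a `manifest.json` recording the seed and
#' parameters. Re-running with identical inputs reproduces the files
#' byte-identically; [readPanelFixtures()] restores the panel exactly.
#'
#' @param panel a [SamplePanel-class].
#' @param dir output directory (created if needed).
#' @param models optional [buildLocusModels()] output to serialise.
#' @param sites optional SNP catalogue data.frame.
#' @param seed,params recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
writePanelFixtures <- function(panel, dir, models = NULL, sites = NULL,
                               seed = NULL, params = list()) {
  stopifnot(is(panel, "SamplePanel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- unlist(lapply(sampleIds(panel), function(id) {
    s <- sampleSeqs(panel, id)
    names(s) <- paste(id, names(s), sep = "|")
    s
  }))
  writeFastaIupac(seqs, file.path(dir, "samples.fasta"))
  write.table(panelInfo(panel), file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sites))
    write.table(sites, file.path(dir, "snp_sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(models)) {
    gm <- list(models$ag$female, models$ag$male_ag2, models$ag$male_ag3,
               models$ran1$gene)
    rtracklayer::export(geneModelsToGRanges(gm),
                        file.path(dir, "gene_models.gff3"), format = "gff3")
    gseqs <- vapply(gm, function(m) as.character(genomicSeq(m)), "")
    names(gseqs) <- vapply(gm, geneName, "")
    writeFastaIupac(gseqs, file.path(dir, "gene_models.fasta"))
  }
  manifest <- list(seed = seed, params = params,
                   n_samples = length(panel),
                   populations = unique(panelInfo(panel)$population),
                   loci = sort(unique(unlist(lapply(panel@seqs, names)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read panel fixtures back from a directory
#'
#' @param dir directory written by [writePanelFixtures()].
#' @return list with `panel` ([SamplePanel-class]), `sites` (data.frame or
#'   `NULL`), `models` (list of [GeneModel-class] or `NULL`) and `manifest`.
#' @export
readPanelFixtures <- function(dir) {
  seqs <- readFastaIupac(file.path(dir, "samples.fasta"))
  info <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  sid <- vapply(parts, `[`, "", 1L)
  locus <- vapply(parts, `[`, "", 2L)
  slist <- lapply(info$sample_id, function(id) {
    s <- seqs[sid == id]
    names(s) <- locus[sid == id]
    s
  })
  names(slist) <- info$sample_id
  panel <- new("SamplePanel", info = info, seqs = slist)
  sitesPath <- file.path(dir, "snp_sites.tsv")
  sites <- if (file.exists(sitesPath))
    read.delim(sitesPath, stringsAsFactors = FALSE) else NULL
  models <- NULL
  gffPath <- file.path(dir, "gene_models.gff3")
  if (file.exists(gffPath)) {
    gr <- rtracklayer::import(gffPath)
    gseqs <- readFastaIupac(file.path(dir, "gene_models.fasta"))
    models <- lapply(names(gseqs), function(nm) {
      sel <- as.character(GenomicRanges::seqnames(gr)) == nm & gr$type == "exon"
      new("GeneModel", name = nm, genomic = DNAString(gseqs[[nm]]),
          exons = IRanges(GenomicRanges::start(gr[sel]),
                          GenomicRanges::end(gr[sel])),
          strand = "+")
    })
    names(models) <- names(gseqs)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  list(panel = panel, sites = sites, models = models, manifest = manifest)
}
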