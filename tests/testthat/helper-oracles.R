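# Independent oracles used to validate the implementation paths. These are
# deliberately plain re-derivations: a small dynamic program for affine-gap
# global alignment scores and naive position-by-position scanners for primer
# sites and restriction motifs.

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupacCompatible <- function(x, y) {
  length(intersect(.oracle_iupac[[x]], .oracle_iupac[[y]])) > 0L
}

# optimal global affine-gap score; gap of length L costs open + L * ext
oracleAlignScore <- function(a, b, match = 2, mismatch = -3,
                             open = -5, ext = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- open + ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- open + ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (iupacCompatible(av[i], bv[j])) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, X[i, j + 1] + ext,
                             Y[i, j + 1] + open + ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, Y[i + 1, j] + ext,
                             X[i + 1, j] + open + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracleRevComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive scan of primer sites on both strands, 0 mismatches
oraclePrimerSites <- function(template, primer) {
  tv <- strsplit(template, "")[[1]]
  scan <- function(pat, strand) {
    pv <- strsplit(pat, "")[[1]]
    k <- length(pv)
    out <- NULL
    if (k > length(tv)) return(NULL)
    for (i in seq_len(length(tv) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!iupacCompatible(pv[j], tv[i + j - 1L])) { ok <- FALSE; break }
      }
      if (ok) out <- rbind(out, data.frame(start = i, end = i + k - 1L,
                                           strand = strand))
    }
    out
  }
  res <- rbind(scan(primer, "+"), scan(oracleRevComp(primer), "-"))
  if (is.null(res)) data.frame(start = integer(), end = integer(),
                               strand = character())
  else res[order(res$start, res$strand), , drop = FALSE]
}

oracleMotifScan <- function(seq, motif) {
  tv <- strsplit(seq, "")[[1]]; mv <- strsplit(motif, "")[[1]]
  k <- length(mv)
  out <- integer(0)
  if (k > length(tv)) return(out)
  for (i in seq_len(length(tv) - k + 1L)) {
    if (all(vapply(seq_len(k), function(j)
      iupacCompatible(mv[j], tv[i + j - 1L]), logical(1))))
      out <- c(out, i)
  }
  out
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
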