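# Shared helpers: residue splitting, an exhaustive alignment oracle for
# short sequences, and toy builders.

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Enumerate every global alignment of two short strings, score with affine
# gaps (cost = open + len * ext, matching the implementation's scoring),
# and return the percent-similarity values of all maximum-score alignments
# (terminal gap columns excluded from the alignment length, positive-scoring
# pairs in the numerator). Only safe for sequences of length <= 7.
oracle_similarities <- function(a, b, open = 10, ext = 0.5) {
  a <- chars(a); b <- chars(b)
  alns <- list()
  rec <- function(i, j, qa, sa) {
    if (i > length(a) && j > length(b)) {
      alns[[length(alns) + 1L]] <<- list(qa = qa, sa = sa)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1L, j + 1L, c(qa, a[i]), c(sa, b[j]))
    }
    if (i <= length(a)) rec(i + 1L, j, c(qa, a[i]), c(sa, "-"))
    if (j <= length(b)) rec(i, j + 1L, c(qa, "-"), c(sa, b[j]))
  }
  rec(1L, 1L, character(0), character(0))

  score_aln <- function(al) {
    s <- 0; gap_q <- FALSE; gap_s <- FALSE
    for (k in seq_along(al$qa)) {
      if (al$qa[k] == "-") {
        s <- s - ext - (if (!gap_q) open else 0)
        gap_q <- TRUE; gap_s <- FALSE
      } else if (al$sa[k] == "-") {
        s <- s - ext - (if (!gap_s) open else 0)
        gap_s <- TRUE; gap_q <- FALSE
      } else {
        s <- s + b62[al$qa[k], al$sa[k]]
        gap_q <- FALSE; gap_s <- FALSE
      }
    }
    s
  }
  sim_of <- function(al) {
    both <- al$qa != "-" & al$sa != "-"
    inner <- which(both)
    if (!length(inner)) return(0)
    keep <- seq.int(min(inner), max(inner))
    qa <- al$qa[keep]; sa <- al$sa[keep]
    ok <- qa != "-" & sa != "-"
    pos <- sum(ok & b62[cbind(match(qa, rownames(b62)),
                              match(sa, colnames(b62)))] > 0, na.rm = TRUE)
    100 * pos / length(keep)
  }
  scores <- vapply(alns, score_aln, numeric(1))
  best <- which(scores > max(scores) - 1e-9)
  unique(vapply(alns[best], sim_of, numeric(1)))
}

# toy gene-model builder in the package's normalized form
toy_model <- function(id, seqid, strand, exons) {
  mat <- cbind(start = vapply(exons, `[`, 0, 1),
               end = vapply(exons, `[`, 0, 2))
  list(id = id, seqid = seqid, strand = strand,
       start = min(mat[, "start"]), end = max(mat[, "end"]),
       exons = mat, cds = mat)
}

toy_models <- function(...) structure(list(...), class = "aqp_gene_models")
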