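# Gene-inventory curation: gene-model arithmetic, family-level summary
# statistics, and pseudogene flagging.

#' Protein length implied by a CDS length
#'
#' The coding sequence runs from start to stop codon, so a CDS of `n` bp
#' encodes `n/3 - 1` residues (the stop codon is excluded).
#'
#' @param cds_len CDS length(s) in bp; must be >= 6 and divisible by 3
#' @return integer residue count(s)
#' @export
#' @examples
#' protein_length_from_cds(729) # 242
protein_length_from_cds <- function(cds_len) {
  if (any(cds_len < 6)) stop("CDS length must be at least 6 bp")
  off <- which(cds_len %% 3 != 0)
  if (length(off)) {
    stop("frameshift: CDS length not divisible by 3: ",
         paste(cds_len[off], collapse = ", "))
  }
  as.integer(cds_len / 3 - 1)
}

#' Reconstruct gene, transcript and genomic spans for a catalog record
#'
#' Applies the catalog's span arithmetic: the gene span (start to stop
#' codon) is the CDS plus all introns; the transcript span adds the UTRs;
#' the genomic span is the absolute width of the identified coordinate pair.
#' Recorded values are compared against the computed ones and
#' inconsistencies are reported, never raised.
#'
#' @param rec a list or one-row data.frame with `cds_len`, optional
#'   `introns` (numeric vector), `utr5`, `utr3`, `gene_len`,
#'   `identified_start`, `identified_end`
#' @return list with `gene_span`, `transcript_span`, `genomic_span`
#'   (NA when coordinates are absent), and `flags`, a character vector of
#'   reported inconsistencies (empty when all recorded values agree)
#' @export
#' @examples
#' reconstruct_spans(list(cds_len = 720, introns = c(590, 3167),
#'                        utr5 = 329, utr3 = 562))
reconstruct_spans <- function(rec) {
  g <- function(field) {
    v <- rec[[field]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
  }
  introns <- rec[["introns"]]
  if (is.list(introns)) introns <- introns[[1]]
  if (is.null(introns)) introns <- numeric(0)
  introns <- introns[!is.na(introns)]
  if (any(introns <= 0)) stop("intron lengths must be positive")

  cds_len <- g("cds_len")
  if (is.na(cds_len)) stop("record has no cds_len")
  gene_span <- cds_len + sum(introns)
  utr5 <- g("utr5"); utr3 <- g("utr3")
  transcript_span <- gene_span + (if (is.na(utr5)) 0 else utr5) +
    (if (is.na(utr3)) 0 else utr3)
  is_ <- g("identified_start"); ie <- g("identified_end")
  genomic_span <- if (is.na(is_) || is.na(ie)) NA_real_ else abs(ie - is_) + 1

  flags <- character(0)
  rec_gene_len <- g("gene_len")
  if (!is.na(rec_gene_len) && length(introns) > 0 &&
      rec_gene_len != gene_span) {
    flags <- c(flags, sprintf("recorded gene length %d != computed %d",
                              as.integer(rec_gene_len),
                              as.integer(gene_span)))
  }
  if (!is.na(genomic_span) && genomic_span != transcript_span) {
    flags <- c(flags, sprintf(
      "genomic span %d (coordinates) != transcript span %d (components)",
      as.integer(genomic_span), as.integer(transcript_span)))
  }
  list(gene_span = gene_span, transcript_span = transcript_span,
       genomic_span = genomic_span, flags = flags)
}

#' Family-level summary of a gene inventory
#'
#' Deterministic recount of the catalog: scaffold and chromosome
#' distribution, ORF and gene-length ranges, EST and read support,
#' alternative splicing, subfamily composition and intron statistics.
#' Records lacking a per-intron list contribute `gene_len - cds_len` as a
#' single unresolved pseudo-intron (when positive).
#'
#' @param records inventory data.frame as returned by
#'   `load_fixture("table2_inventory")` (columns `name`, `scaffold`,
#'   `chromosome`, `cds_len`, `gene_len`, `est_hits`, `expressed`,
#'   `splice_est`, `splice_read`, `subfamily`; optional list column
#'   `introns`)
#' @return a `family_summary` list; all counts are zero on empty input
#' @export
family_summary <- function(records) {
  n <- nrow(records)
  if (is.null(n) || n == 0L) {
    return(structure(list(
      n_genes = 0L, n_scaffolds = 0L, multi_gene_scaffolds = character(0),
      per_chromosome_counts = integer(0), n_chromosomes_multi = 0L,
      orf_min = NA_integer_, orf_max = NA_integer_,
      gene_min = NA_integer_, gene_max = NA_integer_,
      n_est_supported = 0L, max_est = list(gene = NA_character_, count = 0L),
      n_splice_read = 0L, n_splice_est = 0L,
      subfamily_counts = integer(0),
      intron_mean = NA_real_, intron_min = NA_integer_,
      intron_max = NA_integer_, n_introns_unresolved = 0L
    ), class = "family_summary"))
  }
  scaff <- table(records$scaffold)
  chrom <- table(records$chromosome)
  imax <- which.max(records$est_hits)

  introns <- numeric(0)
  unresolved <- 0L
  for (i in seq_len(n)) {
    per <- if ("introns" %in% names(records)) records$introns[[i]] else NULL
    per <- per[!is.na(per)]
    if (length(per)) {
      introns <- c(introns, per)
    } else {
      gap <- records$gene_len[i] - records$cds_len[i]
      if (!is.na(gap) && gap > 0) {
        introns <- c(introns, gap)
        unresolved <- unresolved + 1L
      }
    }
  }
  structure(list(
    n_genes = n,
    n_scaffolds = length(scaff),
    multi_gene_scaffolds = names(scaff)[scaff > 1L],
    per_chromosome_counts = c(chrom),
    n_chromosomes_multi = sum(chrom > 1L),
    orf_min = min(records$cds_len), orf_max = max(records$cds_len),
    gene_min = min(records$gene_len), gene_max = max(records$gene_len),
    n_est_supported = sum(records$est_hits > 0L),
    max_est = list(gene = records$name[imax],
                   count = records$est_hits[imax]),
    n_splice_read = sum(records$splice_read),
    n_splice_est = sum(records$splice_est),
    subfamily_counts = c(table(records$subfamily)),
    intron_mean = if (length(introns)) mean(introns) else NA_real_,
    intron_min = if (length(introns)) as.integer(min(introns)) else NA_integer_,
    intron_max = if (length(introns)) as.integer(max(introns)) else NA_integer_,
    n_introns_unresolved = unresolved
  ), class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat("family_summary:", x$n_genes, "genes on", x$n_scaffolds, "scaffolds\n")
  cat("  subfamilies:",
      paste(names(x$subfamily_counts), x$subfamily_counts,
            sep = "=", collapse = " "), "\n")
  cat("  EST-supported:", x$n_est_supported,
      "| splicing (read/EST):", x$n_splice_read, "/", x$n_splice_est, "\n")
  invisible(x)
}

#' Flag a pseudogene candidate from its CDS
#'
#' A locus is called a pseudogene candidate when its CDS carries an
#' ORF-disrupting difference relative to the subgroup consensus (a
#' frameshifting indel or a premature stop codon) AND no expression evidence
#' exists. Both conditions are required; an expressed gene is never flagged.
#'
#' @param cds_seq CDS nucleotide sequence (character scalar)
#' @param consensus subgroup consensus CDS to compare against
#' @param expressed logical; any EST or read support for expression
#' @param min_identity alignment identity floor below which the pair is
#'   considered unalignable (error)
#' @return list with `pseudogene` (logical) and `evidence` (character
#'   vector, one entry per disruption with its 1-based consensus position)
#' @export
flag_pseudogene <- function(cds_seq, consensus, expressed = FALSE,
                            min_identity = 50) {
  cds_seq <- toupper(cds_seq)
  consensus <- toupper(consensus)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(cds_seq, consensus, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  if (Biostrings::pid(pa) < min_identity) {
    stop("sequences are unalignable (identity below ", min_identity, "%)")
  }
  qa <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(pa)))

  evidence <- character(0)
  # scan indel runs; a run whose length is not a multiple of 3 shifts frame
  i <- 1L
  cons_pos <- 0L
  while (i <= length(qa)) {
    if (qa[i] == "-" || sa[i] == "-") {
      run_start_cons <- cons_pos + 1L
      is_del <- qa[i] == "-"
      len <- 0L
      while (i <= length(qa) &&
             ((is_del && qa[i] == "-") || (!is_del && sa[i] == "-"))) {
        if (sa[i] != "-") cons_pos <- cons_pos + 1L
        len <- len + 1L
        i <- i + 1L
      }
      if (len %% 3L != 0L) {
        evidence <- c(evidence, sprintf("frameshift @%d", run_start_cons))
      }
    } else {
      cons_pos <- cons_pos + 1L
      i <- i + 1L
    }
  }
  # premature internal stop in the query reading frame
  n_codons <- nchar(cds_seq) %/% 3L
  if (n_codons >= 2L) {
    codons <- substring(cds_seq, 3L * (seq_len(n_codons) - 1L) + 1L,
                        3L * seq_len(n_codons))
    internal <- codons[-n_codons]
    stops <- which(internal %in% c("TAA", "TAG", "TGA"))
    if (length(stops)) {
      evidence <- c(evidence,
                    sprintf("premature stop @codon %d", stops))
    }
  }
  list(pseudogene = length(evidence) > 0L && !isTRUE(expressed),
       evidence = evidence)
}
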