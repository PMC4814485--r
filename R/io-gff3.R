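# Gene models are held in a normalized form: 1-based inclusive coordinates
# on (seqid, strand, min, max), with an explicit '+'/'-' strand flag.
# Catalog-style descending coordinate pairs are interpreted as minus strand.

#' Read gene models from a GFF3 file
#'
#' Parses GFF3 (via rtracklayer) into a list of normalized gene models. Each
#' gene is expected to carry `mRNA` (optional) and `exon`/`CDS` children.
#' Coordinates are 1-based inclusive; minus-strand genes are normalized to
#' `start <= end` with strand `"-"`.
#'
#' @param path path to a GFF3 file
#' @return an object of class `aqp_gene_models`: a named list of gene
#'   models, each a list with `id`, `seqid`, `strand`, `start`, `end`,
#'   `exons` and `cds` (two-column matrices, rows sorted by start)
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  df$Parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p)[1]
    }, character(1))
  } else NA_character_

  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("GFF3 contains no gene features: ", path)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]

  # map each part to its gene (directly or through its mRNA)
  mrna_gene <- setNames(mrna$Parent, mrna$ID)
  part_gene <- ifelse(parts$Parent %in% genes$ID, parts$Parent,
                      unname(mrna_gene[parts$Parent]))

  models <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    sel <- which(part_gene == gid)
    p <- parts[sel, , drop = FALSE]
    get_mat <- function(type) {
      q <- p[p$type == type, , drop = FALSE]
      q <- q[order(q$start), , drop = FALSE]
      m <- cbind(start = q$start, end = q$end)
      if (nrow(m) > 1L) {
        if (any(m[-1L, "start"] <= m[-nrow(m), "end"])) {
          stop("overlapping ", type, " parts within gene '", gid, "'")
        }
      }
      m
    }
    list(id = gid,
         seqid = as.character(genes$seqnames[i]),
         strand = as.character(genes$strand[i]),
         start = genes$start[i],
         end = genes$end[i],
         exons = get_mat("exon"),
         cds = get_mat("CDS"))
  })
  names(models) <- genes$ID
  structure(models, class = "aqp_gene_models")
}

#' Write gene models to a GFF3 file
#'
#' @param models an `aqp_gene_models` object (see [read_gff3()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "aqp_gene_models"))
  rows <- list()
  for (m in models) {
    mrna_id <- paste0(m$id, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$seqid, source = "aqpscan", type = "gene",
      start = m$start, end = m$end, strand = m$strand,
      attr = paste0("ID=", m$id), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$seqid, source = "aqpscan", type = "mRNA",
      start = m$start, end = m$end, strand = m$strand,
      attr = paste0("ID=", mrna_id, ";Parent=", m$id),
      stringsAsFactors = FALSE)
    for (part in c("exon", "CDS")) {
      mat <- if (part == "exon") m$exons else m$cds
      for (k in seq_len(nrow(mat))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = m$seqid, source = "aqpscan", type = part,
          start = mat[k, "start"], end = mat[k, "end"], strand = m$strand,
          attr = paste0("ID=", mrna_id, ".", part, k, ";Parent=", mrna_id),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   tab$seqid, tab$source, tab$type,
                   as.integer(tab$start), as.integer(tab$end),
                   tab$strand, tab$attr)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Intron lengths of a gene model
#'
#' Introns are the gaps between consecutive exons of the (single-isoform)
#' model; a two-exon gene with exons 100-199 and 300-399 has one intron of
#' 100 bp.
#'
#' @param model one element of an `aqp_gene_models` list
#' @return integer vector of intron lengths (possibly empty)
#' @export
gene_introns <- function(model) {
  ex <- model$exons
  if (is.null(ex) || nrow(ex) < 2L) return(integer(0))
  as.integer(ex[-1L, "start"] - ex[-nrow(ex), "end"] - 1L)
}

#' @export
print.aqp_gene_models <- function(x, ...) {
  cat("aqp_gene_models:", length(x), "gene model(s)\n")
  for (m in utils::head(x, 5)) {
    cat(sprintf("  %s %s:%d-%d(%s) exons=%d\n", m$id, m$seqid,
                m$start, m$end, m$strand, nrow(m$exons)))
  }
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}
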