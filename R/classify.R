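# Family classification: pairwise percent similarity, subfamily/subgroup
# assignment against a labelled reference panel, neighbor-joining tree
# support, and systematic-name assignment.

#' Percent similarity of two protein sequences
#'
#' Global alignment (BLOSUM62, affine gaps) followed by
#' `100 * positive-scoring aligned pairs / alignment length`, where the
#' alignment length excludes terminal gap columns and a pair is
#' positive-scoring when both residues are aligned and their substitution
#' score is strictly positive.
#'
#' @param a,b protein sequences (nonempty character scalars)
#' @return percent similarity in `[0, 100]`
#' @export
#' @examples
#' pairwise_similarity("ACDEFG", "ACDEFG") # 100
pairwise_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  pa <- aqp_align(a, b)
  qa <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  both <- qa != "-" & sa != "-"
  inner <- which(both)
  if (!length(inner)) return(0)
  keep <- seq.int(min(inner), max(inner))  # drop terminal gap columns
  qa <- qa[keep]; sa <- sa[keep]
  mat <- blosum62()
  aligned <- qa != "-" & sa != "-"
  pos <- sum(aligned & mat[cbind(match(qa, rownames(mat)),
                                 match(sa, colnames(mat)))] > 0,
             na.rm = TRUE)
  100 * pos / length(keep)
}

#' Pairwise similarity matrix
#'
#' @param seqs named character vector of protein sequences
#' @return symmetric matrix of percent similarities with a 100 diagonal
#' @export
similarity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- pairwise_similarity(seqs[[i]], seqs[[j]])
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

#' Parse a labelled reference panel from FASTA headers
#'
#' Panel headers encode labels as `>HbTIP2;1 subfamily=TIP subgroup=TIP2`.
#'
#' @param path path to the panel FASTA
#' @return list with `seqs` (named character) and `labels` (data.frame
#'   `id`, `subfamily`, `subgroup`)
#' @export
read_reference_panel <- function(path) {
  seqs <- read_fasta(path)
  headers <- attr(seqs, "headers")
  get_tag <- function(h, tag) {
    m <- regmatches(h, regexpr(paste0(tag, "=\\S+"), h))
    if (length(m)) sub(paste0(tag, "="), "", m) else NA_character_
  }
  labels <- data.frame(
    id = names(seqs),
    subfamily = vapply(headers, get_tag, "", tag = "subfamily"),
    subgroup = vapply(headers, get_tag, "", tag = "subgroup"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (anyNA(labels$subfamily)) {
    stop("panel headers must carry subfamily= labels")
  }
  list(seqs = seqs, labels = labels)
}

#' Assign a query protein to a subfamily and subgroup
#'
#' Nearest-reference classification: the query takes the labels of the
#' panel reference with maximal percent similarity. Ties are broken by a
#' subgroup vote among the top three references, then by lexicographic
#' reference id. Queries whose best similarity falls below the floor are
#' returned as unclassified.
#'
#' @param query protein sequence
#' @param panel a labelled panel as from [read_reference_panel()] (list
#'   with `seqs` and `labels`)
#' @param floor percent-similarity floor below which the query is
#'   unclassified
#' @return one-row data.frame: `subfamily`, `subgroup`, `nearest`,
#'   `similarity`, `margin` (similarity gap to the best other-subfamily
#'   reference, 0 when no other subfamily is present)
#' @export
assign_subfamily <- function(query, panel, floor = 25) {
  sims <- vapply(panel$seqs, function(s) pairwise_similarity(query, s),
                 numeric(1))
  ord <- order(-sims, panel$labels$id)
  best <- ord[1L]
  if (sims[best] < floor) {
    return(data.frame(subfamily = "unclassified", subgroup = NA_character_,
                      nearest = NA_character_, similarity = sims[best],
                      margin = NA_real_, stringsAsFactors = FALSE))
  }
  tied <- which(abs(sims - sims[best]) < 1e-9)
  if (length(tied) > 1L) {
    top3 <- ord[seq_len(min(3L, length(ord)))]
    vote <- table(panel$labels$subgroup[top3])
    winners <- names(vote)[vote == max(vote)]
    cand <- tied[panel$labels$subgroup[tied] %in% winners]
    if (!length(cand)) cand <- tied
    best <- cand[order(panel$labels$id[cand])][1L]
  }
  sf <- panel$labels$subfamily[best]
  other <- panel$labels$subfamily != sf
  margin <- if (any(other)) sims[best] - max(sims[other]) else 0
  data.frame(subfamily = sf, subgroup = panel$labels$subgroup[best],
             nearest = panel$labels$id[best], similarity = sims[best],
             margin = margin, stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration. Negative branch lengths are
#' clamped to zero with the deficit shifted to the sister edge, preserving
#' the joined pair's total length. On additive distance matrices the tree
#' reproduces all pairwise path lengths exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and >= 3 taxa
#'   (row/column names are the taxon labels)
#' @return an unrooted `phylo` tree (ape)
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  quote_label <- function(x) {
    if (grepl("[ ;,():\\[\\]']", x)) {
      paste0("'", gsub("'", "_", x), "'")
    } else x
  }
  nodes <- vapply(labels, quote_label, character(1))

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  fmt <- function(x) sprintf("%.12g", x)

  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    l <- clamp_pair(li, lj)
    new_node <- paste0("(", nodes[i], ":", fmt(l[1]), ",",
                       nodes[j], ":", fmt(l[2]), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  newick <- paste0("(", nodes[1], ":", fmt(lens[1]), ",",
                   nodes[2], ":", fmt(lens[2]), ",",
                   nodes[3], ":", fmt(lens[3]), ");")
  ape::read.tree(text = newick)
}

#' Assign systematic names from subfamily/subgroup assignments
#'
#' Names follow the `<prefix><subgroup>;<index>` convention. Within a
#' subgroup, indices are ordered by ortholog hint first (the numeric
#' suffix of the hinted ortholog name), then by similarity rank, then by
#' query id.
#'
#' @param assignments data.frame with `id`, `subfamily`, `subgroup` and
#'   optionally `similarity` (unclassified rows have subfamily
#'   `"unclassified"`)
#' @param hints optional named character vector: query id -> ortholog name
#'   (e.g. `"HbTIP2;1"`) used to order indices
#' @param prefix species prefix for the names
#' @return named character vector query id -> systematic name
#'   (NA for unclassified queries, which keep their raw id)
#' @export
assign_systematic_names <- function(assignments, hints = NULL,
                                    prefix = "") {
  out <- setNames(rep(NA_character_, nrow(assignments)), assignments$id)
  classified <- assignments[assignments$subfamily != "unclassified", ,
                            drop = FALSE]
  hint_index <- function(id) {
    h <- if (!is.null(hints) && id %in% names(hints)) hints[[id]] else NA
    if (is.na(h)) return(Inf)
    suf <- suppressWarnings(as.numeric(sub("^.*;", "", h)))
    if (is.na(suf)) Inf else suf
  }
  for (sg in unique(classified$subgroup)) {
    rows <- classified[classified$subgroup == sg, , drop = FALSE]
    hi <- vapply(rows$id, hint_index, numeric(1))
    simrank <- if ("similarity" %in% names(rows)) -rows$similarity else
      rep(0, nrow(rows))
    ord <- order(hi, simrank, rows$id)
    out[rows$id[ord]] <- paste0(prefix, sg, ";", seq_len(nrow(rows)))
  }
  out
}
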