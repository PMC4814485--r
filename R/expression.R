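# FPKM expression summarization: normalization, expressed calls,
# subfamily shares and fold ratios, duplicate-pair divergence, and the
# log2 heatmap matrix.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (eff_len * total_mapped)`. The effective length is
#' the mapping target length (the CDS, when reads are mapped to coding
#' sequences); the total is the library-wide mapped-fragment count.
#'
#' @param count mapped-fragment count(s), >= 0
#' @param eff_len effective length(s) in bp, > 0
#' @param total_mapped library-wide mapped fragments, > 0
#' @return FPKM value(s)
#' @export
#' @examples
#' fpkm(10, 1000, 1e6) # 10
fpkm <- function(count, eff_len, total_mapped) {
  if (any(eff_len <= 0)) stop("effective length must be positive")
  if (any(total_mapped <= 0)) stop("total mapped fragments must be positive")
  if (any(count < 0)) stop("counts must be nonnegative")
  count * 1e9 / (eff_len * total_mapped)
}

#' Expressed call from a mapped-fragment count
#'
#' A gene is counted as expressed when more than one fragment maps to it
#' (count >= `min_fragments`, default 2).
#'
#' @param count mapped-fragment count(s)
#' @param min_fragments minimum count for an expressed call
#' @return logical vector
#' @export
call_expressed <- function(count, min_fragments = 2L) {
  if (any(count < 0)) stop("counts must be nonnegative")
  count >= min_fragments
}

#' Build an expression matrix object
#'
#' @param fpkm_matrix numeric gene-by-tissue FPKM matrix (named dims)
#' @param subfamily named character vector: gene -> subfamily label
#' @param expressed optional logical gene-by-tissue matrix of expressed
#'   calls
#' @return an `aqp_expr` list
#' @export
expression_matrix <- function(fpkm_matrix, subfamily, expressed = NULL) {
  if (any(fpkm_matrix < 0)) stop("FPKM values must be nonnegative")
  genes <- rownames(fpkm_matrix)
  if (is.null(genes)) stop("FPKM matrix must have gene row names")
  if (!all(genes %in% names(subfamily))) {
    stop("every gene needs a subfamily label")
  }
  structure(list(fpkm = fpkm_matrix,
                 subfamily = subfamily[genes],
                 expressed = expressed),
            class = "aqp_expr")
}

#' Per-tissue subfamily totals, member shares and fold ratios
#'
#' For every tissue: the summed FPKM of each subfamily, each member's
#' percent share of its subfamily total (undefined over a zero total), and
#' the pairwise fold ratio between subfamily totals (NA when the
#' denominator subfamily total is zero).
#'
#' @param expr an [expression_matrix()] object
#' @return list with `totals` (subfamily-by-tissue matrix), `shares`
#'   (data.frame `tissue`, `gene`, `subfamily`, `share_pct`) and `folds`
#'   (data.frame `tissue`, `numerator`, `denominator`, `fold`)
#' @export
subfamily_shares <- function(expr) {
  stopifnot(inherits(expr, "aqp_expr"))
  f <- expr$fpkm
  subs <- sort(unique(expr$subfamily))
  tissues <- colnames(f)
  totals <- vapply(tissues, function(tis) {
    vapply(subs, function(sf) {
      sum(f[expr$subfamily == sf, tis])
    }, numeric(1))
  }, numeric(length(subs)))
  totals <- matrix(totals, nrow = length(subs),
                   dimnames = list(subs, tissues))

  shares <- do.call(rbind, lapply(tissues, function(tis) {
    data.frame(tissue = tis, gene = rownames(f),
               subfamily = unname(expr$subfamily),
               share_pct = vapply(seq_len(nrow(f)), function(i) {
                 tot <- totals[expr$subfamily[i], tis]
                 if (tot > 0) 100 * f[i, tis] / tot else NA_real_
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))

  folds <- do.call(rbind, lapply(tissues, function(tis) {
    grid <- expand.grid(numerator = subs, denominator = subs,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$numerator != grid$denominator, , drop = FALSE]
    grid$tissue <- tis
    grid$fold <- vapply(seq_len(nrow(grid)), function(k) {
      den <- totals[grid$denominator[k], tis]
      if (den > 0) totals[grid$numerator[k], tis] / den else NA_real_
    }, numeric(1))
    grid[, c("tissue", "numerator", "denominator", "fold")]
  }))
  list(totals = totals, shares = shares, folds = folds)
}

#' Expression divergence of a duplicate pair
#'
#' Per tissue, `log2((FPKM_a + pseudocount) / (FPKM_b + pseudocount))`,
#' with a preference-switch flag when the ratio changes sign across
#' tissues.
#'
#' @param a,b gene names, both present in `expr`
#' @param expr an [expression_matrix()] object
#' @param pseudocount added to both FPKM values before the ratio (> 0)
#' @return list with `log2_ratio` (named by tissue) and `switch`
#' @export
pair_divergence <- function(a, b, expr, pseudocount = 1) {
  stopifnot(inherits(expr, "aqp_expr"), pseudocount > 0)
  for (g in c(a, b)) {
    if (!g %in% rownames(expr$fpkm)) {
      stop("gene not in expression matrix: ", g)
    }
  }
  ratio <- log2((expr$fpkm[a, ] + pseudocount) /
                (expr$fpkm[b, ] + pseudocount))
  list(log2_ratio = ratio,
       switch = any(ratio > 0) && any(ratio < 0))
}

#' Log2 heatmap matrix
#'
#' `log2(FPKM + pseudocount)` with rows ordered by subfamily, then gene
#' name.
#'
#' @param expr an [expression_matrix()] object
#' @param pseudocount added before the log (> 0)
#' @return numeric matrix
#' @export
heatmap_matrix <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "aqp_expr"), pseudocount > 0)
  ord <- order(expr$subfamily, rownames(expr$fpkm))
  log2(expr$fpkm[ord, , drop = FALSE] + pseudocount)
}
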