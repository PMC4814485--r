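# Comparative analysis: best-hit ortholog mapping, duplicate-pair typing,
# species-by-subgroup count matrices, and ancestral family-size
# reconstruction.

#' Best-hit ortholog table
#'
#' For every query and every target species panel, records the
#' maximal-similarity target at or above the floor (absent otherwise).
#' Ties are broken deterministically by target id, so the table is stable
#' under permutation of panel order.
#'
#' @param queries named character vector of query protein sequences
#' @param panels named list (by species) of named character vectors of
#'   target sequences
#' @param min_similarity percent-similarity floor for a best-hit call
#' @return data.frame `query`, `species`, `best_hit`, `similarity`
#'   (at most one row per query/species; queries below the floor have no
#'   row)
#' @export
best_hit_table <- function(queries, panels, min_similarity = 40) {
  rows <- list()
  for (qi in seq_along(queries)) {
    for (sp in sort(names(panels))) {
      panel <- panels[[sp]]
      sims <- vapply(panel, function(s) {
        pairwise_similarity(queries[[qi]], s)
      }, numeric(1))
      ord <- order(-sims, names(panel))
      if (sims[ord[1]] >= min_similarity) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = names(queries)[qi], species = sp,
          best_hit = names(panel)[ord[1]], similarity = sims[ord[1]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query = character(0), species = character(0),
                      best_hit = character(0), similarity = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Classify a duplicate gene pair
#'
#' Tandem duplicates sit on the same scaffold, in the same orientation
#' (foot-to-head order), with no other family gene in between; pairs on
#' different chromosomes are dispersed; everything else is a
#' whole-genome-duplication candidate. The call is symmetric in its
#' arguments.
#'
#' @param a,b gene names, both present in `inventory`
#' @param inventory inventory data.frame (as from
#'   `load_fixture("table2_inventory")`) with `name`, `scaffold`,
#'   `chromosome`, `strand`, `identified_start`, `identified_end`
#' @return list with `genes`, `type` (`tandem`, `dispersed` or
#'   `wgd-candidate`) and `evidence`
#' @export
classify_duplicate_pair <- function(a, b, inventory) {
  if (identical(a, b)) stop("the two genes must differ")
  row_of <- function(g) {
    i <- which(inventory$name == g)
    if (!length(i)) stop("gene not in inventory: ", g)
    inventory[i[1], , drop = FALSE]
  }
  ra <- row_of(a); rb <- row_of(b)
  midpoint <- function(r) (r$identified_start + r$identified_end) / 2

  same_scaffold <- ra$scaffold == rb$scaffold
  same_strand <- ra$strand == rb$strand
  intervening <- FALSE
  if (same_scaffold) {
    lo <- min(midpoint(ra), midpoint(rb))
    hi <- max(midpoint(ra), midpoint(rb))
    others <- inventory[inventory$scaffold == ra$scaffold &
                          !(inventory$name %in% c(a, b)), , drop = FALSE]
    if (nrow(others)) {
      mids <- (others$identified_start + others$identified_end) / 2
      intervening <- any(mids > lo & mids < hi)
    }
  }
  type <- if (same_scaffold && same_strand && !intervening) {
    "tandem"
  } else if (ra$chromosome != rb$chromosome) {
    "dispersed"
  } else {
    "wgd-candidate"
  }
  list(genes = sort(c(a, b)), type = type,
       evidence = list(scaffolds = c(ra$scaffold, rb$scaffold),
                       strands = c(ra$strand, rb$strand),
                       chromosomes = c(ra$chromosome, rb$chromosome),
                       adjacent = same_scaffold && !intervening))
}

#' Species-by-subgroup count matrix
#'
#' @param assignments data.frame with `species` and `subgroup` columns,
#'   one row per gene
#' @return integer matrix (species rows, subgroup columns) with per-species
#'   totals in the `"totals"` attribute
#' @export
subgroup_count_matrix <- function(assignments) {
  if (nrow(assignments) == 0L) {
    m <- matrix(integer(0), 0, 0)
    attr(m, "totals") <- integer(0)
    return(m)
  }
  tab <- table(assignments$species, assignments$subgroup)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  attr(m, "totals") <- rowSums(m)
  m
}

#' Ancestral family-size reconstruction
#'
#' Per-subgroup bookkeeping with an outgroup presence vote: a subgroup is
#' ancestral when it is present in the outgroup or in at least two ingroup
#' species. Its ancestral count is the maximum ingroup count after
#' collapsing annotated lineage-specific duplicate pairs (each pair counts
#' once) and excluding annotated pseudogenes.
#'
#' @param matrix species-by-subgroup count matrix
#'   (see [subgroup_count_matrix()])
#' @param outgroup species (row) name used for the presence vote
#' @param pairs optional data.frame `species`, `subgroup`: each row
#'   collapses one annotated duplicate pair in that species/subgroup
#' @param pseudogenes optional data.frame `species`, `subgroup`: each row
#'   removes one annotated pseudogene
#' @return list with `per_subgroup` (named integer) and `total`
#' @export
ancestral_counts <- function(matrix, outgroup, pairs = NULL,
                             pseudogenes = NULL) {
  if (!outgroup %in% rownames(matrix)) {
    stop("outgroup '", outgroup, "' is not a row of the count matrix")
  }
  adj <- matrix
  subtract <- function(adj, ann) {
    if (is.null(ann) || nrow(ann) == 0L) return(adj)
    for (i in seq_len(nrow(ann))) {
      sp <- ann$species[i]; sg <- ann$subgroup[i]
      if (sp %in% rownames(adj) && sg %in% colnames(adj)) {
        adj[sp, sg] <- max(adj[sp, sg] - 1L, 0L)
      }
    }
    adj
  }
  adj <- subtract(adj, pairs)
  adj <- subtract(adj, pseudogenes)

  ingroup <- setdiff(rownames(adj), outgroup)
  per <- vapply(colnames(adj), function(sg) {
    present <- adj[outgroup, sg] > 0L ||
      sum(adj[ingroup, sg] > 0L) >= 2L
    if (!present) return(0L)
    as.integer(max(adj[ingroup, sg]))
  }, integer(1))
  list(per_subgroup = per, total = sum(per))
}
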