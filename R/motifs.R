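# Structure-anchored residue extraction: queries are globally aligned to
# the reference backbone (BLOSUM62, affine gaps: open 10, extend 0.5) and
# residues are read off at the annotated columns.

.GAP_OPEN <- 10
.GAP_EXT <- 0.5

aqp_align <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = blosum62(),
                                gapOpening = .GAP_OPEN,
                                gapExtension = .GAP_EXT)
}

#' Map a query protein onto the reference topology
#'
#' Globally aligns `query` to the reference backbone and returns, for every
#' reference column, the aligned query index (NA where the query has a
#' gap). Queries that do not look MIP-like (alignment score at or below the
#' relatedness floor) are rejected.
#'
#' @param query protein sequence (character scalar, length >= 100)
#' @param topology a [default_topology()] object
#' @param score_floor minimum global alignment score for a MIP-like call
#' @return integer vector of length `topology$length` (query index or NA),
#'   with the alignment score in the `"score"` attribute
#' @export
map_to_reference <- function(query, topology = default_topology(),
                             score_floor = 0) {
  query <- toupper(query)
  if (nchar(query) < 100L) {
    stop("query too short (", nchar(query), " residues; need >= 100)")
  }
  pa <- aqp_align(query, topology$reference)
  if (score(pa) <= score_floor) {
    stop("not MIP-like: alignment score ", round(score(pa), 1),
         " is at or below the relatedness floor (", score_floor, ")")
  }
  qa <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  posmap <- rep(NA_integer_, topology$length)
  qpos <- 0L; rpos <- 0L
  for (i in seq_along(qa)) {
    if (qa[i] != "-") qpos <- qpos + 1L
    if (sa[i] != "-") {
      rpos <- rpos + 1L
      if (qa[i] != "-") posmap[rpos] <- qpos
    }
  }
  attr(posmap, "score") <- score(pa)
  posmap
}

#' Extract the dual NPA motifs and their spacing
#'
#' Searches a +/- 10-column window around each annotated motif column for an
#' x-P-x triplet, preferring asparagine, then serine, at the first position,
#' and the candidate closest to the annotated column on ties. The literal
#' triplet is reported (canonical NPA or variants such as NPV, NPS, NPT,
#' NPL, SPI). Spacing counts residues strictly between the two motif start
#' positions.
#'
#' @param query protein sequence
#' @param posmap position map from [map_to_reference()]
#' @param topology the topology the map was built against
#' @param window half-width of the search window, in alignment columns
#' @return list with `npa_lb`, `npa_le` (triplet strings or the missing
#'   marker), `lb_start`, `le_start` (query indices or NA) and
#'   `npa_spacing` (residue count or NA)
#' @export
extract_npa <- function(query, posmap, topology = default_topology(),
                        window = 10L) {
  query <- toupper(query)
  chars <- seq_chars(query)
  find_motif <- function(col) {
    cols <- max(1L, col - window):min(topology$length, col + window)
    mapped <- posmap[cols]
    mapped <- mapped[!is.na(mapped)]
    if (!length(mapped)) return(list(triplet = MISSING_RESIDUE, start = NA))
    anchor <- if (!is.na(posmap[col])) posmap[col] else
      as.integer(round(mean(range(mapped))))
    lo <- max(1L, min(mapped)); hi <- min(length(chars) - 2L, max(mapped))
    if (hi < lo) return(list(triplet = MISSING_RESIDUE, start = NA))
    cand <- lo:hi
    cand <- cand[chars[cand + 1L] == "P"]
    if (!length(cand)) return(list(triplet = MISSING_RESIDUE, start = NA))
    pref <- ifelse(chars[cand] == "N", 0L, ifelse(chars[cand] == "S", 1L, 2L))
    ord <- order(pref, abs(cand - anchor), cand)
    best <- cand[ord[1L]]
    list(triplet = paste(chars[best + 0:2], collapse = ""), start = best)
  }
  lb <- find_motif(topology$npa_lb)
  le <- find_motif(topology$npa_le)
  spacing <- if (is.na(lb$start) || is.na(le$start)) NA_integer_ else
    as.integer(le$start - lb$start - 1L)
  list(npa_lb = lb$triplet, npa_le = le$triplet,
       lb_start = lb$start, le_start = le$start, npa_spacing = spacing)
}

#' Extract query residues at a set of annotated reference columns
#'
#' @param query protein sequence
#' @param posmap position map from [map_to_reference()]
#' @param position_set integer vector of annotated reference columns
#' @return character vector of residues, with the missing marker (".")
#'   where the query is gapped
#' @export
extract_positions <- function(query, posmap, position_set) {
  chars <- seq_chars(toupper(query))
  idx <- posmap[position_set]
  out <- ifelse(is.na(idx), MISSING_RESIDUE, chars[ifelse(is.na(idx), 1L, idx)])
  names(out) <- names(position_set)
  out
}

#' Full residue annotation of one protein
#'
#' Convenience wrapper: maps the query to the reference and extracts the
#' NPA motifs and spacing, the ar/R filter (H2, H5, LE1, LE2), Froger's
#' positions (P1-P5) and the nine SDP residues of every substrate class.
#'
#' @param query protein sequence
#' @param topology a [default_topology()] object
#' @return an `aqp_annotation` list with `npa_lb`, `npa_le`, `npa_spacing`,
#'   `arR`, `froger` and `sdp` (named list, one 9-residue vector per
#'   substrate class)
#' @export
annotate_protein <- function(query, topology = default_topology()) {
  posmap <- map_to_reference(query, topology)
  npa <- extract_npa(query, posmap, topology)
  structure(list(
    npa_lb = npa$npa_lb, npa_le = npa$npa_le, npa_spacing = npa$npa_spacing,
    arR = extract_positions(query, posmap, topology$arR),
    froger = extract_positions(query, posmap, topology$froger),
    sdp = lapply(topology$sdp, function(cols) {
      extract_positions(query, posmap, cols)
    })
  ), class = "aqp_annotation")
}

#' @export
print.aqp_annotation <- function(x, ...) {
  cat("aqp_annotation\n")
  cat("  NPA:", x$npa_lb, "/", x$npa_le, " spacing:", x$npa_spacing, "\n")
  cat("  ar/R:", paste(x$arR, collapse = "-"),
      " Froger:", paste(x$froger, collapse = "-"), "\n")
  invisible(x)
}

# Kyte-Doolittle hydropathy values
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Transmembrane segments by windowed hydropathy
#'
#' A simple hydropathy-based transmembrane finder: maximal runs of window
#' centers whose Kyte-Doolittle windowed mean exceeds the threshold, with
#' runs separated by fewer than `merge_gap` positions merged. This is a
#' heuristic topology substitute, not a full topology predictor.
#'
#' @param query protein sequence
#' @param window sliding window width (odd; default 19)
#' @param threshold windowed-mean hydropathy cutoff (default 1.6)
#' @param merge_gap runs closer than this many positions are merged
#' @return two-column integer matrix (`start`, `end`) of segment centers;
#'   zero rows when no window passes
#' @export
hydropathy_tm_segments <- function(query, window = 19L, threshold = 1.6,
                                   merge_gap = 3L) {
  chars <- seq_chars(toupper(query))
  n <- length(chars)
  if (n < window) stop("sequence shorter than the hydropathy window")
  vals <- .KD[chars]
  if (anyNA(vals)) {
    stop("nonstandard residue: ",
         paste(unique(chars[is.na(vals)]), collapse = ", "))
  }
  cs <- cumsum(c(0, vals))
  centers <- seq.int((window + 1L) %/% 2L, n - window %/% 2L)
  means <- (cs[centers + window %/% 2L + 1L] -
            cs[centers - (window - 1L) %/% 2L]) / window
  above <- centers[means > threshold]
  if (!length(above)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  breaks <- which(diff(above) >= merge_gap)
  starts <- above[c(1L, breaks + 1L)]
  ends <- above[c(breaks, length(above))]
  cbind(start = starts, end = ends)
}

# average residue masses (Da)
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

# EMBOSS pKa set
.PKA <- list(nterm = 8.6, cterm = 3.6,
             pos = c(K = 10.8, R = 12.5, H = 6.5),
             neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

protein_net_charge <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - .PKA$nterm)) +
    sum(counts[names(.PKA$pos)] / (1 + 10^(ph - .PKA$pos)), na.rm = TRUE)
  neg <- 1 / (1 + 10^(.PKA$cterm - ph)) +
    sum(counts[names(.PKA$neg)] / (1 + 10^(.PKA$neg - ph)), na.rm = TRUE)
  pos - neg
}

#' Molecular weight and isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' the isoelectric point is found by bisection of the Henderson-Hasselbalch
#' net charge using the EMBOSS pKa set (the charge is strictly decreasing
#' in pH, so the root is unique).
#'
#' @param query protein sequence of standard residues
#' @param tol bisection tolerance in pH units
#' @return list with `mw` (Da), `mw_kda` and `pi`
#' @export
#' @examples
#' physicochem("GG")$mw # 132.12
physicochem <- function(query, tol = 1e-4) {
  chars <- seq_chars(toupper(query))
  if (!length(chars)) stop("empty sequence")
  bad <- setdiff(unique(chars), names(.AA_MASS))
  if (length(bad)) {
    stop("nonstandard residue: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(chars, levels = names(.AA_MASS)))
  counts <- setNames(as.numeric(counts), names(.AA_MASS))
  mw <- sum(counts * .AA_MASS) + .WATER_MASS

  lo <- 0; hi <- 14
  stopifnot(protein_net_charge(counts, lo) > 0,
            protein_net_charge(counts, hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  list(mw = mw, mw_kda = mw / 1000, pi = (lo + hi) / 2)
}
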