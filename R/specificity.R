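# Rule-based substrate specificity prediction from extracted residues:
# degenerate SDP profile matching, Froger AqpZ/GlpF discrimination, the
# ar/R water-permeability call, and the NPA-spacing silicon rule.

#' Degenerate SDP profile for one substrate class
#'
#' @param substrate substrate class name (one of `NH3`, `boric acid`,
#'   `CO2`, `H2O2`, `silicic acid`, `urea`)
#' @param allowed list of 9 nonempty character vectors: the residues
#'   allowed at SDP1-SDP9
#' @return an `sdp_profile` object
#' @export
sdp_profile <- function(substrate, allowed) {
  if (length(allowed) != 9L) stop("an SDP profile has exactly 9 positions")
  if (any(lengths(allowed) == 0L)) stop("every allowed set must be nonempty")
  structure(list(substrate = substrate,
                 allowed = lapply(allowed, as.character)),
            class = "sdp_profile")
}

#' @export
print.sdp_profile <- function(x, ...) {
  cat("sdp_profile:", x$substrate, "\n  ",
      paste(vapply(x$allowed, paste, "", collapse = "/"), collapse = " "),
      "\n")
  invisible(x)
}

#' Match a nine-residue SDP vector against a degenerate profile
#'
#' @param vector9 character vector of 9 residues (the missing marker "."
#'   or NA is allowed and always mismatches)
#' @param profile an [sdp_profile()]
#' @return integer vector of mismatching positions (empty on a full match)
#' @export
#' @examples
#' urea <- load_fixture("table4_profiles")[["urea"]]
#' match_sdp(c("H","P","F","F","L","P","G","G","N"), urea)
match_sdp <- function(vector9, profile) {
  stopifnot(inherits(profile, "sdp_profile"))
  if (length(vector9) != 9L) {
    stop("SDP vector must have 9 entries, got ", length(vector9))
  }
  hit <- vapply(seq_len(9L), function(i) {
    v <- vector9[i]
    !is.na(v) && v != MISSING_RESIDUE && v %in% profile$allowed[[i]]
  }, logical(1))
  which(!hit)
}

#' Predict substrates from a residue annotation
#'
#' A substrate is predicted when the protein's SDP vector for that class
#' matches the class profile with at most `max_mismatch` deviations
#' (default 0: single-position deviations are "novel SDPs", not matches).
#' Near misses (one mismatch) are reported separately, and the full
#' per-substrate mismatch table is returned for inspection.
#'
#' @param annotation an [annotate_protein()] result (or any list with an
#'   `sdp` element mapping substrate class to a 9-residue vector)
#' @param profiles named list of [sdp_profile()]s
#'   (default: the packaged typical-transporter profiles)
#' @param max_mismatch maximum allowed mismatches for a predicted substrate
#' @return list with `substrates` (character), `near_miss` (named list of
#'   mismatch positions for substrates at exactly one mismatch),
#'   `mismatch_counts` (named integer) and `mismatch_positions`
#'   (named list)
#' @export
predict_substrates <- function(annotation,
                               profiles = load_fixture("table4_profiles"),
                               max_mismatch = 0L) {
  pos <- lapply(profiles, function(pr) {
    v <- annotation$sdp[[pr$substrate]]
    if (is.null(v)) {
      stop("annotation has no SDP vector for substrate class '",
           pr$substrate, "'")
    }
    match_sdp(v, pr)
  })
  counts <- vapply(pos, length, integer(1))
  list(substrates = names(profiles)[counts <= max_mismatch],
       near_miss = pos[counts == 1L],
       mismatch_counts = counts,
       mismatch_positions = pos)
}

#' Froger exemplar residues
#'
#' The P1-P5 residues of the water-selective exemplar AqpZ and the
#' glycerol-transporting exemplar GlpF.
#' @return list with `aqpz` and `glpf` five-residue vectors
#' @export
froger_exemplars <- function() {
  list(aqpz = c("A", "S", "A", "F", "W"),
       glpf = c("Y", "D", "K", "P", "L"))
}

# fallback chemical signature of aquaglyceroporins at each Froger position
.glpf_chemical <- function(p, i) {
  switch(i,
    p %in% c("F", "W", "Y"),            # P1 aromatic
    p %in% c("D", "E"),                 # P2 acidic
    p %in% c("K", "R", "H"),            # P3 basic
    p == "P",                           # P4 proline
    !(p %in% c("F", "W", "Y"))          # P5 nonaromatic
  )
}

#' Classify Froger's positions as AqpZ-like or GlpF-like
#'
#' Each position is called by exemplar identity first (AqpZ, then GlpF);
#' positions matching neither exemplar fall back to the aquaglyceroporin
#' chemical rule (aromatic P1, acidic P2, basic P3, P at P4, nonaromatic
#' P5), and are "other" if that also fails. The overall class is
#' `aquaporin-like` when all five positions are AqpZ-like,
#' `aquaglyceroporin-like` when all are GlpF-like, and `mixed` otherwise.
#'
#' @param p character vector of 5 residues (P1-P5)
#' @return list with `class` and `positions` (per-position calls)
#' @export
froger_classify <- function(p) {
  if (length(p) != 5L) stop("Froger vector must have 5 entries")
  ex <- froger_exemplars()
  calls <- vapply(seq_len(5L), function(i) {
    if (is.na(p[i]) || p[i] == MISSING_RESIDUE) return("other")
    if (p[i] == ex$aqpz[i]) return("aqpz-like")
    if (p[i] == ex$glpf[i]) return("glpf-like")
    if (.glpf_chemical(p[i], i)) return("glpf-like")
    "other"
  }, character(1))
  names(calls) <- paste0("P", 1:5)
  cls <- if (all(calls == "aqpz-like")) "aquaporin-like"
         else if (all(calls == "glpf-like")) "aquaglyceroporin-like"
         else "mixed"
  list(class = cls, positions = calls)
}

#' Water-permeability call from the ar/R selectivity filter
#'
#' The F-H-T-R filter (as in AqpZ) indicates high water permeability; any
#' other filter is called unknown.
#'
#' @param arR character vector of 4 residues (H2, H5, LE1, LE2)
#' @return `"high"` or `"unknown"`
#' @export
arR_water_call <- function(arR) {
  if (length(arR) != 4L) stop("ar/R vector must have 4 entries")
  if (!anyNA(arR) && identical(unname(arR), c("F", "H", "T", "R"))) {
    "high"
  } else {
    "unknown"
  }
}

#' Silicon-transporter spacing feature
#'
#' A spacing of exactly 108 residues between the two NPA motifs is a
#' feature specific to silicon transporters; a G-S-G-R ar/R filter adds
#' supporting evidence.
#'
#' @param npa_spacing residue count between the motif start positions
#' @param arR optional ar/R vector for the supporting note
#' @return list with `flag` (logical) and `note`
#' @export
silicon_feature <- function(npa_spacing, arR = NULL) {
  if (is.na(npa_spacing)) return(list(flag = FALSE, note = "spacing missing"))
  if (npa_spacing < 0) stop("spacing must be nonnegative")
  flag <- npa_spacing == 108L
  note <- if (!flag) {
    sprintf("spacing %d != 108", as.integer(npa_spacing))
  } else if (!is.null(arR) &&
             identical(unname(arR), c("G", "S", "G", "R"))) {
    "supported by G-S-G-R ar/R"
  } else {
    "108-residue spacing without G-S-G-R ar/R support"
  }
  list(flag = flag, note = note)
}

#' Combined specificity report for one protein
#'
#' Keeps the three evidence channels separate: per-substrate SDP matching,
#' the Froger AqpZ/GlpF class, the ar/R water call, and the silicon
#' spacing flag.
#'
#' @inheritParams predict_substrates
#' @return a `specificity_report` list
#' @export
specificity_report <- function(annotation,
                               profiles = load_fixture("table4_profiles"),
                               max_mismatch = 0L) {
  pred <- predict_substrates(annotation, profiles, max_mismatch)
  structure(list(
    substrates = pred$substrates,
    near_miss = pred$near_miss,
    mismatch_counts = pred$mismatch_counts,
    mismatch_positions = pred$mismatch_positions,
    froger = froger_classify(annotation$froger),
    water_call = arR_water_call(annotation$arR),
    silicon = silicon_feature(annotation$npa_spacing, annotation$arR)
  ), class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("specificity_report\n")
  cat("  substrates:", if (length(x$substrates))
    paste(x$substrates, collapse = ", ") else "(none)", "\n")
  cat("  Froger:", x$froger$class, "| water:", x$water_call,
      "| silicon:", x$silicon$flag, "\n")
  invisible(x)
}
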