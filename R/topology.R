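# Reference topology: a synthetic plant-PIP-like backbone with annotated
# alignment columns. The anchor is built in code (it is NOT a natural
# sequence); its column annotation mirrors the canonical MIP fold: six
# transmembrane helices (TM1-TM6), loops LA-LE, the two NPA half-helix
# motifs on loops B and E, the ar/R constriction (H2, H5, LE1, LE2),
# Froger's positions P1-P5, and one nine-column set of
# specificity-determining positions (SDPs) per substrate class.

.TOPOLOGY_TM <- list(
  TM1 = 12:32, TM2 = 45:65, TM3 = 115:135,
  TM4 = 152:172, TM5 = 182:202, TM6 = 255:275
)

.TOPOLOGY_NPA_LB <- 97L   # motif start column, loop B
.TOPOLOGY_NPA_LE <- 206L  # motif start column, loop E; spacing 206-97-1 = 108

.TOPOLOGY_ARR <- c(H2 = 61L, H5 = 196L, LE1 = 211L, LE2 = 217L)
.TOPOLOGY_FROGER <- c(P1 = 105L, P2 = 221L, P3 = 225L, P4 = 239L, P5 = 240L)

SDP_SUBSTRATES <- c("NH3", "boric acid", "CO2", "H2O2", "silicic acid", "urea")

.TOPOLOGY_SDP <- list(
  "NH3"          = 70:78,
  "boric acid"   = 80:88,
  "CO2"          = 140:148,
  "H2O2"         = 230:238,
  "silicic acid" = 282:290,
  "urea"         = 295:303
)

.TOPOLOGY_LENGTH <- 320L

# hydrophobic filler for TM spans, polar filler for loops/termini
.TM_FILLER   <- c("L", "I", "V", "A", "F", "L", "I", "V", "A", "G")
.LOOP_FILLER <- c("G", "S", "T", "N", "Q", "E", "D", "K", "A", "R")

#' Reference topology for residue extraction
#'
#' Builds the package's structure-anchored reference: a synthetic
#' plant-PIP-like backbone of `r 320` residues with annotated alignment
#' columns for the six transmembrane helices, the dual NPA motifs, the ar/R
#' selectivity filter (H2, H5, LE1, LE2), Froger's positions (P1-P5) and one
#' nine-column SDP set per substrate class. Query proteins are globally
#' aligned to this backbone and residues are read off at the annotated
#' columns.
#'
#' The backbone's own annotated residues are PIP1-like: F-H-T-R ar/R filter,
#' NPA/NPA motifs spaced 108 residues apart, E-S-A-F-W Froger residues, and
#' the typical boric acid / CO2 / H2O2 / urea SDP vectors.
#'
#' @return an object of class `aqp_topology`: a list with elements
#'   `reference` (the backbone sequence), `length`, `tm`, `npa_lb`, `npa_le`
#'   (motif start columns), `arR`, `froger`, `sdp` (annotated columns) and
#'   `annotated` (all annotated single columns, sorted).
#' @export
#' @examples
#' top <- default_topology()
#' nchar(top$reference)
default_topology <- function() {
  res <- rep(.LOOP_FILLER, length.out = .TOPOLOGY_LENGTH)
  for (span in .TOPOLOGY_TM) {
    res[span] <- rep(.TM_FILLER, length.out = length(span))
  }
  plant <- function(cols, letters) {
    stopifnot(length(cols) == length(letters))
    res[cols] <<- letters
  }
  plant(.TOPOLOGY_NPA_LB + 0:2, c("N", "P", "A"))
  plant(.TOPOLOGY_NPA_LE + 0:2, c("N", "P", "A"))
  plant(.TOPOLOGY_ARR, c("F", "H", "T", "R"))
  plant(.TOPOLOGY_FROGER, c("E", "S", "A", "F", "W"))
  plant(.TOPOLOGY_SDP[["boric acid"]], seq_chars("TIHPELLTP"))
  plant(.TOPOLOGY_SDP[["CO2"]], seq_chars("IMCAIDWDW"))
  plant(.TOPOLOGY_SDP[["H2O2"]], seq_chars("AGVFIHFVP"))
  plant(.TOPOLOGY_SDP[["urea"]], seq_chars("HPFFLPGGN"))

  annotated <- sort(unique(c(
    .TOPOLOGY_NPA_LB + 0:2, .TOPOLOGY_NPA_LE + 0:2,
    unname(.TOPOLOGY_ARR), unname(.TOPOLOGY_FROGER),
    unlist(.TOPOLOGY_SDP, use.names = FALSE)
  )))
  structure(list(
    reference = paste(res, collapse = ""),
    length = .TOPOLOGY_LENGTH,
    tm = .TOPOLOGY_TM,
    npa_lb = .TOPOLOGY_NPA_LB,
    npa_le = .TOPOLOGY_NPA_LE,
    arR = .TOPOLOGY_ARR,
    froger = .TOPOLOGY_FROGER,
    sdp = .TOPOLOGY_SDP,
    annotated = annotated
  ), class = "aqp_topology")
}

#' @export
print.aqp_topology <- function(x, ...) {
  cat("aqp_topology: synthetic MIP backbone,", x$length, "columns\n")
  cat("  NPA motifs at", x$npa_lb, "and", x$npa_le,
      "(spacing", x$npa_le - x$npa_lb - 1L, ")\n")
  cat("  ar/R:", paste(names(x$arR), x$arR, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Planted residue profiles per subgroup, used by the synthetic-data
# generator. Values follow the subfamily-typical patterns of plant AQPs
# (ar/R filter, Froger residues, NPA variants, substrate-typical SDPs).
# Classes absent from a profile keep the backbone residues.
.subgroup_profile <- function(arR, froger, npa = c("NPA", "NPA"), sdp = list()) {
  list(arR = seq_chars(arR), froger = seq_chars(froger), npa = npa,
       sdp = lapply(sdp, seq_chars))
}

SUBGROUP_PROFILES <- list(
  PIP1 = .subgroup_profile("FHTR", "ESAFW", sdp = list(
    "urea" = "HPFFLPGGN", "boric acid" = "TIHPELLTP",
    "CO2" = "LICAIDWDW", "H2O2" = "AGVFIHFVP")),
  PIP2 = .subgroup_profile("FHTR", "QSAFW", sdp = list(
    "urea" = "HPFFLPGGN", "CO2" = "IMCAVDWDW", "H2O2" = "AGVFIQFVP")),
  TIP1 = .subgroup_profile("HIAV", "TSAYW", sdp = list(
    "urea" = "HPFFLAGSN", "H2O2" = "SALAIHYVP")),
  TIP2 = .subgroup_profile("HIGR", "TSAYW", sdp = list("urea" = "HPFALPGSN")),
  TIP3 = .subgroup_profile("HIAR", "TAAYW", sdp = list("H2O2" = "SALVIHYVP")),
  TIP4 = .subgroup_profile("HIAR", "TSAYW", sdp = list("urea" = "HPLLLAGSN")),
  TIP5 = .subgroup_profile("NVGS", "IAAYW", sdp = list(
    "urea" = "HPFALPGSN", "H2O2" = "SALAIQYVP")),
  NIP1 = .subgroup_profile("WVAR", "FSAYL", sdp = list(
    "NH3" = "FKFTADLET", "urea" = "HPLALPGSN")),
  NIP2 = .subgroup_profile("GSGR", "LTAYI", sdp = list(
    "boric acid" = "VVHPEIIAP", "silicic acid" = "GFVHGNRTK",
    "urea" = "HPTAMPGSN", "H2O2" = "AALLVIYVP")),
  NIP3 = .subgroup_profile("WVAR", "FSAFL", sdp = list("urea" = "HPIALPGSN")),
  NIP4 = .subgroup_profile("WVAR", "FSAYI", sdp = list(
    "urea" = "HPIALPGSN", "H2O2" = "SALLVLYAP")),
  NIP5 = .subgroup_profile("SIAR", "FTAYL", npa = c("NPA", "NPV"), sdp = list(
    "boric acid" = "TIHPELLAP", "H2O2" = "SALVVIYVP", "urea" = "HPIALPGSN")),
  NIP6 = .subgroup_profile("SIAR", "LTAYL", npa = c("NPS", "NPV"), sdp = list(
    "boric acid" = "TIHPELLAP", "urea" = "HPIALPGSN")),
  NIP7 = .subgroup_profile("AVGR", "YSAYI"),
  SIP1 = .subgroup_profile("VLPN", "IAAYW", npa = c("NPT", "NPA")),
  SIP2 = .subgroup_profile("SLGS", "FVAYW", npa = c("NPL", "NPA")),
  XIP1 = .subgroup_profile("IIVR", "MCAFW", npa = c("SPI", "NPA")),
  XIP2 = .subgroup_profile("ITVR", "LCAFW", npa = c("NPV", "NPA"), sdp = list(
    "H2O2" = "AGLAVHFVP"))
)

SUBFAMILIES <- c("PIP", "TIP", "NIP", "SIP", "XIP")

# per-subfamily subgroup composition template (physic nut proportions)
.SUBGROUP_TEMPLATE <- list(
  PIP = c(PIP1 = 4, PIP2 = 5),
  TIP = c(TIP1 = 4, TIP2 = 2, TIP3 = 1, TIP4 = 1, TIP5 = 1),
  NIP = c(NIP1 = 1, NIP2 = 1, NIP3 = 2, NIP4 = 1, NIP5 = 1, NIP6 = 1, NIP7 = 1),
  SIP = c(SIP1 = 3, SIP2 = 1),
  XIP = c(XIP1 = 1, XIP2 = 1)
)

# per-subgroup intron-count template (subfamily default, subgroup overrides)
.INTRON_TEMPLATE <- c(PIP = 3L, TIP = 2L, NIP = 4L, SIP = 0L, XIP = 1L)
.INTRON_OVERRIDE <- c(NIP5 = 3L, SIP2 = 2L, XIP2 = 2L)

intron_count_for <- function(subfamily, subgroup) {
  if (subgroup %in% names(.INTRON_OVERRIDE)) {
    return(unname(.INTRON_OVERRIDE[subgroup]))
  }
  unname(.INTRON_TEMPLATE[subfamily])
}
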