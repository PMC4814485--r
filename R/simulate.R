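# Seeded synthetic-data generators: AQP-like protein families built on the
# reference backbone with subfamily-specific residues planted at the
# annotated columns, back-translated CDS with subfamily-typical intron
# structures, and tissue count tables drawn around known FPKM ground truth.

#' Simulation configuration
#'
#' @param n_genes named integer vector of genes per subfamily (default
#'   mirrors the physic nut composition: 9 PIP, 9 TIP, 8 NIP, 4 SIP, 2 XIP)
#' @param substitution_rate per-site substitution probability outside the
#'   annotated columns, in `[0, 1)`
#' @param indel_rate per-site indel probability outside the annotated
#'   columns, in `[0, 1)`
#' @param tissues tissue names for the expression ground truth
#' @param mean_library_size library-wide mapped fragments per tissue
#' @param rng_seed integer seed; all generators are pure functions of
#'   (config, seed)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_genes = c(PIP = 9L, TIP = 9L, NIP = 8L,
                                   SIP = 4L, XIP = 2L),
                       substitution_rate = 0.05,
                       indel_rate = 0,
                       tissues = c("root", "leaf", "seed"),
                       mean_library_size = 3e7,
                       rng_seed = 1L) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1) {
    stop("rates must be in [0, 1)")
  }
  if (any(n_genes < 0)) stop("n_genes must be nonnegative")
  if (!all(names(n_genes) %in% SUBFAMILIES)) {
    stop("n_genes names must be subfamilies: ",
         paste(SUBFAMILIES, collapse = ", "))
  }
  structure(list(n_genes = n_genes,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 tissues = tissues,
                 mean_library_size = mean_library_size,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# largest-remainder allocation of n genes over a subgroup template
allocate_subgroups <- function(subfamily, n) {
  template <- .SUBGROUP_TEMPLATE[[subfamily]]
  if (n == 0L) return(character(0))
  quota <- n * template / sum(template)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(quota - base), seq_along(quota))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  rep(names(template), times = base)
}

#' Apply substitutions and indels to a sequence
#'
#' Per-site mutation with a complete edit log. Protected positions (e.g.
#' the annotated reference columns carrying planted residues) receive no
#' substitutions, and indels never fall on or immediately before a
#' protected position, so planted residues survive verbatim (though indels
#' elsewhere still shift their coordinates).
#'
#' @param seq sequence to mutate (character scalar)
#' @param substitution_rate,indel_rate per-site probabilities in `[0, 1)`
#' @param protected integer positions (in `seq` coordinates) to protect
#' @return list with `seq` (mutated sequence) and `log` (data.frame
#'   `pos`, `op`, `from`, `to`; positions in parent coordinates)
#' @export
mutate_copy <- function(seq, substitution_rate = 0, indel_rate = 0,
                        protected = integer(0)) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1) {
    stop("rates must be in [0, 1)")
  }
  chars <- seq_chars(seq)
  n <- length(chars)
  is_protected <- rep(FALSE, n)
  is_protected[protected[protected >= 1 & protected <= n]] <- TRUE

  log_pos <- integer(0); log_op <- character(0)
  log_from <- character(0); log_to <- character(0)
  push <- function(pos, op, from, to) {
    log_pos <<- c(log_pos, pos); log_op <<- c(log_op, op)
    log_from <<- c(log_from, from); log_to <<- c(log_to, to)
  }

  if (substitution_rate > 0) {
    hit <- which(runif(n) < substitution_rate & !is_protected)
    for (i in hit) {
      to <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
      push(i, "sub", chars[i], to)
      chars[i] <- to
    }
  }
  out <- as.list(chars)
  if (indel_rate > 0) {
    hit <- which(runif(n) < indel_rate)
    for (i in hit) {
      if (is_protected[i] || (i < n && is_protected[i + 1L])) next
      if (runif(1) < 0.5) {
        push(i, "del", chars[i], "")
        out[[i]] <- character(0)
      } else {
        ins <- sample(AA_STANDARD, 1L)
        push(i, "ins", "", ins)
        out[[i]] <- c(out[[i]], ins)
      }
    }
  }
  list(seq = paste(unlist(out), collapse = ""),
       log = data.frame(pos = log_pos, op = log_op, from = log_from,
                        to = log_to, stringsAsFactors = FALSE))
}

# fixed back-translation codon table (one codon per residue)
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Back-translate a protein to a CDS
#'
#' Uses a fixed one-codon-per-residue table and appends a TAA stop, so
#' only CDS lengths and reading frames matter downstream (no codon-usage
#' model).
#'
#' @param protein protein sequence
#' @return CDS nucleotide string of length `3 * (nchar(protein) + 1)`
#' @export
back_translate <- function(protein) {
  chars <- seq_chars(toupper(protein))
  bad <- setdiff(unique(chars), names(.CODON))
  if (length(bad)) stop("nonstandard residue: ", paste(bad, collapse = ", "))
  paste0(paste(.CODON[chars], collapse = ""), "TAA")
}

# plant one subgroup's profile onto the backbone; returns residue vector
plant_profile <- function(topology, subgroup) {
  res <- seq_chars(topology$reference)
  prof <- SUBGROUP_PROFILES[[subgroup]]
  res[topology$arR] <- prof$arR
  res[topology$froger] <- prof$froger
  res[topology$npa_lb + 0:2] <- seq_chars(prof$npa[1])
  res[topology$npa_le + 0:2] <- seq_chars(prof$npa[2])
  for (cls in names(prof$sdp)) {
    res[topology$sdp[[cls]]] <- prof$sdp[[cls]]
  }
  res
}

#' Simulate an AQP-like gene family with known planted truth
#'
#' Builds one protein per gene from the reference backbone: the subgroup's
#' typical ar/R filter, Froger residues, NPA variants and substrate-typical
#' SDP vectors are planted at the annotated columns, then substitutions and
#' indels are applied outside them at the configured rates. The CDS is
#' back-translated and laid out on synthetic scaffolds with
#' subfamily-typical intron counts; true FPKM values per tissue follow the
#' subfamily abundance ordering (PIP > TIP > SIP > NIP > XIP). Output is
#' deterministic for a fixed config.
#'
#' @param cfg a [sim_config()]
#' @param topology a [default_topology()]
#' @return list with `proteins` and `cds` (named character vectors),
#'   `models` (an `aqp_gene_models` list), `truth` (the truth table
#'   data.frame: planted residues, intron counts, true FPKM per tissue)
#'   and `cfg`
#' @export
simulate_family <- function(cfg = sim_config(),
                            topology = default_topology()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)

  subgroups <- unlist(lapply(names(cfg$n_genes), function(sf) {
    allocate_subgroups(sf, cfg$n_genes[[sf]])
  }), use.names = FALSE)
  if (!length(subgroups)) stop("empty simulation: no genes requested")
  idx <- stats::ave(seq_along(subgroups), subgroups, FUN = seq_along)
  names_ <- paste0("Sim", subgroups, "-", idx)
  subfam <- substr(subgroups, 1L, 3L)

  base_fpkm <- c(PIP = 120, TIP = 70, SIP = 8, NIP = 3, XIP = 0.8)

  proteins <- character(0); cds <- character(0)
  models <- list()
  truth_rows <- list()
  scaffold_cursor <- 1000L
  for (g in seq_along(names_)) {
    sg <- subgroups[g]; sf <- subfam[g]
    planted <- plant_profile(topology, sg)
    mut <- mutate_copy(paste(planted, collapse = ""),
                       substitution_rate = cfg$substitution_rate,
                       indel_rate = cfg$indel_rate,
                       protected = topology$annotated)
    prot <- mut$seq
    cd <- back_translate(prot)
    proteins[names_[g]] <- prot
    cds[names_[g]] <- cd

    n_introns <- intron_count_for(sf, sg)
    cds_len <- nchar(cd)
    # intron insertion points at codon boundaries, evenly spaced
    cuts <- if (n_introns > 0) {
      3L * floor(cds_len / 3 * seq_len(n_introns) / (n_introns + 1L))
    } else integer(0)
    ilens <- if (n_introns > 0) {
      as.integer(round(runif(n_introns, 70, 500)))
    } else integer(0)

    scaffold <- paste0("simscaffold", (g + 1L) %/% 2L)
    strand <- if (g %% 2L == 1L) "+" else "-"
    gstart <- scaffold_cursor
    exon_lens <- diff(c(0L, cuts, cds_len))
    starts <- integer(0); ends <- integer(0)
    pos <- gstart
    for (k in seq_along(exon_lens)) {
      starts <- c(starts, pos)
      ends <- c(ends, pos + exon_lens[k] - 1L)
      pos <- pos + exon_lens[k] + (if (k <= length(ilens)) ilens[k] else 0L)
    }
    scaffold_cursor <- scaffold_cursor + (pos - gstart) + 2000L
    mat <- cbind(start = starts, end = ends)
    models[[names_[g]]] <- list(
      id = names_[g], seqid = scaffold, strand = strand,
      start = min(starts), end = max(ends), exons = mat, cds = mat)

    fpkm_true <- base_fpkm[[sf]] * rlnorm(1, 0, 0.8) *
      rlnorm(length(cfg$tissues), 0, 0.6)
    row <- data.frame(
      name = names_[g], subfamily = sf, subgroup = sg,
      scaffold = scaffold, strand = strand,
      cds_len = cds_len, intron_count = n_introns,
      arR = paste(planted[topology$arR], collapse = ""),
      froger = paste(planted[topology$froger], collapse = ""),
      npa_lb = paste(planted[topology$npa_lb + 0:2], collapse = ""),
      npa_le = paste(planted[topology$npa_le + 0:2], collapse = ""),
      npa_spacing = topology$npa_le - topology$npa_lb - 1L,
      stringsAsFactors = FALSE)
    for (cls in names(topology$sdp)) {
      row[[paste0("sdp_", gsub(" ", "_", cls))]] <-
        paste(planted[topology$sdp[[cls]]], collapse = "")
    }
    for (ti in seq_along(cfg$tissues)) {
      row[[paste0("fpkm_", cfg$tissues[ti])]] <- fpkm_true[ti]
    }
    truth_rows[[g]] <- row
  }
  truth <- do.call(rbind, truth_rows)
  class(models) <- "aqp_gene_models"
  list(proteins = proteins, cds = cds, models = models,
       truth = truth, cfg = cfg)
}

#' Simulate a tissue count table around known FPKM ground truth
#'
#' Counts are Poisson with mean `FPKM * eff_len * total / 1e9` per tissue;
#' the effective length is the CDS length and the per-tissue totals are the
#' configured library size.
#'
#' @param truth truth table from [simulate_family()]
#' @param cfg the [sim_config()] used (supplies tissues and library size)
#' @param seed RNG seed (defaults to the config seed)
#' @return list with `counts` (gene-by-tissue integer matrix), `totals`
#'   (per-tissue library sizes) and `eff_len` (named by gene)
#' @export
simulate_counts <- function(truth, cfg, seed = cfg$rng_seed) {
  set.seed(seed)
  tissues <- cfg$tissues
  totals <- setNames(rep(cfg$mean_library_size, length(tissues)), tissues)
  counts <- matrix(0L, nrow(truth), length(tissues),
                   dimnames = list(truth$name, tissues))
  for (ti in seq_along(tissues)) {
    mu <- truth[[paste0("fpkm_", tissues[ti])]] * truth$cds_len *
      totals[ti] / 1e9
    counts[, ti] <- rpois(nrow(truth), mu)
  }
  list(counts = counts, totals = totals,
       eff_len = setNames(truth$cds_len, truth$name))
}

#' Write a simulated family to disk
#'
#' Writes the protein FASTA (headers carry `subfamily=` / `subgroup=`
#' labels so the file doubles as a labelled reference panel), CDS FASTA,
#' GFF3 gene models, and the truth table TSV.
#'
#' @param sim result of [simulate_family()]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.faa"),
             cds = file.path(dir, "cds.fna"),
             models = file.path(dir, "models.gff3"),
             truth = file.path(dir, "truth.tsv"))
  labelled <- setNames(sim$proteins, sprintf(
    "%s subfamily=%s subgroup=%s", sim$truth$name, sim$truth$subfamily,
    sim$truth$subgroup))
  write_fasta(labelled, paths["proteins"])
  write_fasta(sim$cds, paths["cds"])
  write_gff3(sim$models, paths["models"])
  write_tsv_table(sim$truth, paths["truth"])
  invisible(paths)
}

#' Labelled reference panel from a simulation
#'
#' @param sim result of [simulate_family()]
#' @return a panel list (`seqs`, `labels`) as used by [assign_subfamily()]
#' @export
sim_panel <- function(sim) {
  list(seqs = sim$proteins,
       labels = data.frame(id = sim$truth$name,
                           subfamily = sim$truth$subfamily,
                           subgroup = sim$truth$subgroup,
                           stringsAsFactors = FALSE))
}
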