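# TSV dialect used throughout: tab-separated, '#'-prefixed header line,
# UTF-8, '-' for missing values (matching the dashes of published tables).

#' Read a TSV table in the package dialect
#' @param path file path
#' @return data.frame of character columns; '-' becomes NA
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1], "#")) {
    stop("TSV parse error: expected '#'-prefixed header in ", path)
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L) {
    return(as.data.frame(setNames(rep(list(character(0)), length(header)),
                                  header), stringsAsFactors = FALSE))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(body) != length(header))
  if (length(bad)) {
    stop("TSV parse error at line ", bad[1] + 1L, " of ", path,
         ": expected ", length(header), " fields, got ",
         lengths(body)[bad[1]])
  }
  mat <- do.call(rbind, body)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df[df == "-"] <- NA
  df
}

#' Write a TSV table in the package dialect
#' @param df data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv_table <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "-"
    col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  lines <- c(paste0("#", paste(names(out), collapse = "\t")),
             do.call(paste, c(out, sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.FIXTURES <- c("table2_inventory", "table3_residues", "table4_profiles",
               "table4_observations", "table1_family_sizes",
               "ancestral_counts")

#' Load a packaged fixture table
#'
#' Fixtures are tabular data shipped with the package: the 32-gene physic
#' nut inventory (`table2_inventory`), per-protein residue annotations
#' (`table3_residues`), the degenerate SDP profiles of the six typical
#' transporter classes (`table4_profiles`) and the per-protein SDP vectors
#' printed under them (`table4_observations`), plant AQP family sizes by
#' species (`table1_family_sizes`), and the per-subgroup ancestral
#' Euphorbiaceae family counts (`ancestral_counts`).
#'
#' @param name fixture identifier
#' @return for `table4_profiles`, a named list of [sdp_profile()] objects;
#'   otherwise a parsed data.frame (the inventory gains typed columns plus
#'   derived `strand`, `subfamily` and `subgroup`)
#' @export
#' @examples
#' inv <- load_fixture("table2_inventory")
#' nrow(inv)
load_fixture <- function(name) {
  if (!name %in% .FIXTURES) {
    stop("unknown fixture '", name, "'; available: ",
         paste(.FIXTURES, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "aqpscan",
                      mustWork = TRUE)
  df <- read_tsv_table(path)
  switch(name,
    table2_inventory = parse_inventory(df),
    table4_profiles = parse_profiles(df),
    table1_family_sizes = {
      for (col in c("PIP", "TIP", "NIP", "SIP", "XIP", "total")) {
        df[[col]] <- as.integer(df[[col]])
      }
      df
    },
    ancestral_counts = {
      df$count <- as.integer(df$count)
      df
    },
    table3_residues = {
      for (col in c("length", "tm")) df[[col]] <- as.integer(df[[col]])
      for (col in c("mw_kda", "pi")) df[[col]] <- as.numeric(df[[col]])
      df
    },
    df
  )
}

# typed inventory with derived strand / subfamily / subgroup columns
parse_inventory <- function(df) {
  int_cols <- c("predicted_start", "predicted_end", "identified_start",
                "identified_end", "cds_len", "gene_len", "est_hits")
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  df$est_hits[is.na(df$est_hits)] <- 0L
  for (col in c("expressed", "splice_est", "splice_read")) {
    df[[col]] <- !is.na(df[[col]]) & df[[col]] == "Yes"
  }
  df$strand <- ifelse(df$identified_start > df$identified_end, "-", "+")
  df$subfamily <- sub("^[A-Z][a-z]([A-Z]+)[0-9].*$", "\\1", df$name)
  df$subgroup <- sub("^[A-Z][a-z]([A-Z]+[0-9]+);.*$", "\\1", df$name)
  df
}

parse_profiles <- function(df) {
  profs <- lapply(seq_len(nrow(df)), function(i) {
    allowed <- lapply(unlist(df[i, paste0("SDP", 1:9)], use.names = FALSE),
                      function(x) strsplit(x, "/", fixed = TRUE)[[1]])
    sdp_profile(df$substrate[i], allowed)
  })
  names(profs) <- df$substrate
  profs
}

#' Pipeline configuration
#'
#' Houses the thresholds used across the pipeline: the similarity floor for
#' candidate screening, the floor for best-hit ortholog calls, the minimum
#' EST identity fraction, the minimum mapped-fragment count for an
#' "expressed" call (2, i.e. more than one fragment), the log2 pseudocount
#' for expression transforms, and the RNG seed.
#'
#' @param similarity_screen_threshold percent-similarity floor for candidate
#'   screening
#' @param ortholog_min_score percent-similarity floor for best-hit calls
#' @param est_identity_min minimum EST identity fraction, in (0, 1]
#' @param expressed_min_fragments minimum mapped fragments to call a gene
#'   expressed (>= 1)
#' @param log2_pseudocount pseudocount added before log2 transforms (> 0)
#' @param rng_seed integer seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(similarity_screen_threshold = 25,
                            ortholog_min_score = 40,
                            est_identity_min = 0.98,
                            expressed_min_fragments = 2L,
                            log2_pseudocount = 1,
                            rng_seed = 1L) {
  stopifnot(est_identity_min > 0, est_identity_min <= 1)
  stopifnot(expressed_min_fragments >= 1)
  stopifnot(log2_pseudocount > 0)
  structure(list(
    similarity_screen_threshold = similarity_screen_threshold,
    ortholog_min_score = ortholog_min_score,
    est_identity_min = est_identity_min,
    expressed_min_fragments = as.integer(expressed_min_fragments),
    log2_pseudocount = log2_pseudocount,
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a key: value file
#' @param path path to a YAML-style `key: value` file
#' @return a [pipeline_config()] with file values overriding defaults
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  known <- intersect(names(vals), names(cfg))
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals[known])
}

#' Write a pipeline configuration
#' @param cfg a [pipeline_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
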