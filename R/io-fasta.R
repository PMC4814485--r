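#' Read a FASTA file
#'
#' Validating FASTA reader. The file is first checked line by line (so parse
#' errors can name the offending line), then parsed with Biostrings. Records
#' are returned in file order, identifiers are the first whitespace-delimited
#' token of the header, and residues are upper-cased.
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences; full headers are kept in the
#'   `"headers"` attribute
#' @export
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">a", "MKT", ">b", "GGA"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  headers <- character(0)
  n_seq_lines <- 0L
  current_id <- NULL
  flush_record <- function(line_no) {
    if (!is.null(current_id) && n_seq_lines == 0L) {
      stop("FASTA parse error at line ", line_no,
           ": record '", current_id, "' has an empty sequence")
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln)) next
    if (startsWith(ln, ">")) {
      flush_record(i)
      hdr <- sub("^>", "", ln)
      id <- strsplit(trimws(hdr), "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        stop("FASTA parse error at line ", i, ": malformed header '", ln, "'")
      }
      ids <- c(ids, id)
      headers <- c(headers, hdr)
      current_id <- id
      n_seq_lines <- 0L
    } else {
      if (is.null(current_id)) {
        stop("FASTA parse error at line ", i,
             ": sequence data before any header")
      }
      if (grepl("[^A-Za-z*.\\-]", ln)) {
        stop("FASTA parse error at line ", i,
             ": invalid characters in sequence")
      }
      n_seq_lines <- n_seq_lines + 1L
    }
  }
  flush_record(length(lines) + 1L)
  if (length(ids) == 0L) stop("FASTA parse error: no records in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("FASTA parse error: duplicate record identifiers: ",
         paste(dup, collapse = ", "))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  attr(seqs, "headers") <- headers
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
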