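#' Read a protein FASTA file into a record table
#'
#' Parses a multi-record protein FASTA via [Biostrings::readAAStringSet()]
#' and validates it against the package's record contract: the header
#' token before the first whitespace becomes the record `id`, the
#' remainder (possibly empty) the free-text `taxon` tag, and sequences
#' are uppercased. A single terminal `'*'` (stop) is stripped.
#'
#' @param path Path to an existing FASTA file.
#' @return A `data.frame` with columns `id`, `taxon`, `seq`, one row per
#'   record, input order preserved.
#' @details Hard errors: duplicate ids (named in the message), empty
#'   sequences, and any character outside the 20 standard amino acids
#'   plus `'X'` (after terminal-`'*'` stripping).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # validate residues on the raw text: the FASTA backend silently drops
  # characters it does not recognise
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^>", lines)
  if (any(is_hdr)) {
    raw_ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
    body <- vapply(split(lines[!is_hdr],
                         cumsum(is_hdr)[!is_hdr]),
                   function(x) toupper(paste(gsub("\\s", "", x),
                                             collapse = "")), "")
    body <- sub("\\*$", "", body)
    ok <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""),
                       "X]*$"), body)
    if (any(!ok)) {
      stop("non-amino-acid character in record ",
           raw_ids[as.integer(names(body))[!ok]][1], call. = FALSE)
    }
  }
  ss <- suppressWarnings(Biostrings::readAAStringSet(path))
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  taxa <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(ss))
  # strip a single terminal stop character
  seqs <- sub("\\*$", "", seqs)
  if (any(ids == "")) stop("FASTA record with empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate id ", dup[1], " in ", path, call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    bad <- ids[nchar(seqs) == 0][1]
    stop("empty sequence for record ", bad, call. = FALSE)
  }
  ok <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "X]+$"), seqs)
  if (any(!ok)) {
    bad <- ids[!ok][1]
    stop("non-amino-acid character in record ", bad, call. = FALSE)
  }
  data.frame(id = unname(ids), taxon = unname(taxa), seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a protein record table as FASTA
#'
#' Inverse of [read_fasta()]: writes `>id taxon` headers (taxon omitted
#' when empty) with sequence lines wrapped at 60 columns.
#'
#' @param records `data.frame` with columns `id`, `taxon`, `seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate id ", records$id[duplicated(records$id)][1], call. = FALSE)
  }
  ss <- Biostrings::AAStringSet(records$seq)
  taxon <- if ("taxon" %in% names(records)) records$taxon else ""
  names(ss) <- ifelse(is.na(taxon) | taxon == "",
                      records$id, paste(records$id, taxon))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
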