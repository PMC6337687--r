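#' @importFrom utils read.delim write.table
NULL

.BASES <- c("A", "C", "G", "T")

## IUPAC ambiguity codes other than N are unmatchable for exact-match PCR;
## map them to N instead of rejecting (real assemblies contain them).
.AMBIG <- "RYSWKMBDHV"

normalize_residues <- function(x) {
  x <- toupper(x)
  chartr(.AMBIG, strrep("N", nchar(.AMBIG)), x)
}

#' Construct a set of sequence records
#'
#' A sequence-record set is a plain \code{data.frame} with columns
#' \code{id}, \code{description}, \code{residues} and \code{length}.
#' Residues are normalized to the \{A,C,G,T,N\} alphabet (uppercased;
#' IUPAC ambiguity codes other than N mapped to N).
#'
#' @param ids character vector of record identifiers (no whitespace).
#' @param residues character vector of sequences.
#' @param descriptions full header lines; defaults to \code{ids}.
#' @return data.frame with one row per record.
#' @export
sequence_records <- function(ids, residues, descriptions = ids) {
  ids <- as.character(ids)
  if (length(ids) != length(residues))
    stop("ids and residues must have equal length")
  if (any(!nzchar(ids)))
    stop("record ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1L])
  residues <- normalize_residues(as.character(residues))
  bad <- grepl("[^ACGTN]", residues)
  if (any(bad)) {
    ch <- gsub("[ACGTN]", "", residues[bad][1L])
    stop("record '", ids[bad][1L], "' contains residues outside the ",
         "IUPAC alphabet: ", substr(ch, 1L, 10L))
  }
  data.frame(id = ids, description = as.character(descriptions),
             residues = residues, length = nchar(residues),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file (arbitrary line width), normalizes
#' residues to \{A,C,G,T,N\} and returns a sequence-record set. The
#' record id is the first whitespace-delimited token of the header; the
#' full header is kept as the description.
#'
#' @param path path to a FASTA file.
#' @return data.frame as returned by [sequence_records()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  head_chunk <- readChar(path, nchars = min(file.size(path), 4096L),
                         useBytes = TRUE)
  first <- sub("^[[:space:]]*", "", head_chunk)
  if (!nzchar(first) || substr(first, 1L, 1L) != ">")
    stop("not a FASTA file (no '>' header): ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  sequence_records(ids, as.character(set), headers)
}

#' Write records to a FASTA file
#'
#' @param records sequence-record set ([sequence_records()]).
#' @param path output path.
#' @param width sequence line width in bp (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be >= 1")
  if (is.null(records) || nrow(records) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write to: ", path)
    return(invisible(path))
  }
  headers <- ifelse(nzchar(records$description), records$description,
                    records$id)
  ## header's first token must round-trip to the id
  tok <- sub("\\s.*$", "", headers)
  headers <- ifelse(tok == records$id, headers,
                    paste(records$id, headers))
  set <- Biostrings::BStringSet(structure(records$residues,
                                          names = headers))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                              width = width)
  invisible(path)
}

#' Reverse-complement a sequence
#'
#' Vectorized over its input. The complement of N is N;
#' `reverse_complement` is an involution.
#'
#' @param seq character vector over \{A,C,G,T,N\}.
#' @return character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seq)))
    stop("invalid residue in sequence (expected A/C/G/T/N)")
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

## internal: one record row as a list (id, residues, length)
.as_record <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) stop("expected a single record")
    record <- as.list(record)
  }
  if (is.null(record$id) || is.null(record$residues))
    stop("a record needs 'id' and 'residues'")
  record$length <- nchar(record$residues)
  record
}

write_tsv <- function(df, path) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
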