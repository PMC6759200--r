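#' Read a FASTA file into a set of sequence records
#'
#' Thin wrapper around the Biostrings FASTA readers that enforces the
#' invariants the rest of the package relies on: non-empty, unique record
#' ids and residues drawn from the IUPAC alphabet for the declared type.
#' Residues are upper-cased on read.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either \code{"dna"} or \code{"protein"}.
#' @return A \link[Biostrings]{DNAStringSet} or
#'   \link[Biostrings]{AAStringSet} with one element per record, in file
#'   order, named by the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("FASTA format error at line 1: empty file: ", path)
  if (!startsWith(first, ">")) {
    stop("FASTA format error at line 1: expected '>' header, got: ", first)
  }
  seqs <- if (alphabet == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA format error: record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chars <- toupper(as.character(seqs))
  seqs <- if (alphabet == "dna") {
    Biostrings::DNAStringSet(chars)
  } else {
    Biostrings::AAStringSet(chars)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named \code{XStringSet} (or named character vector).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Construct a single in-memory sequence record
#'
#' @param id Record identifier (non-empty string).
#' @param residues Residue string.
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @return A length-1 named \code{DNAStringSet}/\code{AAStringSet}.
#' @export
sequence_record <- function(id, residues, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  x <- if (alphabet == "dna") {
    Biostrings::DNAStringSet(toupper(residues))
  } else {
    Biostrings::AAStringSet(toupper(residues))
  }
  names(x) <- id
  x
}
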