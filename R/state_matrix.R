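#' Read a presence/absence tip-state matrix from TSV
#'
#' Expected layout: a header row of gene ids, first column taxon ids, one
#' row per taxon, cells coded \code{1} (present), \code{0} (absent) or
#' \code{?} (unknown).
#'
#' @param path Path to a tab-separated file.
#' @return A character matrix with taxa as rownames, genes as colnames and
#'   entries in \code{c("present", "absent", "unknown")}.
#' @export
read_state_matrix <- function(path) {
  if (!file.exists(path)) stop("state matrix file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("state matrix must have a header row and at least one taxon row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 2L) stop("state matrix header must name at least one gene")
  genes <- header[-1]
  body <- cells[-1]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    stop("ragged state matrix: row(s) ", paste(which(widths != length(header)) + 1L, collapse = ", "),
         " do not have ", length(header), " columns")
  }
  taxa <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(taxa)) stop("duplicate taxon ids in state matrix")
  vals <- do.call(rbind, lapply(body, function(r) r[-1]))
  bad <- !vals %in% c("1", "0", "?")
  if (any(bad)) stop("state matrix cells must be 1, 0 or ?; offending value(s): ",
                     paste(unique(vals[bad]), collapse = ", "))
  out <- matrix(c(`1` = "present", `0` = "absent", `?` = "unknown")[vals],
                nrow = length(taxa), dimnames = list(taxa, genes))
  out
}

#' Write a tip-state matrix to TSV
#'
#' Inverse of \code{\link{read_state_matrix}}; round-trips bit-identically.
#'
#' @param states Character matrix with entries present/absent/unknown.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_state_matrix <- function(states, path) {
  code <- c(present = "1", absent = "0", unknown = "?")
  vals <- matrix(code[states], nrow = nrow(states), dimnames = dimnames(states))
  lines <- c(paste(c("taxon", colnames(states)), collapse = "\t"),
             vapply(seq_len(nrow(states)),
                    function(i) paste(c(rownames(states)[i], vals[i, ]), collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}
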