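#' Engine parameters for the built-in local-alignment search
#'
#' The built-in engine is a desk-scale re-creation of translated
#' (protein query vs. six-frame translated nucleotide subject) and
#' nucleotide local search. It reproduces the *semantics* of an E-value
#' driven search -- Smith-Waterman local alignments scored and converted
#' to expectation values via Karlin-Altschul statistics
#' \eqn{E = K m n e^{-\lambda S}} -- not the exact numbers of any
#' particular external tool. Protein scoring uses BLOSUM62 with gap
#' open 11 / extend 1 and gapped constants lambda = 0.267, K = 0.041;
#' nucleotide scoring uses match +2 / mismatch -3, gap open 5 / extend 2
#' with lambda = 0.625, K = 0.41. \code{m} is the query length and
#' \code{n} the total searched subject length (all six translated frames,
#' or both nucleotide strands).
#'
#' @param type \code{"protein"} (translated search) or \code{"dna"}.
#' @param evalue_max Largest per-region E-value worth reporting (regions
#'   above it are discarded; subjects with no reportable region yield no
#'   hit). Defaults to 0.05, the package-wide "no hit" boundary.
#' @param max_hsps Maximum number of distinct aligned regions recovered
#'   per query/subject/frame by iterative masking.
#' @param db_size Effective database size \code{n} (residues for the
#'   translated engine, nucleotides for the nucleotide engine) used in
#'   the E-value formula. \code{NULL} (the default) uses the actual
#'   searched subject length; set it explicitly when a search against a
#'   small extracted sequence should be judged at the significance scale
#'   of the full database it stands in for, as E-values always scale
#'   with database size.
#' @return A named list of engine parameters.
#' @export
engine_params <- function(type = c("protein", "dna"), evalue_max = 0.05,
                          max_hsps = 4L, db_size = NULL) {
  type <- match.arg(type)
  if (type == "protein") {
    list(type = type, gap_open = 11, gap_ext = 1,
         lambda = 0.267, K = 0.041,
         evalue_max = evalue_max, max_hsps = as.integer(max_hsps),
         db_size = db_size)
  } else {
    list(type = type, match = 2, mismatch = -3, gap_open = 5, gap_ext = 2,
         lambda = 0.625, K = 0.41,
         evalue_max = evalue_max, max_hsps = as.integer(max_hsps),
         db_size = db_size)
  }
}

#' @noRd
karlin_evalue <- function(score, m, n, lambda, K) {
  pmax(K * m * n * exp(-lambda * score), .Machine$double.xmin)
}

# package-local cache for the BLOSUM62 matrix
.condevo_cache <- new.env(parent = emptyenv())

#' @noRd
blosum62 <- function() {
  if (is.null(.condevo_cache$BLOSUM62)) {
    e <- new.env()
    utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
    .condevo_cache$BLOSUM62 <- e$BLOSUM62
  }
  .condevo_cache$BLOSUM62
}

#' @noRd
aligned_identity <- function(pa, sa) {
  a <- strsplit(pa, "", fixed = TRUE)[[1]]
  b <- strsplit(sa, "", fixed = TRUE)[[1]]
  keep <- a != "-" & b != "-" & !(a %in% c("X", "N", "*")) & !(b %in% c("X", "N", "*"))
  if (!any(keep)) return(0)
  mean(a[keep] == b[keep])
}

# Extract up to max_hsps local alignments of `query` within one subject
# string (a translated frame or one nucleotide strand), masking each
# found subject segment so later passes recover distinct regions.
# `first` may carry a precomputed pass-1 alignment (from a batched call).
# Coordinates returned 1-based inclusive on the subject string / query.
#' @noRd
subject_hsps <- function(subject_str, query_str, submat, gap_open, gap_ext,
                         min_score, max_hsps, mask_char, first = NULL) {
  segs <- list()
  cur <- subject_str
  for (i in seq_len(max_hsps)) {
    aln <- if (i == 1L && !is.null(first)) {
      first
    } else {
      Biostrings::pairwiseAlignment(cur, query_str, type = "local",
                                    substitutionMatrix = submat,
                                    gapOpening = gap_open, gapExtension = gap_ext)
    }
    sc <- Biostrings::score(aln)
    if (!is.finite(sc) || sc < min_score) break
    p <- Biostrings::pattern(aln)   # subject side (pattern slot)
    q <- Biostrings::subject(aln)   # query side
    segs[[length(segs) + 1L]] <- list(
      score = sc,
      s_start = Biostrings::start(p), s_end = Biostrings::end(p),
      q_start = Biostrings::start(q), q_end = Biostrings::end(q),
      aligned_subject = as.character(Biostrings::alignedPattern(aln)),
      aligned_query = as.character(Biostrings::alignedSubject(aln))
    )
    substr(cur, Biostrings::start(p), Biostrings::end(p)) <-
      strrep(mask_char, Biostrings::end(p) - Biostrings::start(p) + 1L)
  }
  segs
}

#' Translated local search of a protein query against a nucleotide subject
#'
#' All six reading frames of the subject (three per strand) are translated
#' and locally aligned against the query. Each maximal local alignment
#' whose E-value passes the reporting cutoff becomes one aligned region;
#' regions across frames of the same subject are grouped into a single
#' hit whose E-value is the best per-region E-value. Subject coordinates
#' are reported in nucleotides on the forward strand, 0-based half-open.
#'
#' @param query Length-1 named \code{AAStringSet} (protein).
#' @param subject Length-1 named \code{DNAStringSet}.
#' @param params See \code{\link{engine_params}}.
#' @return A list with zero or one \code{\link{search_hit}}.
#' @export
translated_local_search <- function(query, subject, params = engine_params("protein")) {
  stopifnot(length(query) == 1L, length(subject) == 1L)
  qid <- names(query)
  sid <- names(subject)
  qstr <- as.character(query[[1]])
  dna <- subject[[1]]
  L <- length(dna)
  if (L < 3L) return(list())
  m <- nchar(qstr)

  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else Biostrings::reverseComplement(dna)
    for (f in 0:2) {
      nlen <- ((L - f) %/% 3L) * 3L
      if (nlen < 3L) next
      aa <- suppressWarnings(Biostrings::translate(
        Biostrings::subseq(s, start = f + 1L, width = nlen),
        if.fuzzy.codon = "X"))
      frames[[length(frames) + 1L]] <-
        list(strand = strand, frame = f, aa = chartr("*", "X", as.character(aa)))
    }
  }
  if (length(frames) == 0L) return(list())
  frame_strs <- vapply(frames, `[[`, character(1), "aa")
  n_total <- sum(nchar(frame_strs))
  if (!is.null(params$db_size)) n_total <- max(n_total, params$db_size)
  min_score <- log(params$K * m * n_total / params$evalue_max) / params$lambda

  submat <- blosum62()
  batch <- Biostrings::pairwiseAlignment(Biostrings::AAStringSet(frame_strs), qstr,
                                         type = "local", substitutionMatrix = submat,
                                         gapOpening = params$gap_open,
                                         gapExtension = params$gap_ext)
  scores <- Biostrings::score(batch)

  regions <- list()
  for (i in seq_along(frames)) {
    if (!is.finite(scores[i]) || scores[i] < min_score) next
    fr <- frames[[i]]
    segs <- subject_hsps(fr$aa, qstr, submat, params$gap_open, params$gap_ext,
                         min_score, params$max_hsps, "X", first = batch[i])
    for (sg in segs) {
      ev <- karlin_evalue(sg$score, m, n_total, params$lambda, params$K)
      if (ev > params$evalue_max) next
      nt_lo <- fr$frame + 3L * (sg$s_start - 1L)   # 0-based on the frame's strand
      nt_hi <- fr$frame + 3L * sg$s_end            # half-open
      if (fr$strand == "+") {
        s0 <- nt_lo; s1 <- nt_hi
      } else {
        s0 <- L - nt_hi; s1 <- L - nt_lo
      }
      reg <- aligned_region(query_start = sg$q_start - 1L, query_end = sg$q_end,
                            subject_start = s0, subject_end = s1,
                            identity_fraction = aligned_identity(sg$aligned_query,
                                                                 sg$aligned_subject),
                            length_nt = s1 - s0,
                            strand = fr$strand, score = sg$score, evalue = ev)
      regions[[length(regions) + 1L]] <- list(reg = reg, evalue = ev)
    }
  }
  if (length(regions) == 0L) return(list())
  best_e <- min(vapply(regions, `[[`, numeric(1), "evalue"))
  list(search_hit(qid, sid, evalue = best_e, regions = lapply(regions, `[[`, "reg")))
}

#' Nucleotide local search of a DNA query against a DNA subject
#'
#' Both subject strands are searched; coordinates are reported on the
#' forward strand, 0-based half-open.
#'
#' @inheritParams translated_local_search
#' @param params See \code{\link{engine_params}} with \code{type = "dna"}.
#' @return A list with zero or one \code{\link{search_hit}}.
#' @export
nucleotide_local_search <- function(query, subject, params = engine_params("dna")) {
  stopifnot(length(query) == 1L, length(subject) == 1L)
  qid <- names(query)
  sid <- names(subject)
  qstr <- as.character(query[[1]])
  dna <- subject[[1]]
  L <- length(dna)
  if (L < 3L) return(list())
  m <- nchar(qstr)
  n_total <- 2 * L
  if (!is.null(params$db_size)) n_total <- max(n_total, params$db_size)
  min_score <- log(params$K * m * n_total / params$evalue_max) / params$lambda
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                     mismatch = params$mismatch,
                                                     baseOnly = FALSE)
  strands <- c("+", "-")
  strand_strs <- c(as.character(dna),
                   as.character(Biostrings::reverseComplement(dna)))
  batch <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(strand_strs), qstr,
                                         type = "local", substitutionMatrix = submat,
                                         gapOpening = params$gap_open,
                                         gapExtension = params$gap_ext)
  scores <- Biostrings::score(batch)

  regions <- list()
  for (i in seq_along(strands)) {
    if (!is.finite(scores[i]) || scores[i] < min_score) next
    segs <- subject_hsps(strand_strs[i], qstr, submat, params$gap_open, params$gap_ext,
                         min_score, params$max_hsps, "N", first = batch[i])
    for (sg in segs) {
      ev <- karlin_evalue(sg$score, m, n_total, params$lambda, params$K)
      if (ev > params$evalue_max) next
      if (strands[i] == "+") {
        s0 <- sg$s_start - 1L; s1 <- sg$s_end
      } else {
        s0 <- L - sg$s_end; s1 <- L - (sg$s_start - 1L)
      }
      reg <- aligned_region(query_start = sg$q_start - 1L, query_end = sg$q_end,
                            subject_start = s0, subject_end = s1,
                            identity_fraction = aligned_identity(sg$aligned_query,
                                                                 sg$aligned_subject),
                            length_nt = s1 - s0,
                            strand = strands[i], score = sg$score, evalue = ev)
      regions[[length(regions) + 1L]] <- list(reg = reg, evalue = ev)
    }
  }
  if (length(regions) == 0L) return(list())
  best_e <- min(vapply(regions, `[[`, numeric(1), "evalue"))
  list(search_hit(qid, sid, evalue = best_e, regions = lapply(regions, `[[`, "reg")))
}

#' Search one query against every contig of a genome
#'
#' @param query Length-1 named \code{XStringSet} (protein for the
#'   translated engine, DNA for the nucleotide engine).
#' @param genome Named \code{DNAStringSet} of contigs.
#' @param engine A search function with the signature of
#'   \code{\link{translated_local_search}}; defaults to the translated
#'   engine when the query is protein and the nucleotide engine otherwise.
#' @param params Engine parameters, passed through to \code{engine}.
#' @return A deterministically sorted list of \code{search_hit}s, at most
#'   one per contig.
#' @export
search_genome <- function(query, genome, engine = NULL, params = NULL) {
  if (is.null(engine)) {
    engine <- if (inherits(query, "AAStringSet")) translated_local_search
              else nucleotide_local_search
    if (is.null(params)) {
      params <- engine_params(if (inherits(query, "AAStringSet")) "protein" else "dna")
    }
  }
  hits <- list()
  for (i in seq_along(genome)) {
    h <- if (is.null(params)) engine(query, genome[i]) else engine(query, genome[i], params)
    hits <- c(hits, h)
  }
  sort_hits(hits)
}
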