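#' Classify the mutational steps between two codons
#'
#' Codons differing at k positions (k <= 3) are connected by k!
#' single-nucleotide pathways. Pathways passing through a stop codon at
#' an intermediate step are discarded; each remaining pathway's steps
#' are labeled synonymous or nonsynonymous under the standard genetic
#' code, and labels are averaged over pathways so the returned weights
#' sum to k. Classification is symmetric in its arguments.
#'
#' @param codon_a,codon_b Upper-case, gap-free, unambiguous, non-stop
#'   codons of length 3.
#' @return Data frame with columns \code{effect}
#'   (synonymous/nonsynonymous) and \code{weight}; zero rows for
#'   identical codons. If every pathway is blocked by stop codons the
#'   result has zero rows and attribute \code{blocked = TRUE}.
#' @export
classify_codon_pair <- function(codon_a, codon_b) {
  w <- codon_pair_weights(codon_a, codon_b)
  if (is.null(w)) {
    return(structure(data.frame(effect = character(), weight = numeric()),
                     blocked = TRUE))
  }
  d <- data.frame(effect = c("synonymous", "nonsynonymous"),
                  weight = c(w[["syn"]], w[["non"]]))
  d[d$weight > 0, , drop = FALSE]
}

# Numeric core of the pathway-averaged classification, memoized: returns
# c(syn =, non =), or NULL when every pathway passes through a stop.
#' @noRd
codon_pair_weights <- function(codon_a, codon_b) {
  cache <- .condevo_cache$codon_pairs
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .condevo_cache$codon_pairs <- cache
  }
  key <- paste0(codon_a, codon_b)
  got <- cache[[key]]
  if (!is.null(got)) {
    if (is.character(got)) return(NULL)   # cached blocked marker
    return(got)
  }
  gc <- Biostrings::GENETIC_CODE
  check_codon <- function(x) {
    if (is.na(match(x, names(gc)))) {
      stop("codon must be 3 unambiguous bases, got: ", x)
    }
    if (gc[[x]] == "*") stop("stop codon in input: ", x)
  }
  check_codon(codon_a); check_codon(codon_b)
  if (codon_a == codon_b) {
    out <- c(syn = 0, non = 0)
    cache[[key]] <- out
    return(out)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diffs <- which(a != b)
  k <- length(diffs)
  perms <- list(list(1L), list(c(1L, 2L), c(2L, 1L)),
                list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))[[k]]
  syn <- 0; non <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- a
    s_cnt <- 0L; n_cnt <- 0L
    blocked <- FALSE
    for (j in seq_len(k)) {
      pos <- diffs[ord[j]]
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && j < k) { blocked <- TRUE; break }
      if (aa_cur == aa_nxt) s_cnt <- s_cnt + 1L else n_cnt <- n_cnt + 1L
      cur <- nxt
    }
    if (blocked) next
    n_valid <- n_valid + 1L
    syn <- syn + s_cnt
    non <- non + n_cnt
  }
  if (n_valid == 0L) {
    cache[[key]] <- "blocked"
    return(NULL)
  }
  out <- c(syn = syn / n_valid, non = non / n_valid)
  cache[[key]] <- out
  out
}

#' @noRd
codon_matrix <- function(seqs) {
  chars <- if (is.character(seqs)) seqs else as.character(seqs)
  len <- unique(nchar(chars))
  if (length(len) != 1L) stop("sequences are not aligned to a common length")
  if (len %% 3L != 0L) stop("alignment length not divisible by 3: ", len)
  n_cod <- len %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  m <- vapply(chars, function(s) substring(s, starts, starts + 2L),
              character(n_cod))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(m)))
  t(m)
}

#' Tabulate the 2x2 McDonald-Kreitman table from a codon alignment
#'
#' Per codon site: segregating changes among ingroup haplotypes (each
#' distinct minor allele vs. the major allele) contribute to pN/pS; a
#' site whose ingroup allele set excludes the outgroup consensus codon
#' additionally contributes a fixed change (major allele vs. outgroup
#' consensus) to dN/dS. Sites with a gap, ambiguity code or stop codon
#' in any sequence, and sites where the outgroup segregates with no
#' major allele, are skipped and tallied in the QC report. Fractional
#' pathway weights are summed and rounded half-up only in the final
#' table; both raw and rounded counts are returned.
#'
#' @param ingroup Aligned codon sequences of the ingroup haplotypes
#'   (\code{DNAStringSet} or character vector), >= 2 sequences.
#' @param outgroup One or more aligned outgroup sequences; with several,
#'   the per-site outgroup major allele is used.
#' @return List of class \code{mk_counts}: \code{pS, pN, dS, dN}
#'   (rounded integers), \code{raw} (unrounded weights), \code{skipped}
#'   (named counts of skipped sites by reason), \code{n_sites}.
#' @export
tabulate_mk <- function(ingroup, outgroup) {
  ing <- codon_matrix(ingroup)
  og <- codon_matrix(outgroup)
  if (nrow(ing) < 2L) stop("need at least 2 ingroup haplotypes")
  if (ncol(ing) != ncol(og)) stop("ingroup and outgroup are not aligned to the same length")
  n_sites <- ncol(ing)
  raw <- c(pS = 0, pN = 0, dS = 0, dN = 0)
  skipped <- c(gap_or_ambiguous = 0L, stop_codon = 0L,
               outgroup_ambiguous = 0L, blocked_pathway = 0L)
  gc <- Biostrings::GENETIC_CODE
  codons64 <- names(gc)
  stop_codons <- codons64[gc == "*"]

  # vectorized per-site pre-screens over the whole matrix
  ref <- ing[1L, ]
  varying <- colSums(ing != matrix(ref, nrow(ing), n_sites, byrow = TRUE)) > 0L |
             colSums(og != matrix(ref, nrow(og), n_sites, byrow = TRUE)) > 0L
  clean <- matrix(ing %in% codons64, nrow(ing))
  clean_og <- matrix(og %in% codons64, nrow(og))
  site_clean <- colSums(clean) == nrow(ing) & colSums(clean_og) == nrow(og)
  has_stop <- colSums(matrix(ing %in% stop_codons, nrow(ing))) > 0L |
              colSums(matrix(og %in% stop_codons, nrow(og))) > 0L

  for (s in which(varying)) {
    if (!site_clean[s]) {
      skipped["gap_or_ambiguous"] <- skipped["gap_or_ambiguous"] + 1L
      next
    }
    if (has_stop[s]) {
      skipped["stop_codon"] <- skipped["stop_codon"] + 1L
      next
    }
    ogc <- og[, s]
    u_og <- unique(ogc)
    if (length(u_og) > 1L) {
      cnt_og <- tabulate(match(ogc, u_og))
      top <- u_og[cnt_og == max(cnt_og)]
      if (length(top) > 1L) {   # outgroup segregates with no major allele
        skipped["outgroup_ambiguous"] <- skipped["outgroup_ambiguous"] + 1L
        next
      }
      og_major <- top
    } else {
      og_major <- u_og
    }

    cods <- ing[, s]
    u <- unique(cods)
    if (length(u) == 1L) {
      major <- u
      minors <- character()
    } else {
      cnt <- tabulate(match(cods, u))
      mx <- u[cnt == max(cnt)]
      major <- sort(mx)[1L]   # lexicographic tie-break: order-invariant
      minors <- u[u != major]
    }
    blocked_here <- FALSE
    for (mn in minors) {
      w <- codon_pair_weights(major, mn)
      if (is.null(w)) {
        blocked_here <- TRUE
      } else {
        raw[["pS"]] <- raw[["pS"]] + w[["syn"]]
        raw[["pN"]] <- raw[["pN"]] + w[["non"]]
      }
    }
    if (is.na(match(og_major, u))) {
      w <- codon_pair_weights(major, og_major)
      if (is.null(w)) {
        blocked_here <- TRUE
      } else {
        raw[["dS"]] <- raw[["dS"]] + w[["syn"]]
        raw[["dN"]] <- raw[["dN"]] + w[["non"]]
      }
    }
    if (blocked_here) skipped["blocked_pathway"] <- skipped["blocked_pathway"] + 1L
  }
  rounded <- floor(raw + 0.5)   # round half-up per cell, final table only
  structure(list(pS = rounded[["pS"]], pN = rounded[["pN"]],
                 dS = rounded[["dS"]], dN = rounded[["dN"]],
                 raw = raw, skipped = skipped, n_sites = n_sites),
            class = "mk_counts")
}

#' Construct an MK count table from four counts
#'
#' @param pS,pN,dS,dN Non-negative counts: polymorphic synonymous /
#'   nonsynonymous within species, fixed synonymous / nonsynonymous
#'   between species.
#' @return List of class \code{mk_counts}.
#' @export
mk_counts <- function(pS, pN, dS, dN) {
  v <- c(pS = pS, pN = pN, dS = dS, dN = dN)
  if (any(v < 0)) stop("MK counts must be non-negative")
  structure(list(pS = pS, pN = pN, dS = dS, dN = dN,
                 raw = v, skipped = NULL, n_sites = NA_integer_),
            class = "mk_counts")
}

#' Proportion of adaptive fixed amino-acid substitutions (alpha)
#'
#' \eqn{\alpha = 1 - (dS \cdot pN)/(dN \cdot pS)}, i.e. one minus the
#' neutrality index. May be negative (an excess of nonsynonymous
#' polymorphism); undefined (NA) when dN or pS is zero.
#'
#' @param counts An \code{mk_counts} object (or anything with fields
#'   pS, pN, dS, dN).
#' @return Numeric alpha, or NA when undefined.
#' @export
alpha_from_counts <- function(counts) {
  if (counts$dN == 0 || counts$pS == 0) return(NA_real_)
  1 - (counts$dS * counts$pN) / (counts$dN * counts$pS)
}

#' Fisher's exact test on the MK 2x2 table
#'
#' Tests the table \code{[[dN, dS], [pN, pS]]}. The package default is
#' the two-sided exact test (the convention that reproduces published MK
#' tables computed with standard tools); one-sided alternatives are
#' exposed: \code{"greater"} tests for an excess of nonsynonymous
#' divergence.
#'
#' @param counts An \code{mk_counts} object.
#' @param tail \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return P-value in [0, 1]; an all-zero table gives 1 by convention.
#' @export
mk_fisher <- function(counts, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  m <- matrix(c(counts$dN, counts$dS, counts$pN, counts$pS), nrow = 2, byrow = TRUE)
  if (all(m == 0)) return(1)
  stats::fisher.test(m, alternative = tail)$p.value
}

#' Full MK test result from counts
#'
#' @param counts An \code{mk_counts} object.
#' @param tail Fisher tail convention (see \code{\link{mk_fisher}}).
#' @return List of class \code{mk_result}: \code{counts}, \code{alpha},
#'   \code{p_value}.
#' @export
mk_test <- function(counts, tail = "two.sided") {
  structure(list(counts = counts,
                 alpha = alpha_from_counts(counts),
                 p_value = mk_fisher(counts, tail)),
            class = "mk_result")
}

#' Batch MK tests from a TSV of counts
#'
#' @param path TSV with columns gene, pS, pN, dS, dN.
#' @param tail Fisher tail convention.
#' @return Data frame: gene, pS, pN, dS, dN, alpha, p_value (one row per
#'   input row; alpha is NA where undefined).
#' @export
mk_from_counts_table <- function(path, tail = "two.sided") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene", "pS", "pN", "dS", "dN")
  if (!all(need %in% names(tab))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(data.frame(gene = character(), pS = numeric(), pN = numeric(),
                      dS = numeric(), dN = numeric(), alpha = numeric(),
                      p_value = numeric()))
  }
  if (any(tab[, c("pS", "pN", "dS", "dN")] < 0)) stop("negative counts in table")
  res <- lapply(seq_len(nrow(tab)), function(i) {
    r <- mk_test(mk_counts(tab$pS[i], tab$pN[i], tab$dS[i], tab$dN[i]), tail)
    data.frame(gene = tab$gene[i], pS = tab$pS[i], pN = tab$pN[i],
               dS = tab$dS[i], dN = tab$dN[i],
               alpha = r$alpha, p_value = r$p_value)
  })
  do.call(rbind, res)
}
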