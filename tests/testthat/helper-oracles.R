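# Independent oracles used to freeze expected values: each one is a
# direct, brute-force or closed-form computation kept deliberately
# separate from the package's implementation paths.

# Exhaustive Dollo parsimony: enumerate every labeling of internal nodes
# (and unknown tips), keep those with no gain below the root, count
# present->absent flips (plus a root-edge loss when the ancestor is
# assumed to carry the gene and the root does not).
dollo_brute_force <- function(tree, tipstate, assume_ancestral_present = TRUE) {
  ntip <- length(tree$tip.label)
  nno <- ntip + tree$Nnode
  edge <- tree$edge
  root <- setdiff(edge[, 1], edge[, 2])
  tipv <- tipstate[tree$tip.label] == "present"
  tipv[tipstate[tree$tip.label] == "unknown"] <- NA
  free <- c(if (ntip + 1 <= nno) (ntip + 1):nno, which(is.na(tipv)))
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    st <- c(tipv, rep(NA, tree$Nnode))
    st[free] <- as.logical(bitwAnd(mask, 2^(seq_along(free) - 1)))
    if (any(!st[edge[, 1]] & st[edge[, 2]])) next   # a gain below the root
    losses <- sum(st[edge[, 1]] & !st[edge[, 2]])
    if (assume_ancestral_present && !st[root]) losses <- losses + 1
    best <- min(best, losses)
  }
  best
}

# Exact Fisher p-value by enumerating the full hypergeometric support of
# a 2x2 table [[dN, dS], [pN, pS]] with fixed margins.
fisher_brute_force <- function(dN, dS, pN, pS, tail = "two.sided") {
  r1 <- dN + dS
  c1 <- dN + pN
  n <- dN + dS + pN + pS
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  pobs <- stats::dhyper(dN, c1, n - c1, r1)
  switch(tail,
         greater = sum(probs[support >= dN]),
         less = sum(probs[support <= dN]),
         two.sided = sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Wilson bounds by numeric inversion of the score test: the interval
# ends are the p0 solving (phat - p0)^2 = z^2 p0 (1 - p0) / n. At
# phat = 0 (or 1) the trivial root p0 = phat must be excluded, so the
# search brackets start strictly inside the unit interval.
wilson_bisect <- function(paired, total, confidence = 0.95) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  phat <- paired / total
  f <- function(p0) (phat - p0)^2 - z^2 * p0 * (1 - p0) / total
  lo <- if (paired == 0) 0 else {
    stats::uniroot(f, c(0, phat * (1 - 1e-9)), tol = 1e-14)$root
  }
  hi <- if (paired == total) 1 else {
    stats::uniroot(f, c(phat + (1 - phat) * 1e-9, 1), tol = 1e-14)$root
  }
  c(low = lo, high = hi)
}

# Exhaustive max-count fixed-width window over candidate starts at every
# oligo position.
best_window_brute_force <- function(positions, window_size) {
  counts <- vapply(positions, function(s) {
    sum(positions >= s & positions < s + window_size)
  }, numeric(1))
  best <- which.max(counts)
  list(start = positions[best], count = counts[best])
}

# Upper chi-square tail by numerical integration of the density.
chisq_tail_integrate <- function(stat, df) {
  if (stat == 0) return(1)
  stats::integrate(function(x) stats::dchisq(x, df), stat, Inf,
                   rel.tol = 1e-13, abs.tol = 1e-14)$value
}

# Small random rooted binary tree with unit labels A, B, C, ...
random_rooted_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr
}

# A scripted search engine replaying a fixed hit table: used for
# protocol-layer contract tests. `script` maps "query|subject" to a list
# of search_hit objects.
stub_engine <- function(script, counter = NULL) {
  function(query, subject, params = NULL) {
    if (!is.null(counter)) counter$calls <- counter$calls + 1L
    key <- paste(names(query), names(subject), sep = "|")
    script[[key]] %||% list()
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convenience builders for synthetic hits.
make_region <- function(subject_start = 0, subject_end = 300, identity = 0.9,
                        length_nt = subject_end - subject_start, score = 100,
                        evalue = NA_real_) {
  aligned_region(query_start = 0, query_end = 100,
                 subject_start = subject_start, subject_end = subject_end,
                 identity_fraction = identity, length_nt = length_nt,
                 strand = "+", score = score, evalue = evalue)
}

make_hit <- function(query = "q", subject = "s", evalue = 1e-20, n_regions = 2) {
  regs <- lapply(seq_len(n_regions), function(i) {
    make_region(subject_start = (i - 1) * 400, subject_end = (i - 1) * 400 + 300,
                evalue = evalue)
  })
  search_hit(query, subject, evalue = evalue, regions = regs)
}
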