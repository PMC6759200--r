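#' Wilson score interval for a binomial proportion
#'
#' Inverts the score test: center \eqn{(\hat p + z^2/2n)/(1 + z^2/n)},
#' half-width \eqn{z \sqrt{\hat p (1-\hat p)/n + z^2/4n^2}/(1 + z^2/n)}.
#' Well-behaved at proportions near 0 and 1, which is why it is the
#' interval of choice for nucleus-pairing proportions that are often
#' close to zero.
#'
#' Vectorized over \code{paired} and \code{total}.
#'
#' @param paired Number of successes (paired nuclei), 0 <= paired <= total.
#' @param total Number of trials (nuclei scored), >= 1.
#' @param confidence Confidence level (default 0.95).
#' @return A list with components \code{low} and \code{high}, each in
#'   [0, 1]; the interval always contains \code{paired/total}.
#' @export
wilson_interval <- function(paired, total, confidence = 0.95) {
  if (any(total < 1)) stop("total must be >= 1")
  if (any(paired < 0) || any(paired > total)) stop("need 0 <= paired <= total")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- paired / total
  n <- total
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Pairing-proportion table with Wilson intervals
#'
#' One row per (species, probe) with the observed pairing proportion and
#' its confidence interval; when a species was scored with two probes, a
#' per-species concordance report (absolute difference between the two
#' probe proportions) is attached, since similar values across probes
#' indicate genome-representative rather than locus-specific behavior.
#'
#' @param observations Data frame with columns species, probe, paired,
#'   total.
#' @param confidence Confidence level for the Wilson intervals.
#' @return Data frame: species, probe, paired, total, proportion,
#'   ci_low, ci_high; attribute \code{concordance} is a data frame
#'   (species, delta) for species with exactly two probes.
#' @export
pairing_table <- function(observations, confidence = 0.95) {
  need <- c("species", "probe", "paired", "total")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(observations) == 0L) {
    out <- data.frame(species = character(), probe = character(),
                      paired = integer(), total = integer(),
                      proportion = numeric(), ci_low = numeric(),
                      ci_high = numeric())
    attr(out, "concordance") <- data.frame(species = character(), delta = numeric())
    return(out)
  }
  key <- paste(observations$species, observations$probe)
  if (anyDuplicated(key)) {
    stop("duplicate (species, probe) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  ci <- wilson_interval(observations$paired, observations$total, confidence)
  out <- data.frame(species = observations$species, probe = observations$probe,
                    paired = observations$paired, total = observations$total,
                    proportion = observations$paired / observations$total,
                    ci_low = ci$low, ci_high = ci$high)
  two <- names(which(table(out$species) == 2L))
  conc <- do.call(rbind, lapply(two, function(sp) {
    pr <- out$proportion[out$species == sp]
    data.frame(species = sp, delta = abs(pr[1] - pr[2]))
  }))
  if (is.null(conc)) conc <- data.frame(species = character(), delta = numeric())
  attr(out, "concordance") <- conc
  out
}

#' Fixed-width window with the most oligos
#'
#' Finds the window [s, s + window_size) maximizing the number of oligo
#' start positions it contains, via a two-pointer sweep over candidate
#' windows anchored at oligo positions (sufficient for optimality of a
#' max-count fixed-length window). Ties are broken by the smallest
#' start. With \code{tiled = TRUE} candidate starts are instead the
#' tiling grid 0, window_size, 2*window_size, ...
#'
#' @param oligo_starts Sorted non-negative oligo start positions
#'   (0-based) on one contig.
#' @param window_size Window width in nt (default 300000, i.e. the
#'   300 kb FISH-target convention).
#' @param contig Contig name carried into the result.
#' @param tiled Use non-overlapping tiled windows instead of sliding
#'   anchored windows.
#' @return List of class \code{window_selection}: contig, span (0-based
#'   half-open), oligo_count, window_size.
#' @export
best_window <- function(oligo_starts, window_size = 300000L,
                        contig = "contig", tiled = FALSE) {
  if (length(oligo_starts) == 0L) stop("no oligo positions supplied")
  if (is.unsorted(oligo_starts)) stop("oligo positions must be sorted ascending")
  if (any(oligo_starts < 0)) stop("oligo positions must be non-negative")
  if (window_size < 1) stop("window_size must be positive")
  p <- oligo_starts
  if (tiled) {
    starts <- seq(0L, max(p), by = window_size)
  } else {
    starts <- p
  }
  # two-pointer: for each candidate start, count positions in [s, s+W)
  counts <- findInterval(starts + window_size - 0.5, p) - findInterval(starts - 0.5, p)
  best <- which.max(counts)   # first maximum = smallest start
  s <- starts[best]
  structure(list(contig = contig,
                 span = c(s, s + window_size),
                 oligo_count = as.integer(counts[best]),
                 window_size = as.integer(window_size)),
            class = "window_selection")
}

#' Read oligo start positions from a BED file
#'
#' Only the chrom and chromStart columns are used.
#'
#' @param path BED file path.
#' @return Named list of sorted start-position vectors, one per contig.
#' @export
read_oligo_bed <- function(path) {
  if (!file.exists(path)) stop("BED file does not exist: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("BED needs at least chrom and chromStart columns")
  lapply(split(tab[[2]], tab[[1]]), sort)
}

#' Write window selections as BED
#'
#' @param windows List of \code{window_selection} objects (or one).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  if (inherits(windows, "window_selection")) windows <- list(windows)
  lines <- vapply(windows, function(w) {
    paste(w$contig, w$span[1], w$span[2], paste0("n_oligos=", w$oligo_count),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
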