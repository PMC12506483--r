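# Linguistic complexity by the alphabet-capacity k-mer method.

#' Linguistic complexity (percent)
#'
#' Ratio of the number of distinct subwords actually observed to the
#' maximum possible for a sequence of that length, summed over word sizes:
#' `LC = 100 * sum_k U_k / sum_k E_k`, where `U_k` is the number of
#' distinct k-words in the sequence and `E_k = min(4^k, L - k + 1)` is the
#' alphabet-capacity bound.  Word sizes run from 1 to `min(L, k_max)`.
#' The default cap of 5 keeps the measure in the range where vocabulary
#' capacity binds at primer scale: words much longer than the capacity
#' crossover are almost surely unique, contribute `U_k = E_k`, and only
#' dilute the ratio toward 100; with the cap at 5, published
#' polypurine-rich primers known to misbehave in PCR score below 70 while
#' typical random-sequence primers score above 80.  100% is maximal
#' complexity; homopolymers score lowest.  Degenerate codes are treated as
#' opaque extra symbols (not expanded), while the capacity bound stays at
#' alphabet size 4.
#'
#' @param seq Sequence (string or `nucleotide_sequence`).
#' @param k_max Largest word size considered (default `min(L, 5)`).
#' @return LC in percent.
#' @examples
#' linguistic_complexity("AAAA")  # 40
#' linguistic_complexity("ACGT")  # 100
#' @export
linguistic_complexity <- function(seq, k_max = 5L) {
  res <- as_residues(seq)
  L <- nchar(res)
  if (L < 1) stop("linguistic_complexity: empty sequence")
  km <- min(L, k_max)
  u <- numeric(km); e <- numeric(km)
  for (k in seq_len(km)) {
    nwords <- L - k + 1L
    u[k] <- length(unique(substring(res, 1:nwords, k:L)))
    e[k] <- min(4^k, nwords)
  }
  100 * sum(u) / sum(e)
}

#' Sliding-window linguistic complexity profile
#'
#' Computes LC in windows along a template and reports low-complexity
#' windows (below `low_threshold`) as merged maskable intervals -- used to
#' flag simple sequence repeats and other low-complexity tracts before
#' primer design.
#'
#' @param seq Sequence (string or `nucleotide_sequence`).
#' @param window Window size, bases (must not exceed sequence length).
#' @param step Step between window starts, bases.
#' @param low_threshold LC percent below which a window is called
#'   low-complexity.
#' @param k_max Passed to [linguistic_complexity()].
#' @return Object of class `complexity_profile`: list with `profile`
#'   (data frame `start`, `end`, `lc`; 1-based inclusive), `low_regions`
#'   (merged intervals of low-LC windows), `window`, `step`,
#'   `low_threshold`.
#' @export
windowed_complexity <- function(seq, window, step = window,
                                low_threshold = 50, k_max = 5L) {
  res <- as_residues(seq)
  L <- nchar(res)
  if (window > L) stop("window (", window, ") exceeds sequence length ", L)
  starts <- seq.int(1L, L - window + 1L, by = step)
  if (starts[length(starts)] + window - 1L < L) {
    starts <- c(starts, L - window + 1L)  # cover the tail
  }
  lc <- vapply(starts, function(s) {
    linguistic_complexity(substr(res, s, s + window - 1L), k_max)
  }, numeric(1))
  prof <- data.frame(start = starts, end = starts + window - 1L, lc = lc)
  low <- prof[prof$lc < low_threshold, , drop = FALSE]
  structure(
    list(profile = prof,
         low_regions = merge_intervals(low$start, low$end),
         window = window, step = step, low_threshold = low_threshold),
    class = "complexity_profile"
  )
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat(sprintf(
    "<complexity_profile> %d windows of %d nt (step %d); LC %.1f-%.1f%%; %d low-complexity region(s) < %g%%\n",
    nrow(x$profile), x$window, x$step, min(x$profile$lc), max(x$profile$lc),
    nrow(x$low_regions), x$low_threshold
  ))
  invisible(x)
}
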