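# De novo repeat identification by k-mer frequency transform, block
# calling with boundary refinement, length-descending clustering by
# k-mer-vector similarity, masking and tab-delimited reports.

# Encode residues as integers 0..3 (non-ACGT -> NA).
encode_acgt <- function(chars) {
  m <- match(chars, c("A", "C", "G", "T")) - 1L
  m
}

# Rolling k-mer codes (base-4) for positions 1..L-k+1; NA where the
# window contains a non-ACGT base.  Also returns the reverse-complement
# codes so canonical k-mers can be formed arithmetically.
kmer_codes <- function(chars, k) {
  b <- encode_acgt(chars)
  L <- length(b)
  n <- L - k + 1L
  if (n < 1L) return(list(fwd = integer(0), rc = integer(0)))
  fwd <- numeric(n); rc <- numeric(n)
  for (j in 0:(k - 1L)) {
    bj <- b[(1L + j):(n + j)]
    fwd <- fwd + bj * 4^(k - 1L - j)
    rc <- rc + (3 - bj) * 4^j
  }
  list(fwd = fwd, rc = rc)
}

#' Per-position k-mer frequency profile
#'
#' Position `i` carries the sequence-wide occurrence count of the
#' canonical k-mer starting at `i` (canonical = the lexicographically
#' smaller of the word and its reverse complement, so inverted copies
#' register).  Positions whose window contains a non-ACGT base count 0.
#'
#' @param seq Sequence (string or `nucleotide_sequence`).
#' @param k Word size (default 12).
#' @return Integer vector of length `L - k + 1`.
#' @export
kmer_frequency_profile <- function(seq, k = 12L) {
  chars <- seq_chars(seq)
  if (length(chars) < k) stop("sequence shorter than k")
  cod <- kmer_codes(chars, k)
  canon <- pmin(cod$fwd, cod$rc)
  ok <- !is.na(canon)
  counts <- integer(length(canon))
  if (any(ok)) {
    u <- match(canon[ok], unique(canon[ok]))
    counts[ok] <- tabulate(u)[u]
  }
  counts
}

#' Call repeat blocks from a k-mer frequency profile
#'
#' Maximal runs of positions whose canonical k-mer occurs at least
#' `min_count` times, with gaps up to `merge_gap` bridged and blocks
#' shorter than `min_block_len` dropped.  Each block's right boundary is
#' extended by `k - 1` bases so the block covers the full extent of its
#' last repeated word.
#'
#' @param profile Integer vector from [kmer_frequency_profile()].
#' @param k Word size used for the profile.
#' @param min_count Minimum occurrence count to call a position repetitive.
#' @param min_block_len Minimum block length (bases) after extension.
#' @param merge_gap Maximum gap (bases) bridged between runs.
#' @return Data frame of class `repeat_blocks`: `start`, `end` (1-based
#'   inclusive), `length`, `peak_kmer_frequency`.
#' @export
call_repeat_blocks <- function(profile, k = 12L, min_count = 2L,
                               min_block_len = 2L * k, merge_gap = k) {
  hot <- profile >= min_count
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs)) {
    runs <- merge_intervals(runs$start, runs$end, gap = merge_gap)
    runs$end <- pmin(runs$end + k - 1L, length(profile) + k - 1L)
    runs <- merge_intervals(runs$start, runs$end)  # extension may join
    runs <- runs[runs$end - runs$start + 1L >= min_block_len, , drop = FALSE]
  }
  if (!nrow(runs)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), peak_kmer_frequency = integer(0))
    class(out) <- c("repeat_blocks", class(out))
    return(out)
  }
  runs$length <- runs$end - runs$start + 1L
  runs$peak_kmer_frequency <- vapply(seq_len(nrow(runs)), function(i) {
    lo <- runs$start[i]; hi <- min(runs$end[i], length(profile))
    max(profile[lo:hi])
  }, integer(1))
  rownames(runs) <- NULL
  class(runs) <- c("repeat_blocks", class(runs))
  runs
}

# 5-mer count vector of a sequence (forward strand, non-canonical).
kmer_count_vector <- function(res, k = 5L) {
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  cod <- kmer_codes(chars, k)$fwd
  cod <- cod[!is.na(cod)]
  v <- numeric(4^k)
  if (length(cod)) {
    t <- table(cod)
    v[as.integer(names(t)) + 1L] <- as.integer(t)
  }
  v
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Cluster repeat blocks by k-mer-vector similarity
#'
#' Blocks are sorted by length descending and clustered greedily: each
#' block joins the first existing cluster whose representative (its
#' longest, founding member) has cosine similarity of `kv`-mer count
#' vectors at least `sim_threshold` in either orientation; otherwise it
#' founds a new cluster.  Member orientation is the argmax of forward vs.
#' reverse-complement similarity.
#'
#' @param blocks `repeat_blocks` data frame.
#' @param seq The sequence the blocks were called on.
#' @param sim_threshold Cosine similarity threshold (default 0.7).
#' @param kv Word size of the count vectors (default 5).
#' @return Data frame of class `repeat_clusters`: block coordinates plus
#'   `cluster`, `strand` (orientation vs. the representative),
#'   `similarity`, `sequence`; members sorted by cluster then length
#'   descending.
#' @export
cluster_blocks <- function(blocks, seq, sim_threshold = 0.7, kv = 5L) {
  res <- as_residues(seq)
  blocks <- blocks[order(-(blocks$end - blocks$start)), , drop = FALSE]
  n <- nrow(blocks)
  cluster <- integer(n); strand <- character(n); simv <- numeric(n)
  seqs <- substring(res, blocks$start, blocks$end)
  reps <- list()   # representative count vectors per cluster
  for (i in seq_len(n)) {
    vf <- kmer_count_vector(seqs[i], kv)
    vr <- kmer_count_vector(reverse_complement(seqs[i]), kv)
    placed <- FALSE
    for (ci in seq_along(reps)) {
      sf <- cosine_sim(reps[[ci]], vf)
      sr <- cosine_sim(reps[[ci]], vr)
      if (max(sf, sr) >= sim_threshold) {
        cluster[i] <- ci
        strand[i] <- if (sf >= sr) "+" else "-"
        simv[i] <- max(sf, sr)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- vf
      cluster[i] <- length(reps)
      strand[i] <- "+"
      simv[i] <- 1
    }
  }
  out <- data.frame(cluster = cluster, start = blocks$start,
                    end = blocks$end,
                    length = blocks$end - blocks$start + 1L,
                    strand = strand, similarity = simv,
                    sequence = seqs, stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -out$length), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_clusters", class(out))
  out
}

#' Mask repeat blocks in a sequence
#'
#' @param seq Sequence (string or `nucleotide_sequence`).
#' @param blocks Data frame with `start`/`end` (1-based inclusive).
#' @param mode `"N"` (hard mask) or `"lowercase"` (soft mask).
#' @return Same type as the input; idempotent.
#' @export
mask_sequence <- function(seq, blocks, mode = c("N", "lowercase")) {
  mode <- match.arg(mode)
  is_obj <- inherits(seq, "nucleotide_sequence")
  res <- if (is_obj) seq$residues else paste(seq, collapse = "")
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(blocks))) {
    ii <- blocks$start[i]:blocks$end[i]
    chars[ii] <- if (mode == "N") "N" else tolower(chars[ii])
  }
  out <- paste(chars, collapse = "")
  if (is_obj) {
    seq$residues <- out
    seq
  } else out
}

#' Write a repeat cluster report
#'
#' Tab-delimited file, one row per cluster member: cluster id, start, end
#' (1-based inclusive), orientation, sequence; clusters in founding
#' order, members by length descending.
#'
#' @param clusters `repeat_clusters` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_repeat_report <- function(clusters, path) {
  utils::write.table(
    clusters[, c("cluster", "start", "end", "strand", "sequence")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Identify, cluster and mask repeats in one call
#'
#' @param seq Sequence (string or `nucleotide_sequence`).
#' @param k Word size for the frequency transform.
#' @param min_count,min_block_len,merge_gap Passed to
#'   [call_repeat_blocks()].
#' @param sim_threshold Passed to [cluster_blocks()].
#' @return List of class `repeat_report`: `blocks`, `clusters`, `masked`
#'   (hard-masked sequence).
#' @export
find_repeats <- function(seq, k = 12L, min_count = 2L,
                         min_block_len = 2L * k, merge_gap = k,
                         sim_threshold = 0.7) {
  profile <- kmer_frequency_profile(seq, k)
  blocks <- call_repeat_blocks(profile, k, min_count, min_block_len,
                               merge_gap)
  clusters <- cluster_blocks(blocks, seq, sim_threshold)
  structure(list(blocks = blocks, clusters = clusters,
                 masked = mask_sequence(seq, blocks, "N"), k = k),
            class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(sprintf("<repeat_report> %d block(s) in %d cluster(s), k = %d\n",
              nrow(x$blocks), length(unique(x$clusters$cluster)), x$k))
  invisible(x)
}

# Mask intervals used by primer design "non-specific priming control":
# repeat blocks plus low-complexity windows.
design_mask_intervals <- function(seq, k = 12L, lc_window = 30L,
                                  lc_threshold = 50) {
  res <- as_residues(seq)
  L <- nchar(res)
  blocks <- if (L >= k + 1L) {
    call_repeat_blocks(kmer_frequency_profile(res, k), k)
  } else data.frame(start = integer(0), end = integer(0))
  low <- if (L >= lc_window) {
    windowed_complexity(res, lc_window, step = max(1L, lc_window %/% 3L),
                        low_threshold = lc_threshold)$low_regions
  } else data.frame(start = integer(0), end = integer(0))
  merge_intervals(c(blocks$start, low$start), c(blocks$end, low$end))
}
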