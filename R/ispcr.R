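# In silico PCR: k-mer seeded binding-site search with mismatch-tolerant
# gapless extension, amplicon prediction on linear and circular templates,
# and short-oligo (miRNA/gRNA) screening.

# Does primer base p (possibly degenerate/inosine) match template base t?
base_match_vec <- function(ps, ts) {
  MATCH_MAT[cbind(ps, ts)]
}

#' Mismatch policy for in silico PCR
#'
#' Defaults encode the observation that mismatches matter most near the
#' primer 3' end: at most 3 total mismatches, at most 1 inside the
#' 3'-terminal 12 bases, and the last two 3' bases must match.
#'
#' @param max_total_mm Maximum mismatches over the template-aligned part
#'   of the primer (5' tails excluded).
#' @param max_3prime_mm Maximum mismatches within the 3'-terminal 12
#'   bases.
#' @param terminal2_must_match Must the two 3'-terminal bases match?
#' @param seed_word Seed word size for the hash index.
#' @return List of class `ispcr_policy`.
#' @export
ispcr_policy <- function(max_total_mm = 3L, max_3prime_mm = 1L,
                         terminal2_must_match = TRUE, seed_word = 12L) {
  structure(list(max_total_mm = max_total_mm,
                 max_3prime_mm = max_3prime_mm,
                 terminal2_must_match = terminal2_must_match,
                 seed_word = seed_word),
            class = "ispcr_policy")
}

#' Build a seed index of a template
#'
#' Hash index mapping every `word`-mer of the template (plus strand) to
#' its start positions.  Lookups tolerate one mismatch by querying the
#' word and its 3*word single-substitution neighbors.  Templates shorter
#' than the word size fall back to naive scanning (flagged).
#'
#' @param template Template sequence (string or `nucleotide_sequence`).
#' @param word Word size (default 12).
#' @return Object of class `seed_index`.
#' @export
build_seed_index <- function(template, word = 12L) {
  res <- as_residues(template)
  L <- nchar(res)
  if (L < word) {
    return(structure(list(residues = res, word = word, map = list(),
                          naive = TRUE, L = L), class = "seed_index"))
  }
  starts <- 1:(L - word + 1L)
  words <- substring(res, starts, starts + word - 1L)
  structure(list(residues = res, word = word,
                 map = split(starts, words), naive = FALSE, L = L),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d nt template, %d-mer index (%d distinct words)%s\n",
              x$L, x$word, length(x$map),
              if (x$naive) " [naive fallback]" else ""))
  invisible(x)
}

#' Look up seed positions tolerating up to one mismatch
#'
#' @param index A [build_seed_index()] object.
#' @param w Query word (length equal to the index word size).
#' @return Sorted integer vector of template start positions where `w` or
#'   a single-substitution neighbor of `w` occurs.
#' @export
lookup_seed <- function(index, w) {
  if (nchar(w) != index$word) stop("query length != index word size")
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  variants <- w
  for (i in seq_along(chars)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      v <- chars; v[i] <- b
      variants <- c(variants, paste(v, collapse = ""))
    }
  }
  sort(unique(unlist(index$map[variants], use.names = FALSE)))
}

# Evaluate a primer aligned with its 3' end at plus-coordinate `e` of
# `target` (a plain residue string).  Returns a one-row data frame or NULL.
score_alignment <- function(pchars, target_chars, e, policy) {
  plen <- length(pchars)
  a_start <- e - plen + 1L
  tail_len <- max(0L, 1L - a_start)        # 5' overhang beyond target start
  # the critical 3'-terminal stretch (up to 12 nt) must lie on the template
  if (e > length(target_chars) || plen - tail_len < min(plen, 12L)) {
    return(NULL)
  }
  pal <- pchars[(tail_len + 1L):plen]
  tal <- target_chars[(a_start + tail_len):e]
  ok <- base_match_vec(pal, tal)
  mm <- sum(!ok)
  if (mm > policy$max_total_mm) return(NULL)
  k3 <- min(length(pal), 12L)
  mm3 <- sum(!ok[(length(ok) - k3 + 1L):length(ok)])
  if (mm3 > policy$max_3prime_mm) return(NULL)
  term2_mm <- !all(ok[(length(ok) - 1L):length(ok)])
  if (policy$terminal2_must_match && term2_mm) return(NULL)
  data.frame(
    start = a_start + tail_len, end = e,
    total_mismatches = mm, three_prime_mismatches = mm3,
    terminal2_mismatch = term2_mm, tail_len = tail_len,
    similarity = 100 * sum(ok) / length(ok)
  )
}

#' Find primer binding sites on a template
#'
#' Each primer's 3'-terminal 12-mer is queried against the seed index of
#' both template strands (tolerating one seed mismatch), each seed hit is
#' extended 5'-ward by gapless alignment, and the resulting site is kept
#' when it satisfies the mismatch policy.  5' tails (primer prefixes
#' overhanging the template) are permitted and excluded from mismatch
#' counts.  Primers shorter than the seed word are screened by a naive
#' full scan.  Sites with two or more mismatches inside the 3' 12-mer are
#' only found in naive mode -- a documented sensitivity bound of the seed
#' design.
#'
#' @param primers Named character vector (or list) of primer sequences.
#' @param template Template (string or `nucleotide_sequence`); circularity
#'   is honored when a `nucleotide_sequence` has `circular = TRUE`.
#' @param policy [ispcr_policy()].
#' @param cond [thermo_conditions()] for the per-site duplex Tm.
#' @param max_sites_per_primer Explosion guard: a primer yielding more
#'   sites triggers a warning naming the primer and its count (sites are
#'   kept; downstream pairing truncates).
#' @return Data frame: `primer_id`, `strand` (`+`: primer matches the
#'   plus strand and extends rightward), `start`, `end` (1-based plus
#'   strand footprint of the aligned region), `three_prime_pos`,
#'   `total_mismatches`, `three_prime_mismatches`, `terminal2_mismatch`,
#'   `tail_len`, `similarity`, `site_tm`.
#' @export
find_binding_sites <- function(primers, template, policy = ispcr_policy(),
                               cond = thermo_conditions(),
                               max_sites_per_primer = 10000L) {
  if (is.list(primers)) {
    primers <- vapply(primers, as_residues, character(1))
  }
  if (is.null(names(primers)) || any(!nzchar(names(primers)))) {
    names(primers) <- paste0("primer", seq_along(primers))
  }
  circular <- inherits(template, "nucleotide_sequence") && template$circular
  plus <- as_residues(template)
  L <- nchar(plus)
  strands <- list(`+` = plus, `-` = reverse_complement(plus))
  word <- policy$seed_word
  out <- list()
  for (sgn in names(strands)) {
    target <- strands[[sgn]]
    # circular templates: extend by a wrap margin so origin-spanning
    # sites are seen; mapped coordinates are folded back below.
    margin <- if (circular) min(L, max(nchar(primers)) + word) else 0L
    target_ext <- if (margin > 0L) {
      paste0(target, substr(target, 1L, margin))
    } else target
    tchars <- strsplit(target_ext, "", fixed = TRUE)[[1]]
    index <- build_seed_index(target_ext, word)
    for (pid in names(primers)) {
      pres <- as_residues(primers[[pid]])
      pchars <- strsplit(pres, "", fixed = TRUE)[[1]]
      plen <- length(pchars)
      if (plen >= word && !index$naive) {
        seed <- substr(pres, plen - word + 1L, plen)
        ends <- lookup_seed(index, seed) + word - 1L
      } else {
        ends <- seq_len(nchar(target_ext))
      }
      ends <- ends[ends <= L + (if (circular) plen else 0L)]
      hits <- lapply(ends, score_alignment, pchars = pchars,
                     target_chars = tchars, policy = policy)
      hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
      if (is.null(hits) || !nrow(hits)) next
      # fold extended coordinates and map minus-strand coords to plus
      if (sgn == "+") {
        hits$three_prime_pos <- (hits$end - 1L) %% L + 1L
        st <- hits$start; en <- hits$end
      } else {
        st <- L - ((hits$end - 1L) %% L + 1L) + 1L
        en <- st + (hits$end - hits$start)
        hits$three_prime_pos <- st
      }
      hits$start <- (st - 1L) %% L + 1L
      hits$end <- (en - 1L) %% L + 1L
      if (!circular) {
        keep <- hits$start <= hits$end
        hits <- hits[keep, , drop = FALSE]
      }
      if (!nrow(hits)) next
      hits <- hits[!duplicated(hits[c("start", "end")]), , drop = FALSE]
      hits$primer_id <- pid
      hits$strand <- sgn
      hits$site_tm <- vapply(seq_len(nrow(hits)), function(r) {
        al_len <- plen - hits$tail_len[r]
        pal <- pchars[(hits$tail_len[r] + 1L):plen]
        seg <- if (sgn == "+") {
          substr_circular(plus, hits$start[r], al_len, circular)
        } else {
          reverse_complement(
            substr_circular(plus, hits$start[r], al_len, circular))
        }
        bot <- unname(COMPLEMENT_DNA[strsplit(seg, "", fixed = TRUE)[[1]]])
        duplex_tm_vec(pal, bot, cond)
      }, numeric(1))
      if (nrow(hits) > max_sites_per_primer) {
        warning(sprintf(
          "primer '%s' has %d binding sites (> %d): repeat-region hit explosion",
          pid, nrow(hits), max_sites_per_primer))
      }
      out[[length(out) + 1L]] <- hits
    }
  }
  cols <- c("primer_id", "strand", "start", "end", "three_prime_pos",
            "total_mismatches", "three_prime_mismatches",
            "terminal2_mismatch", "tail_len", "similarity", "site_tm")
  if (!length(out)) {
    empty <- data.frame(primer_id = character(0), strand = character(0),
                        start = integer(0), end = integer(0),
                        three_prime_pos = integer(0),
                        total_mismatches = integer(0),
                        three_prime_mismatches = integer(0),
                        terminal2_mismatch = logical(0),
                        tail_len = integer(0), similarity = numeric(0),
                        site_tm = numeric(0))
    return(empty)
  }
  res <- do.call(rbind, out)[, cols]
  rownames(res) <- NULL
  res[order(res$primer_id, res$strand, res$start), , drop = FALSE]
}

# Substring of length `len` starting at `start`, wrapping when circular.
substr_circular <- function(res, start, len, circular = FALSE) {
  L <- nchar(res)
  if (!circular || start + len - 1L <= L) {
    return(substr(res, start, start + len - 1L))
  }
  paste0(substr(res, start, L), substr(res, 1L, start + len - 1L - L))
}

#' Predict PCR amplicons from binding sites
#'
#' Pairs every convergent (+, -) site combination whose product size lies
#' within bounds.  On circular templates origin-spanning products are
#' allowed; `multiplex = TRUE` pairs sites across all primers, otherwise
#' only (+)/(-) sites of one and the same primer are paired
#' (single-primer amplification).
#'
#' @param sites Data frame from [find_binding_sites()].
#' @param template Template used for the search.
#' @param size Length-2 numeric, product size bounds in bp.
#' @param multiplex Pair across all primers?
#' @param max_pairings Explosion guard on the (+) x (-) combination count.
#' @return Data frame: `forward_primer`, `reverse_primer`, `start`, `end`,
#'   `length`, `wrapped`, `mode`, `sequence` (tails excluded),
#'   `total_mismatches` (sum of both sites).
#' @export
predict_amplicons <- function(sites, template, size = c(50, 5000),
                              multiplex = TRUE, max_pairings = 1e6) {
  circular <- inherits(template, "nucleotide_sequence") && template$circular
  res <- as_residues(template)
  L <- nchar(res)
  fw <- sites[sites$strand == "+", , drop = FALSE]
  rv <- sites[sites$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(fw) && nrow(rv) && nrow(fw) * nrow(rv) <= max_pairings) {
    for (i in seq_len(nrow(fw))) {
      for (j in seq_len(nrow(rv))) {
        if (!multiplex && fw$primer_id[i] != rv$primer_id[j]) next
        a <- fw$start[i]; b <- rv$end[j]
        wrapped <- FALSE
        if (fw$three_prime_pos[i] <= rv$three_prime_pos[j] && a <= b) {
          len <- b - a + 1L
        } else if (circular) {
          len <- (L - a + 1L) + b
          wrapped <- TRUE
        } else next
        if (len < size[1] || len > size[2]) next
        seqn <- if (!wrapped) substr(res, a, b)
                else paste0(substr(res, a, L), substr(res, 1L, b))
        out[[length(out) + 1L]] <- data.frame(
          forward_primer = fw$primer_id[i], reverse_primer = rv$primer_id[j],
          start = a, end = b, length = len, wrapped = wrapped,
          mode = if (wrapped) "circular-wrapped" else "standard",
          sequence = seqn,
          total_mismatches = fw$total_mismatches[i] + rv$total_mismatches[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(forward_primer = character(0),
                      reverse_primer = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      wrapped = logical(0), mode = character(0),
                      sequence = character(0),
                      total_mismatches = integer(0)))
  }
  amp <- do.call(rbind, out)
  amp[order(amp$start, amp$length), , drop = FALSE]
}

#' In silico PCR in one call
#'
#' @inheritParams find_binding_sites
#' @inheritParams predict_amplicons
#' @return List with `sites` and `amplicons`.
#' @export
in_silico_pcr <- function(primers, template, policy = ispcr_policy(),
                          size = c(50, 5000), multiplex = TRUE,
                          cond = thermo_conditions()) {
  sites <- find_binding_sites(primers, template, policy, cond)
  list(sites = sites,
       amplicons = predict_amplicons(sites, template, size, multiplex))
}

#' Screen a short oligo (miRNA / guide RNA) against a template
#'
#' Full-length Hamming-distance search on both strands with no 5' tails;
#' the tolerated mismatch count must not exceed three.
#'
#' @param oligo Oligo sequence (typically 18-30 nt; U is accepted and
#'   matched as T).
#' @param template Template sequence.
#' @param max_mm Maximum tolerated mismatches (1-3).
#' @return Data frame in the [find_binding_sites()] site format.
#' @export
screen_short_oligo <- function(oligo, template, max_mm = 3L) {
  if (max_mm < 1L || max_mm > 3L) {
    stop("max_mm must be between 1 and 3 (high mismatch counts are not ",
         "informative for short-oligo screening)")
  }
  ores <- chartr("U", "T", as_residues(oligo))
  plen <- nchar(ores)
  pchars <- strsplit(ores, "", fixed = TRUE)[[1]]
  plus <- as_residues(template)
  L <- nchar(plus)
  if (plen > L) stop("oligo longer than template")
  out <- list()
  for (sgn in c("+", "-")) {
    target <- if (sgn == "+") plus else reverse_complement(plus)
    tchars <- strsplit(target, "", fixed = TRUE)[[1]]
    for (st in 1:(L - plen + 1L)) {
      ok <- base_match_vec(pchars, tchars[st:(st + plen - 1L)])
      mm <- sum(!ok)
      if (mm > max_mm) next
      ps <- if (sgn == "+") st else L - (st + plen - 1L) + 1L
      out[[length(out) + 1L]] <- data.frame(
        primer_id = "oligo", strand = sgn, start = ps,
        end = ps + plen - 1L,
        three_prime_pos = if (sgn == "+") ps + plen - 1L else ps,
        total_mismatches = mm,
        three_prime_mismatches = sum(!ok[max(1L, plen - 11L):plen]),
        terminal2_mismatch = !all(ok[(plen - 1L):plen]),
        tail_len = 0L, similarity = 100 * sum(ok) / plen,
        site_tm = NA_real_, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(find_binding_sites(character(0), template))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$start), , drop = FALSE]
}
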