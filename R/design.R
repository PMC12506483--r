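# Candidate primer enumeration, quality filtering, pair assembly and
# ranking, hydrolysis probe design; standard, inverse and bisulfite modes.

#' Primer design constraints
#'
#' @param primer_len Length-2 integer, candidate primer length range
#'   (bases); hard bounds 15-35.
#' @param tm_range Length-2 numeric, acceptable primer Tm window, degrees
#'   C.
#' @param lc_min Minimum linguistic complexity, percent.
#' @param gc_range Length-2 numeric, acceptable GC percent range.
#' @param product_size Length-2 numeric, PCR product size bounds, bp.
#' @param pair_tm_gap_max Maximum |Tm difference| within a pair, degrees
#'   C.
#' @param allow_overlapping_candidates Keep overlapping candidate windows?
#' @param mode `"standard"`, `"inverse"` (circular template, product
#'   spans the origin) or `"bisulfite"` (design on the converted strand).
#' @param rank_weights Named weights of the pair score components
#'   (`lc`, `dtm`, `end3`, `gc`, `size`).
#' @param max_candidates_per_strand Deterministic cap on candidates kept
#'   per strand (best Tm-centrality first) to bound pairing cost.
#' @return List of class `design_constraints`.
#' @export
design_constraints <- function(primer_len = c(18L, 22L),
                               tm_range = c(60, 62), lc_min = 75,
                               gc_range = c(40, 60),
                               product_size = c(100, 300),
                               pair_tm_gap_max = 3,
                               allow_overlapping_candidates = TRUE,
                               mode = c("standard", "inverse", "bisulfite"),
                               rank_weights = c(lc = 0.30, dtm = 0.25,
                                                end3 = 0.20, gc = 0.15,
                                                size = 0.10),
                               max_candidates_per_strand = 120L) {
  mode <- match.arg(mode)
  primer_len <- pmin(pmax(as.integer(primer_len), 15L), 35L)
  stopifnot(primer_len[1] <= primer_len[2],
            tm_range[1] <= tm_range[2],
            diff(range(tm_range)) >= 1 || TRUE,
            gc_range[1] <= gc_range[2],
            product_size[1] <= product_size[2])
  structure(list(primer_len = primer_len, tm_range = tm_range,
                 lc_min = lc_min, gc_range = gc_range,
                 product_size = product_size,
                 pair_tm_gap_max = pair_tm_gap_max,
                 allow_overlapping_candidates = allow_overlapping_candidates,
                 mode = mode, rank_weights = rank_weights,
                 max_candidates_per_strand = max_candidates_per_strand),
            class = "design_constraints")
}

# G-quadruplex motif intervals on either strand: >= 4 runs of >= 3 G
# separated by loops of 1-7 nt (and the C-strand mirror).
find_gquad_intervals <- function(res) {
  pat_g <- "G{3,}([ACGTU]{1,7}G{3,}){3,}"
  pat_c <- "C{3,}([ACGTU]{1,7}C{3,}){3,}"
  out <- list()
  for (pat in c(pat_g, pat_c)) {
    m <- gregexpr(pat, res, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  do.call(rbind, out)
}

# Fast window Tm for a pure-ACGT template: cumulative NN sums; falls back
# to NA for windows containing other characters (screened exactly later).
window_tm_fast <- function(chars, starts, len, cond) {
  L <- length(chars)
  keys <- paste0(chars[-L], chars[-1])
  dh_step <- unname(NN_DH[keys]); ds_step <- unname(NN_DS[keys])
  cdh <- c(0, cumsum(ifelse(is.na(dh_step), 0, dh_step)))
  cds <- c(0, cumsum(ifelse(is.na(ds_step), 0, ds_step)))
  bad_step <- is.na(dh_step)
  cbad <- c(0, cumsum(bad_step))
  is_gc <- chars %in% c("G", "C")
  cgc <- c(0, cumsum(is_gc))
  ends <- starts + len - 1L
  dh <- cdh[ends] - cdh[starts]
  ds <- cds[ends] - cds[starts]
  nbad <- cbad[ends] - cbad[starts]
  term_gc1 <- is_gc[starts]; term_gc2 <- is_gc[ends]
  dh <- dh + ifelse(term_gc1, NN_INIT_DH[["GC"]], NN_INIT_DH[["AT"]]) +
    ifelse(term_gc2, NN_INIT_DH[["GC"]], NN_INIT_DH[["AT"]])
  ds <- ds + ifelse(term_gc1, NN_INIT_DS[["GC"]], NN_INIT_DS[["AT"]]) +
    ifelse(term_gc2, NN_INIT_DS[["GC"]], NN_INIT_DS[["AT"]])
  cf <- cond$oligo_conc * 1e-9 / 4
  tm_1m <- 1000 * dh / (ds + GAS_CONSTANT * log(cf))
  f_gc <- (cgc[ends + 1L] - cgc[starts]) / len
  tm <- salt_correct_tm(tm_1m, f_gc, sodium_equivalent(cond)) - 273.15
  tm[nbad > 0] <- NA_real_
  list(tm = tm, gc = 100 * f_gc)
}

#' Enumerate candidate primers on a template
#'
#' Slides windows of every allowed length over both strands, keeping
#' windows that satisfy the Tm/GC/LC bounds, do not intersect masked
#' intervals, do not cover a G-quadruplex motif, and pass the self-dimer
#' filter.  When bracket regions are supplied, forward candidates are
#' restricted to `forward-zone` regions and reverse candidates to
#' `reverse-zone` regions.
#'
#' @param template Template (string or `nucleotide_sequence`).
#' @param constraints [design_constraints()].
#' @param masked Optional data frame of masked intervals
#'   (`start`, `end`, 1-based inclusive).
#' @param regions Optional bracket-region data frame
#'   (`start`, `end`, `role`) from [extract_bracket_regions()].
#' @param cond [thermo_conditions()].
#' @return Data frame (possibly 0 rows) of candidates: `name`,
#'   `sequence`, `start`, `end` (template coordinates of the footprint,
#'   1-based), `strand`, `length`, `tm`, `gc`, `lc`.  Attribute
#'   `rejections` holds per-filter rejection counts; when no candidate
#'   survives the attribute explains why ("no primers found").
#' @export
generate_candidates <- function(template, constraints = design_constraints(),
                                masked = NULL, regions = NULL,
                                cond = thermo_conditions()) {
  res <- as_residues(template)
  L <- nchar(res)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  gq <- find_gquad_intervals(res)
  rej <- c(tm = 0L, gc = 0L, lc = 0L, masked = 0L, gquad = 0L,
           self_dimer = 0L)
  rows <- list()
  for (strand in c("+", "-")) {
    zone <- NULL
    if (!is.null(regions) && nrow(regions)) {
      role <- if (strand == "+") "forward-zone" else "reverse-zone"
      zone <- regions[regions$role %in% c(role), , drop = FALSE]
      if (!nrow(zone)) zone <- NULL
    }
    for (len in constraints$primer_len[1]:constraints$primer_len[2]) {
      if (len > L) next
      starts <- 1:(L - len + 1L)
      ft <- window_tm_fast(chars, starts, len, cond)
      ok <- !is.na(ft$tm) &
        ft$tm >= constraints$tm_range[1] & ft$tm <= constraints$tm_range[2]
      rej[["tm"]] <- rej[["tm"]] + sum(!ok)
      gok <- ft$gc >= constraints$gc_range[1] &
        ft$gc <= constraints$gc_range[2]
      rej[["gc"]] <- rej[["gc"]] + sum(ok & !gok)
      ok <- ok & gok
      if (!is.null(zone)) {
        inz <- rep(FALSE, length(starts))
        for (zi in seq_len(nrow(zone))) {
          inz <- inz | (starts >= zone$start[zi] &
                          starts + len - 1L <= zone$end[zi])
        }
        ok <- ok & inz
      }
      for (s in starts[ok]) {
        e <- s + len - 1L
        if (!is.null(masked) && nrow(masked) &&
            any(intervals_overlap(masked$start, masked$end, s, e))) {
          rej[["masked"]] <- rej[["masked"]] + 1L
          next
        }
        if (nrow(gq) && any(intervals_overlap(gq$start, gq$end, s, e))) {
          rej[["gquad"]] <- rej[["gquad"]] + 1L
          next
        }
        w <- substr(res, s, e)
        sq <- if (strand == "+") w else reverse_complement(w)
        lc <- linguistic_complexity(sq)
        if (lc < constraints$lc_min) {
          rej[["lc"]] <- rej[["lc"]] + 1L
          next
        }
        tm_exact <- melting_temperature(sq, cond)
        if (tm_exact < constraints$tm_range[1] ||
            tm_exact > constraints$tm_range[2]) {
          rej[["tm"]] <- rej[["tm"]] + 1L
          next
        }
        if (!passes_dimer_filter(sq, sq, cond = cond)$pass) {
          rej[["self_dimer"]] <- rej[["self_dimer"]] + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s%d_%d", if (strand == "+") "F" else "R", s, len),
          sequence = sq, start = s, end = e, strand = strand,
          length = len, tm = tm_exact, gc = gc_content(sq), lc = lc,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(name = character(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      tm = numeric(0), gc = numeric(0), lc = numeric(0))
    attr(out, "rejections") <- rej
    attr(out, "message") <- "no primers found"
    return(out)
  }
  out <- do.call(rbind, rows)
  if (!constraints$allow_overlapping_candidates) {
    keep <- logical(nrow(out))
    for (strand in c("+", "-")) {
      idx <- which(out$strand == strand)
      idx <- idx[order(out$start[idx])]
      last_end <- -1L
      for (i in idx) {
        if (out$start[i] > last_end) {
          keep[i] <- TRUE
          last_end <- out$end[i]
        }
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  # deterministic cap: prefer Tm closest to the window center
  tm_mid <- mean(constraints$tm_range)
  cap <- constraints$max_candidates_per_strand
  out <- do.call(rbind, lapply(c("+", "-"), function(strand) {
    sub <- out[out$strand == strand, , drop = FALSE]
    if (nrow(sub) > cap) {
      sub <- sub[order(abs(sub$tm - tm_mid), sub$start, sub$length), ,
                 drop = FALSE][1:cap, ]
    }
    sub[order(sub$start, sub$length), , drop = FALSE]
  }))
  rownames(out) <- NULL
  attr(out, "rejections") <- rej
  out
}

# 3'-end stability proxy: GC fraction of the five 3'-terminal bases.
end3_gc <- function(sq) {
  n <- nchar(sq)
  tail <- substr(sq, max(1L, n - 4L), n)
  gc_content(tail) / 100
}

#' Design ranked primer pairs on a template
#'
#' Enumerates candidates on both strands ([generate_candidates()]),
#' assembles all cross-compatible combinations (product size within
#' bounds, |Tm difference| within `pair_tm_gap_max`, cross-dimer filter
#' passed), computes the annealing temperature and product Tm for each,
#' and returns them ranked by a weighted quality score (mean LC, Tm
#' balance, 3'-end stability, GC mid-range, product-size centrality).
#' Ties break deterministically by leftmost forward start, then shortest
#' product.  With `mode = "inverse"` (circular templates) products span
#' the origin; with `mode = "bisulfite"` design runs on the
#' plus-strand-converted template and primers whose 3' end sits on a
#' preserved CpG base are excluded.
#'
#' When `repeat_control = TRUE` (default), repeat blocks and
#' low-complexity tracts of the template are masked before enumeration so
#' no primer overlaps them.
#'
#' @inheritParams generate_candidates
#' @param repeat_control Mask repeats/low-complexity regions first?
#' @param max_pairs Maximum number of pairs returned.
#' @return Data frame of class `primer_pairs`, ranked: forward and
#'   reverse primer columns (prefixed `f_`/`r_`), `product_len`,
#'   `product_gc`, `ta`, `product_tm`, `rank_score`, `mode`.  Attributes:
#'   `template_used` (residues the design ran on -- the converted strand
#'   in bisulfite mode), `candidates`, `rejections`, and `reasons` when
#'   empty.
#' @export
design_pairs <- function(template, constraints = design_constraints(),
                         masked = NULL, regions = NULL,
                         repeat_control = TRUE,
                         cond = thermo_conditions(), max_pairs = 50L) {
  circular <- inherits(template, "nucleotide_sequence") && template$circular
  res <- as_residues(template)
  if (constraints$mode == "inverse" && !circular) {
    stop("inverse mode requires a circular template")
  }
  cpg_plus <- integer(0)
  if (constraints$mode == "bisulfite") {
    res <- bisulfite_convert(res, "plus")
    # every C left after conversion is a CpG cytosine; its partner G
    # (position + 1) is the CpG base seen by minus-strand primers
    cpg_plus <- which(strsplit(res, "", fixed = TRUE)[[1]] == "C")
  }
  if (repeat_control) {
    auto_mask <- design_mask_intervals(res)
    masked <- if (is.null(masked)) auto_mask else {
      merge_intervals(c(masked$start, auto_mask$start),
                      c(masked$end, auto_mask$end))
    }
  }
  cands <- generate_candidates(res, constraints, masked, regions, cond)
  if (constraints$mode == "bisulfite" && nrow(cands)) {
    bad3 <- (cands$strand == "+" & cands$end %in% cpg_plus) |
      (cands$strand == "-" & cands$start %in% (cpg_plus + 1L))
    cands <- cands[!bad3, , drop = FALSE]
  }
  fwd <- cands[cands$strand == "+", , drop = FALSE]
  rev <- cands[cands$strand == "-", , drop = FALSE]
  empty_pairs <- function(reason) {
    out <- data.frame()
    class(out) <- c("primer_pairs", class(out))
    attr(out, "reasons") <- reason
    attr(out, "rejections") <- attr(cands, "rejections")
    attr(out, "template_used") <- res
    attr(out, "candidates") <- cands
    out
  }
  if (!nrow(fwd) || !nrow(rev)) {
    return(empty_pairs("no candidates on one or both strands"))
  }
  L <- nchar(res)
  w <- constraints$rank_weights
  size_mid <- mean(constraints$product_size)
  size_half <- max(diff(constraints$product_size) / 2, 1)
  # vectorized pre-screen of all combinations (size, Tm balance, zones)
  cmb <- expand.grid(i = seq_len(nrow(fwd)), j = seq_len(nrow(rev)))
  if (constraints$mode == "inverse") {
    ok <- fwd$start[cmb$i] > rev$end[cmb$j]
    plen <- (L - fwd$start[cmb$i] + 1L) + rev$end[cmb$j]
  } else {
    plen <- rev$end[cmb$j] - fwd$start[cmb$i] + 1L
    ok <- plen >= fwd$length[cmb$i] + rev$length[cmb$j]
  }
  ok <- ok & plen >= constraints$product_size[1] &
    plen <= constraints$product_size[2]
  if (!is.null(regions) && nrow(regions) && constraints$mode != "inverse") {
    amp <- regions[regions$role == "amplify-inside", , drop = FALSE]
    for (ai in seq_len(nrow(amp))) {
      ok <- ok & fwd$end[cmb$i] < amp$start[ai] &
        rev$start[cmb$j] > amp$end[ai]
    }
  }
  dtm <- abs(fwd$tm[cmb$i] - rev$tm[cmb$j])
  ok <- ok & dtm <= constraints$pair_tm_gap_max
  n_prescreen <- sum(ok)
  if (!n_prescreen) {
    return(empty_pairs("no size/Tm-compatible combinations"))
  }
  cmb <- cmb[ok, , drop = FALSE]
  plen <- plen[ok]; dtm <- dtm[ok]
  f_end3 <- vapply(fwd$sequence, end3_gc, numeric(1))
  r_end3 <- vapply(rev$sequence, end3_gc, numeric(1))
  score <-
    w[["lc"]] * (fwd$lc[cmb$i] + rev$lc[cmb$j]) / 200 +
    w[["dtm"]] * (1 - dtm / max(constraints$pair_tm_gap_max, 1)) +
    w[["end3"]] * (1 - (f_end3[cmb$i] + r_end3[cmb$j]) / 2) +
    w[["gc"]] * (1 - (abs(fwd$gc[cmb$i] - 50) +
                        abs(rev$gc[cmb$j] - 50)) / 100) +
    w[["size"]] * pmax(0, 1 - abs(plen - size_mid) / size_half)
  # rank first, dimer-screen in rank order, stop once max_pairs accepted
  # (the dimer filter does not enter the score, so this yields the same
  # top of the ranking as screening everything)
  ord <- order(-score, fwd$start[cmb$i], plen, rev$start[cmb$j])
  rows <- list()
  for (r in ord) {
    i <- cmb$i[r]; j <- cmb$j[r]
    if (!passes_dimer_filter(fwd$sequence[i], rev$sequence[j],
                             cond = cond)$pass) next
    pseq <- if (constraints$mode == "inverse") {
      paste0(substr(res, fwd$start[i], L), substr(res, 1L, rev$end[j]))
    } else {
      substr(res, fwd$start[i], rev$end[j])
    }
    pgc <- gc_content(pseq)
    rows[[length(rows) + 1L]] <- data.frame(
      f_name = fwd$name[i], f_sequence = fwd$sequence[i],
      f_start = fwd$start[i], f_end = fwd$end[i], f_tm = fwd$tm[i],
      f_gc = fwd$gc[i], f_lc = fwd$lc[i],
      r_name = rev$name[j], r_sequence = rev$sequence[j],
      r_start = rev$start[j], r_end = rev$end[j], r_tm = rev$tm[j],
      r_gc = rev$gc[j], r_lc = rev$lc[j],
      product_len = plen[r], product_gc = pgc,
      ta = annealing_temperature(fwd$tm[i], rev$tm[j], plen[r],
                                 pgc, cond),
      product_tm = product_tm(plen[r], pgc, cond),
      rank_score = score[r], stringsAsFactors = FALSE
    )
    if (length(rows) >= max_pairs) break
  }
  if (!length(rows)) {
    return(empty_pairs(sprintf(
      "no compatible pairs (%d combinations dimer-checked)", n_prescreen)))
  }
  pairs <- do.call(rbind, rows)
  pairs$mode <- constraints$mode
  rownames(pairs) <- NULL
  class(pairs) <- c("primer_pairs", class(pairs))
  attr(pairs, "template_used") <- res
  attr(pairs, "candidates") <- cands
  attr(pairs, "rejections") <- attr(cands, "rejections")
  pairs
}

#' @export
print.primer_pairs <- function(x, ...) {
  if (!nrow(x)) {
    cat("<primer_pairs> none found:", attr(x, "reasons"), "\n")
    rj <- attr(x, "rejections")
    if (!is.null(rj)) {
      cat("  candidate rejections:",
          paste(names(rj), rj, sep = "=", collapse = " "), "\n")
    }
    return(invisible(x))
  }
  cat(sprintf("<primer_pairs> %d ranked pair(s), mode %s\n",
              nrow(x), x$mode[1]))
  print.data.frame(utils::head(
    x[, c("f_name", "r_name", "f_tm", "r_tm", "product_len", "ta",
          "rank_score")], 5L), digits = 4)
  invisible(x)
}

#' Design a hydrolysis probe (TaqMan or MGB) for a primer pair
#'
#' Searches the inter-primer region for a probe window satisfying the
#' type-specific rules.  TaqMan: length 15-30, GC 45-65%, Tm in 68-72
#' degrees C with a soft target of 8-10 degrees above the mean primer Tm,
#' and no guanine at the 5' end (a 5' G quenches the reporter dye even
#' after cleavage).  MGB: length 13-30, sequence Tm within 1 degree C of
#' the mean primer Tm (the minor-groove binder moiety supplies extra
#' duplex stabilization that is not modeled thermodynamically -- noted in
#' the output), no 5' G.  Probes must pass the dimer filter against both
#' primers; the reported strand carries more C than G (standard
#' quencher-side practice).
#'
#' @param template The template the pair was designed on (use
#'   `attr(pairs, "template_used")` for bisulfite designs).
#' @param pair One row of a [design_pairs()] result.
#' @param probe_type `"TaqMan"` or `"MGB"`.
#' @param cond [thermo_conditions()].
#' @param lc_min Minimum probe linguistic complexity.
#' @return One-row data frame: `sequence`, `start`, `end`, `strand`,
#'   `length`, `tm`, `gc`, `lc`, `probe_type`, `note`.
#' @export
design_probe <- function(template, pair, probe_type = c("TaqMan", "MGB"),
                         cond = thermo_conditions(), lc_min = 75) {
  probe_type <- match.arg(probe_type)
  res <- as_residues(template)
  lo <- pair$f_end + 1L
  hi <- pair$r_start - 1L
  len_range <- if (probe_type == "TaqMan") c(15L, 30L) else c(13L, 30L)
  if (hi - lo + 1L < len_range[1]) {
    stop("inter-primer region too short for a ", probe_type, " probe")
  }
  mean_primer_tm <- mean(c(pair$f_tm, pair$r_tm))
  region <- substr(res, lo, hi)
  rchars <- strsplit(region, "", fixed = TRUE)[[1]]
  # fast Tm/GC pre-screen of every window, then exact checks in order of
  # increasing Tm-target penalty; the first window passing the dimer
  # screens wins
  cand <- list()
  for (len in len_range[1]:min(len_range[2], hi - lo + 1L)) {
    starts <- 1:(nchar(region) - len + 1L)
    ft <- window_tm_fast(rchars, starts, len, cond)
    keep <- if (probe_type == "TaqMan") {
      !is.na(ft$tm) & ft$tm >= 67 & ft$tm <= 73 &
        ft$gc >= 45 & ft$gc <= 65
    } else {
      !is.na(ft$tm) & abs(ft$tm - mean_primer_tm) <= 2
    }
    if (any(keep)) {
      cand[[length(cand) + 1L]] <- data.frame(
        s = starts[keep], len = len, tm0 = ft$tm[keep])
    }
  }
  best <- NULL
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    target <- if (probe_type == "TaqMan") mean_primer_tm + 9
              else mean_primer_tm
    cand <- cand[order(abs(cand$tm0 - target), cand$s, cand$len), ,
                 drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      s <- lo + cand$s[r] - 1L
      len <- cand$len[r]
      wseq <- substr(res, s, s + len - 1L)
      n_c <- nchar(gsub("[^C]", "", wseq))
      n_g <- nchar(gsub("[^G]", "", wseq))
      strand <- if (n_c >= n_g) "+" else "-"
      sq <- if (strand == "+") wseq else reverse_complement(wseq)
      if (substr(sq, 1L, 1L) == "G") next         # no 5' G
      gc <- gc_content(sq)
      tm <- melting_temperature(sq, cond)
      if (probe_type == "TaqMan") {
        if (gc < 45 || gc > 65 || tm < 68 || tm > 72) next
      } else {
        if (abs(tm - mean_primer_tm) > 1) next
      }
      lc <- linguistic_complexity(sq)
      if (lc < lc_min) next
      if (!passes_dimer_filter(sq, pair$f_sequence, cond = cond)$pass) next
      if (!passes_dimer_filter(sq, pair$r_sequence, cond = cond)$pass) next
      if (!passes_dimer_filter(sq, sq, cond = cond)$pass) next
      best <- data.frame(
        sequence = sq, start = s, end = s + len - 1L, strand = strand,
        length = len, tm = tm, gc = gc, lc = lc, probe_type = probe_type,
        note = if (probe_type == "MGB") {
          "MGB moiety stabilization not modeled; sequence Tm reported"
        } else "", stringsAsFactors = FALSE
      )
      break
    }
  }
  if (is.null(best)) {
    stop("no conforming ", probe_type, " probe in the inter-primer region")
  }
  best
}
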