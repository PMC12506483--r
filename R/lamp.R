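# LAMP primer-set design: F3/F2/F1c and B1c/B2/B3 core regions, FIP/BIP
# fusion primers, optional LF/LB loop primers, spacing constraints,
# bisulfite option.

#' LAMP geometry and Tm configuration
#'
#' Region lengths, Tm tiers and spacing windows follow the conventions
#' popularized by the PrimerExplorer tool family; every value is
#' user-adjustable.  All coordinates are plus-strand, 1-based inclusive,
#' ordered `F3 < F2 < (LF) < F1 < B1 < (LB) < B2 < B3`.
#'
#' @param f2b2_len Allowed span from F2 start to B2 end (the core
#'   amplicon), bp.
#' @param core_len,f1c_len,loop_len Length ranges (bases) for
#'   F3/B3/F2/B2, F1c/B1c, and loop primers.
#' @param tm_core,tm_f1c,tm_loop Tm tiers (degrees C): outer/inner core
#'   primers anneal first, the F1c/B1c fold-back arms must melt ~5
#'   degrees higher, loop primers sit in between.
#' @param gap_f2_f1 Gap between F2 end and F1 start (and mirrored between
#'   B1 end and B2 start), bases -- the loop-forming spacer.
#' @param gap_f3 Gap between F3 end and F2 start (mirrored for B3),
#'   bases.
#' @param lc_min Minimum linguistic complexity per region.
#' @param gc_range Allowed GC percent per region.
#' @return List of class `lamp_config`.
#' @export
lamp_config <- function(f2b2_len = c(120L, 300L),
                        core_len = c(18L, 22L), f1c_len = c(18L, 24L),
                        loop_len = c(18L, 22L),
                        tm_core = c(59, 61), tm_f1c = c(64, 66),
                        tm_loop = c(62, 64),
                        gap_f2_f1 = c(20L, 60L), gap_f3 = c(0L, 20L),
                        lc_min = 70, gc_range = c(30, 70)) {
  structure(list(f2b2_len = f2b2_len, core_len = core_len,
                 f1c_len = f1c_len, loop_len = loop_len,
                 tm_core = tm_core, tm_f1c = tm_f1c, tm_loop = tm_loop,
                 gap_f2_f1 = gap_f2_f1, gap_f3 = gap_f3,
                 lc_min = lc_min, gc_range = gc_range),
            class = "lamp_config")
}

# Plus-strand candidate windows for one LAMP region tier.
lamp_candidates <- function(res, chars, len_range, tm_range, lc_min,
                            gc_range, masked, cond, cap = 40L) {
  L <- nchar(res)
  rows <- list()
  for (len in len_range[1]:len_range[2]) {
    if (len > L) next
    starts <- 1:(L - len + 1L)
    ft <- window_tm_fast(chars, starts, len, cond)
    ok <- !is.na(ft$tm) & ft$tm >= tm_range[1] & ft$tm <= tm_range[2] &
      ft$gc >= gc_range[1] & ft$gc <= gc_range[2]
    for (s in starts[ok]) {
      e <- s + len - 1L
      if (!is.null(masked) && nrow(masked) &&
          any(intervals_overlap(masked$start, masked$end, s, e))) next
      w <- substr(res, s, e)
      lc <- linguistic_complexity(w)
      if (lc < lc_min) next
      if (!passes_dimer_filter(w, w, cond = cond)$pass) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, length = len,
        tm = melting_temperature(w, cond), seq = w, lc = lc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), tm = numeric(0),
                      seq = character(0), lc = numeric(0)))
  }
  out <- do.call(rbind, rows)
  mid <- mean(tm_range)
  out <- out[order(abs(out$tm - mid), out$start), , drop = FALSE]
  utils::head(out, cap)
}

#' Design LAMP primer sets
#'
#' Builds ranked LAMP sets from per-region candidate lists: outer primers
#' F3/B3, fusion primers FIP (= F1c + F2, i.e. the reverse complement of
#' the F1 region concatenated with the F2 region sequence) and BIP
#' (= B1c + B2, the strand-mirrored analogue: B1 region sequence plus the
#' reverse complement of the B2 region), with optional loop primers LF
#' (minus strand, between F2 and F1) and LB (plus strand, between B1 and
#' B2).  Repeated and low-complexity stretches of the template are masked
#' before candidate generation (default on), all region spacing windows
#' are honored, and every returned set is free of intra- and inter-primer
#' dimers.  With `bisulfite` set, design runs on the converted strand.
#'
#' @param template Template (string or `nucleotide_sequence`).
#' @param config [lamp_config()].
#' @param with_loops Also place LF/LB loop primers ([loop_primer_fill()]).
#' @param bisulfite `"none"`, `"plus"` or `"minus"`.
#' @param repeat_control Mask repeats/low-complexity tracts first.
#' @param cond [thermo_conditions()].
#' @param max_sets Maximum number of ranked sets returned.
#' @return Data frame of class `lamp_sets`, one row per set: per-region
#'   coordinates and Tm, primer sequences (`f3_seq`, `fip_seq`,
#'   `bip_seq`, `b3_seq`, optionally `lf_seq`, `lb_seq`),
#'   `amplicon_f2b2`, `rank_score`, `loops` flag.  A structured error
#'   with per-region candidate counts is raised when no set is feasible.
#' @export
design_lamp <- function(template, config = lamp_config(),
                        with_loops = TRUE,
                        bisulfite = c("none", "plus", "minus"),
                        repeat_control = TRUE,
                        cond = thermo_conditions(), max_sets = 5L) {
  bisulfite <- match.arg(bisulfite)
  res <- as_residues(template)
  if (bisulfite != "none") res <- bisulfite_convert(res, bisulfite)
  L <- nchar(res)
  if (L < config$f2b2_len[1] + 2L * (config$core_len[2] + config$gap_f3[2])) {
    stop("template too short for the requested F2-B2 amplicon length ",
         "(insufficient flanks)")
  }
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  masked <- if (repeat_control) design_mask_intervals(res) else NULL
  cand_core <- lamp_candidates(res, chars, config$core_len, config$tm_core,
                               config$lc_min, config$gc_range, masked, cond)
  cand_f1c <- lamp_candidates(res, chars, config$f1c_len, config$tm_f1c,
                              config$lc_min, config$gc_range, masked, cond)
  shortfall <- function() {
    stop(sprintf(
      "no viable LAMP set: candidate counts core=%d inner(F1c/B1c)=%d",
      nrow(cand_core), nrow(cand_f1c)))
  }
  if (nrow(cand_core) < 4L || nrow(cand_f1c) < 2L) shortfall()
  sets <- list()
  tmc <- mean(config$tm_core); tmf <- mean(config$tm_f1c)
  for (i2 in seq_len(nrow(cand_core))) {         # F2
    f2 <- cand_core[i2, ]
    f1s <- cand_f1c[cand_f1c$start >= f2$end + config$gap_f2_f1[1] + 1L &
                      cand_f1c$start <= f2$end + config$gap_f2_f1[2] + 1L, ,
                    drop = FALSE]
    f3s <- cand_core[cand_core$end >= f2$start - config$gap_f3[2] - 1L &
                       cand_core$end <= f2$start - config$gap_f3[1] - 1L, ,
                     drop = FALSE]
    if (!nrow(f1s) || !nrow(f3s)) next
    b2s <- cand_core[cand_core$end >= f2$start + config$f2b2_len[1] - 1L &
                       cand_core$end <= f2$start + config$f2b2_len[2] - 1L, ,
                     drop = FALSE]
    for (j2 in seq_len(nrow(b2s))) {             # B2
      b2 <- b2s[j2, ]
      b1s <- cand_f1c[cand_f1c$end <= b2$start - config$gap_f2_f1[1] - 1L &
                        cand_f1c$end >= b2$start - config$gap_f2_f1[2] - 1L, ,
                      drop = FALSE]
      b3s <- cand_core[cand_core$start >= b2$end + config$gap_f3[1] + 1L &
                         cand_core$start <= b2$end + config$gap_f3[2] + 1L, ,
                       drop = FALSE]
      if (!nrow(b1s) || !nrow(b3s)) next
      for (i1 in seq_len(min(nrow(f1s), 5L))) {
        f1 <- f1s[i1, ]
        for (j1 in seq_len(min(nrow(b1s), 5L))) {
          b1 <- b1s[j1, ]
          if (b1$start <= f1$end) next           # ordering/disjointness
          f3 <- f3s[1, ]; b3 <- b3s[1, ]
          fip <- paste0(reverse_complement(f1$seq), f2$seq)
          bip <- paste0(b1$seq, reverse_complement(b2$seq))
          b3_seq <- reverse_complement(b3$seq)
          oligos <- c(F3 = f3$seq, FIP = fip, BIP = bip, B3 = b3_seq)
          if (nrow(audit_dimer_compatibility(oligos, cond))) next
          dev <- mean(c(abs(f3$tm - tmc), abs(f2$tm - tmc),
                        abs(b2$tm - tmc), abs(b3$tm - tmc),
                        abs(f1$tm - tmf), abs(b1$tm - tmf)))
          span <- b2$end - f2$start + 1L
          centr <- 1 - abs(span - mean(config$f2b2_len)) /
            (diff(config$f2b2_len) / 2)
          sets[[length(sets) + 1L]] <- data.frame(
            f3_start = f3$start, f3_end = f3$end, f3_tm = f3$tm,
            f2_start = f2$start, f2_end = f2$end, f2_tm = f2$tm,
            f1_start = f1$start, f1_end = f1$end, f1_tm = f1$tm,
            b1_start = b1$start, b1_end = b1$end, b1_tm = b1$tm,
            b2_start = b2$start, b2_end = b2$end, b2_tm = b2$tm,
            b3_start = b3$start, b3_end = b3$end, b3_tm = b3$tm,
            f3_seq = f3$seq, fip_seq = fip, bip_seq = bip,
            b3_seq = b3_seq, amplicon_f2b2 = span,
            rank_score = centr - dev, loops = FALSE,
            lf_seq = NA_character_, lb_seq = NA_character_,
            lf_start = NA_integer_, lf_end = NA_integer_,
            lb_start = NA_integer_, lb_end = NA_integer_,
            lf_tm = NA_real_, lb_tm = NA_real_,
            loop_note = "", stringsAsFactors = FALSE)
          if (length(sets) >= 4L * max_sets) break
        }
        if (length(sets) >= 4L * max_sets) break
      }
      if (length(sets) >= 4L * max_sets) break
    }
    if (length(sets) >= 4L * max_sets) break
  }
  if (!length(sets)) shortfall()
  out <- do.call(rbind, sets)
  out <- out[order(-out$rank_score, out$f2_start), , drop = FALSE]
  out <- utils::head(out, max_sets)
  rownames(out) <- NULL
  if (with_loops) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(r) {
      loop_primer_fill(out[r, ], res, config, cond)
    }))
  }
  class(out) <- c("lamp_sets", class(out))
  attr(out, "template_used") <- res
  out
}

#' Place LF/LB loop primers into a LAMP set
#'
#' LF anneals on the minus strand inside the F2-F1 spacer; LB on the plus
#' strand inside the B1-B2 spacer.  Loop primers must fit wholly inside
#' their spacer, meet the loop Tm tier, and pass the dimer filter against
#' the four core primers.  When a spacer is too short the set is returned
#' unchanged with a `loop_note` flag.
#'
#' @param set One row of a [design_lamp()] result.
#' @param template The (possibly converted) template residues the set was
#'   designed on.
#' @param config [lamp_config()].
#' @param cond [thermo_conditions()].
#' @return The set row with loop fields filled where possible.
#' @export
loop_primer_fill <- function(set, template, config = lamp_config(),
                             cond = thermo_conditions()) {
  res <- as_residues(template)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  core <- c(set$f3_seq, set$fip_seq, set$bip_seq, set$b3_seq)
  fill_one <- function(lo, hi, minus_strand) {
    if (hi - lo + 1L < config$loop_len[1]) return(NULL)
    cands <- lamp_candidates(res, chars, config$loop_len, config$tm_loop,
                             config$lc_min, config$gc_range, NULL, cond,
                             cap = 200L)
    cands <- cands[cands$start >= lo & cands$end <= hi, , drop = FALSE]
    for (r in seq_len(nrow(cands))) {
      sq <- if (minus_strand) reverse_complement(cands$seq[r])
            else cands$seq[r]
      okc <- all(vapply(core, function(o) {
        passes_dimer_filter(sq, o, cond = cond)$pass
      }, logical(1)))
      if (okc) {
        return(data.frame(start = cands$start[r], end = cands$end[r],
                          tm = cands$tm[r], seq = sq,
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  }
  lf <- fill_one(set$f2_end + 1L, set$f1_start - 1L, minus_strand = TRUE)
  lb <- fill_one(set$b1_end + 1L, set$b2_start - 1L, minus_strand = FALSE)
  notes <- character(0)
  if (is.null(lf)) notes <- c(notes, "LF: loop region too short or no primer")
  else {
    set$lf_start <- lf$start; set$lf_end <- lf$end
    set$lf_tm <- lf$tm; set$lf_seq <- lf$seq
  }
  if (is.null(lb)) notes <- c(notes, "LB: loop region too short or no primer")
  else {
    set$lb_start <- lb$start; set$lb_end <- lb$end
    set$lb_tm <- lb$tm; set$lb_seq <- lb$seq
  }
  set$loops <- !is.null(lf) && !is.null(lb)
  set$loop_note <- paste(notes, collapse = "; ")
  set
}

#' @export
print.lamp_sets <- function(x, ...) {
  cat(sprintf("<lamp_sets> %d ranked set(s); F2-B2 span %s bp%s\n",
              nrow(x), paste(range(x$amplicon_f2b2), collapse = "-"),
              if (all(x$loops)) " (with loop primers)" else ""))
  invisible(x)
}
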