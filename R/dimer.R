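# Primer-dimer screening by gapless local alignment, run-length rejection
# rules, duplex Tm with internal mismatches, and 3' hairpin check.

# Logical vector: elementwise WC pairing of two equal-length char vectors
# (degenerate codes pair when any expansion of x complements any expansion
# of y; G:T wobbles do not count).
wc_pairs_vec <- function(xs, ys) {
  PAIR_MAT[cbind(xs, ys)]
}

# Internal Tm-free dimer scan: all maximal complementary runs >= min_run
# over every antiparallel offset.  Returns a list of equal-length vectors.
# Implemented as a single pass over all n*m cells ordered by
# anti-diagonal (offset); the ordering is cached per (n, m) shape.
.dimer_ord_cache <- new.env(parent = emptyenv())

dimer_ord <- function(n, m) {
  key <- paste0(n, "_", m)
  hit <- .dimer_ord_cache[[key]]
  if (!is.null(hit)) return(hit)
  i_idx <- rep.int(seq_len(n), m)            # column-major cell -> i
  j_idx <- rep(seq_len(m), each = n)
  s_idx <- i_idx + j_idx
  ord <- order(s_idx, i_idx)
  out <- list(ord = ord, i = i_idx[ord], s = s_idx[ord],
              grp = cumsum(c(TRUE, diff(s_idx[ord]) != 0L)))
  .dimer_ord_cache[[key]] <- out
  out
}

dimer_runs <- function(ca, cb, min_run = 2L) {
  n <- length(ca); m <- length(cb)
  M <- PAIR_MAT[cbind(rep.int(ca, m), rep(cb, each = n))]
  oc <- dimer_ord(n, m)
  mv <- M[oc$ord]
  code <- oc$grp * 2L + mv                   # odd = complementary cell
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which((r$values %% 2L == 1L) & r$lengths >= min_run)
  if (!length(keep)) {
    return(list(offset = integer(0), i1 = integer(0), i2 = integer(0),
                run = integer(0), inv3 = logical(0)))
  }
  i1 <- oc$i[starts[keep]]
  i2 <- oc$i[ends[keep]]
  s <- oc$s[starts[keep]]
  list(offset = s, i1 = i1, i2 = i2, run = i2 - i1 + 1L,
       inv3 = (i2 == n) | (s - i1 >= m & m >= s - i2))
}

#' Find self- and cross-dimers between two oligos
#'
#' Scans every gapless antiparallel alignment offset of oligo `a` against
#' oligo `b` and records each maximal run of contiguous Watson-Crick
#' complementary bases of length at least `min_run`.  A run "involves the
#' 3' end" when it includes the 3'-terminal base of either oligo (those
#' dimers are polymerase-extensible and most inhibitory).
#'
#' @param a,b Oligos (strings or `nucleotide_sequence`); `a` may equal `b`
#'   for self-dimer analysis.
#' @param min_run Minimum run length reported.
#' @param cond [thermo_conditions()] for the duplex Tm of each alignment.
#' @return Data frame sorted by `run_length` then `dimer_tm` (descending):
#'   `offset` (alignment shift constant: position i of `a` pairs position
#'   `offset - i` of `b`), `run_length`, `involves_3prime`, `a_start`,
#'   `a_end`, `b_start`, `b_end` (1-based on each oligo, 5'->3'),
#'   `dimer_tm` (degrees C for the full alignment at that offset; `NA`
#'   below model range).
#' @export
find_dimers <- function(a, b, min_run = 2L, cond = thermo_conditions()) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  rr <- dimer_runs(ca, cb, min_run)
  if (!length(rr$offset)) {
    return(data.frame(offset = integer(0), run_length = integer(0),
                      involves_3prime = logical(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), dimer_tm = numeric(0)))
  }
  tm_by_offset <- vapply(unique(rr$offset), function(s) {
    dimer_tm(a, b, s, cond)
  }, numeric(1))
  names(tm_by_offset) <- unique(rr$offset)
  hits <- data.frame(
    offset = rr$offset, run_length = rr$run,
    involves_3prime = rr$inv3, a_start = rr$i1, a_end = rr$i2,
    b_start = rr$offset - rr$i2, b_end = rr$offset - rr$i1,
    dimer_tm = unname(tm_by_offset[as.character(rr$offset)])
  )
  hits[order(-hits$run_length, -ifelse(is.na(hits$dimer_tm), -Inf,
                                       hits$dimer_tm)), , drop = FALSE]
}

#' Duplex Tm of one dimer alignment (mismatches allowed)
#'
#' Nearest-neighbor Tm over the full gapless antiparallel alignment of
#' `a` against `b` at the given offset.  Matched steps use the unified
#' Watson-Crick parameters; steps containing a single internal mismatch
#' use the published mismatch parameters (steps with two mismatched pairs
#' carry no tabulated value and contribute nothing); degenerate positions
#' are averaged over expansions.  Initiation terms are added for
#' Watson-Crick terminal pairs only; dangling ends are ignored.
#'
#' @param a,b Oligos.
#' @param offset Alignment shift constant as reported by [find_dimers()].
#' @param cond [thermo_conditions()].
#' @return Tm in degrees C, or `NA` when the alignment has fewer than two
#'   NN steps (below model range).
#' @export
dimer_tm <- function(a, b, offset, cond = thermo_conditions()) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  n <- length(ca); m <- length(cb); s <- offset
  i_lo <- max(1L, s - m); i_hi <- min(n, s - 1L)
  if (i_hi - i_lo < 2L) return(NA_real_)  # < 2 NN steps
  ii <- i_lo:i_hi
  duplex_tm_vec(ca[ii], cb[s - ii], cond)  # bottom read 3'->5' under top
}

# NN Tm of an aligned duplex given as top (5'->3') and bottom (3'->5')
# character vectors of equal length; mismatch steps use the published
# internal-mismatch parameters.
duplex_tm_vec <- function(top, bot, cond = thermo_conditions()) {
  k <- length(top)
  if (k < 3L) return(NA_real_)
  pure <- c("A", "C", "G", "T")
  all_pure <- all(top %in% pure) && all(bot %in% pure)
  matched0 <- PAIR_MAT[cbind(top, bot)]
  if (all_pure && all(matched0)) {
    keys <- paste0(top[-k], top[-1])
    dh <- sum(NN_DH[keys]); ds <- sum(NN_DS[keys])
  } else if (all_pure) {
    steps_dh <- numeric(k - 1L); steps_ds <- numeric(k - 1L)
    for (p in seq_len(k - 1L)) {
      st <- duplex_step_pure(top[p], top[p + 1L], bot[p], bot[p + 1L],
                             matched0[p], matched0[p + 1L])
      steps_dh[p] <- st[1]; steps_ds[p] <- st[2]
    }
    dh <- sum(steps_dh); ds <- sum(steps_ds)
  } else {
    dh <- 0; ds <- 0
    for (p in seq_len(k - 1L)) {
      st <- duplex_step(top[p], top[p + 1L], bot[p], bot[p + 1L])
      dh <- dh + st[["dh"]]; ds <- ds + st[["ds"]]
    }
  }
  matched <- wc_pairs_vec(top, bot)
  for (term in c(1L, k)) {
    if (matched[term]) {
      f_gc <- mean(expand_base(top[term]) %in% c("G", "C"))
      dh <- dh + f_gc * NN_INIT_DH[["GC"]] + (1 - f_gc) * NN_INIT_DH[["AT"]]
      ds <- ds + f_gc * NN_INIT_DS[["GC"]] + (1 - f_gc) * NN_INIT_DS[["AT"]]
    }
  }
  if (dh >= 0) return(NA_real_)           # no net stability: no duplex
  cf <- cond$oligo_conc * 1e-9 / 4
  tm_1m <- 1000 * dh / (ds + GAS_CONSTANT * log(cf))
  f_gc <- mean(vapply(top, function(ch) {
    mean(expand_base(ch) %in% c("G", "C"))
  }, numeric(1)))
  salt_correct_tm(tm_1m, f_gc, sodium_equivalent(cond)) - 273.15
}

# Pure-base duplex step (no degenerate averaging): wc flags say whether
# each pair is Watson-Crick.  Returns c(dh, ds); double mismatches 0.
duplex_step_pure <- function(a1, a2, b1, b2, wc1, wc2) {
  if (wc1 && wc2) {
    key <- paste0(a1, a2)
    return(c(NN_DH[[key]], NN_DS[[key]]))
  }
  key <- paste0(a1, a2, "/", b1, b2)
  v <- MM_TABLE$dh[key][[1]]
  if (!is.null(v) && !is.na(v)) {
    return(c(v, MM_TABLE$ds[[key]]))
  }
  key2 <- paste0(b2, b1, "/", a2, a1)      # same doublet, other strand
  v2 <- MM_TABLE$dh[key2][[1]]
  if (!is.null(v2) && !is.na(v2)) {
    return(c(v2, MM_TABLE$ds[[key2]]))
  }
  c(0, 0)
}

# Mean dH/dS of one duplex step top 5'-x1 x2-3' over bottom 3'-y1 y2-5',
# averaged over degenerate expansions; unmatched (double-mismatch) steps
# return 0.
duplex_step <- function(x1, x2, y1, y2) {
  e <- expand.grid(a1 = expand_base(x1), a2 = expand_base(x2),
                   b1 = expand_base(y1), b2 = expand_base(y2),
                   stringsAsFactors = FALSE)
  dh <- numeric(nrow(e)); ds <- numeric(nrow(e))
  for (r in seq_len(nrow(e))) {
    a1 <- e$a1[r]; a2 <- e$a2[r]; b1 <- e$b1[r]; b2 <- e$b2[r]
    wc1 <- b1 == COMPLEMENT_DNA[[a1]]; wc2 <- b2 == COMPLEMENT_DNA[[a2]]
    if (wc1 && wc2) {
      key <- paste0(a1, a2)
      dh[r] <- NN_DH[[key]]; ds[r] <- NN_DS[[key]]
    } else {
      key <- paste0(a1, a2, "/", b1, b2)
      if (!is.null(v <- MM_TABLE$dh[key][[1]]) && !is.na(v)) {
        dh[r] <- v; ds[r] <- MM_TABLE$ds[[key]]
      } else {
        key2 <- paste0(b2, b1, "/", a2, a1)  # same doublet, other strand
        v2 <- MM_TABLE$dh[key2][[1]]
        if (!is.null(v2) && !is.na(v2)) {
          dh[r] <- v2; ds[r] <- MM_TABLE$ds[[key2]]
        }                                     # else: double mismatch, 0
      }
    }
  }
  c(dh = mean(dh), ds = mean(ds))
}

#' Dimer rejection filter
#'
#' A pair of oligos fails the filter when any gapless alignment shows a
#' complementary run of at least `three_prime_run` bases that includes a
#' 3'-terminal base of either oligo, or a run of at least `middle_run`
#' bases anywhere.  Symmetric in its arguments.  An optional free-energy
#' gate (off by default) additionally requires the offending alignment's
#' duplex Tm to reach `ta - 10` degrees C before rejecting.
#'
#' @param a,b Oligos; `a == b` screens for self-dimers.
#' @param three_prime_run Minimal rejecting 3'-anchored run (bases).
#' @param middle_run Minimal rejecting run anywhere (bases).
#' @param dg_gate Logical; apply the Tm gate.
#' @param ta Annealing temperature for the gate, degrees C.
#' @param cond [thermo_conditions()].
#' @return List: `pass` (logical), `reason` (`"ok"`, `"3' run <k>"` or
#'   `"middle run <k>"`), `max_run`, `dimer_tm` of the worst hit (`NA`
#'   when no hit).
#' @export
passes_dimer_filter <- function(a, b, three_prime_run = 5L, middle_run = 7L,
                                dg_gate = FALSE, ta = NULL,
                                cond = thermo_conditions()) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  rr <- dimer_runs(ca, cb, min_run = 2L)
  if (!length(rr$offset)) {
    return(list(pass = TRUE, reason = "ok", max_run = 0L,
                dimer_tm = NA_real_))
  }
  bad <- rr$run >= middle_run |
    (rr$run >= three_prime_run & rr$inv3)
  if (dg_gate && !is.null(ta) && any(bad)) {
    tm_bad <- vapply(rr$offset[bad], function(s) dimer_tm(a, b, s, cond),
                     numeric(1))
    bad[bad] <- !is.na(tm_bad) & tm_bad >= ta - 10
  }
  if (!any(bad)) {
    return(list(pass = TRUE, reason = "ok", max_run = max(rr$run),
                dimer_tm = NA_real_))
  }
  w <- which(bad)[which.max(rr$run[bad])]
  reason <- if (rr$run[w] >= middle_run) {
    sprintf("middle run %d", rr$run[w])
  } else {
    sprintf("3' run %d", rr$run[w])
  }
  list(pass = FALSE, reason = reason, max_run = max(rr$run),
       dimer_tm = dimer_tm(a, b, rr$offset[w], cond))
}

#' 3'-terminal hairpin check
#'
#' Flags an oligo whose 3'-terminal bases can fold back onto an upstream
#' segment with a stem of at least `stem_min` Watson-Crick pairs and a
#' loop of at least `loop_min` bases.  By default the stem must include
#' the 3'-terminal base; `three_prime_window` relaxes this to a window at
#' the 3' end.
#'
#' @param a Oligo (length >= 8).
#' @param stem_min Minimum stem length, bp.
#' @param loop_min Minimum loop length, bases.
#' @param three_prime_window The stem's 3' arm must end within this many
#'   bases of the 3' terminus (1 = must include the terminal base).
#' @return List: `flagged` (logical) and, when flagged, `stem_length`,
#'   `loop_length`, `stem5_start`, `stem5_end`, `stem3_start`, `stem3_end`
#'   (1-based positions of the two stem arms).
#' @export
three_prime_hairpin_check <- function(a, stem_min = 4L, loop_min = 3L,
                                      three_prime_window = 1L) {
  ch <- seq_chars(a)
  n <- length(ch)
  if (n < 8) stop("three_prime_hairpin_check: oligo shorter than 8 nt")
  best <- NULL
  for (end3 in n:(n - three_prime_window + 1L)) {
    if (end3 < stem_min) next
    max_stem <- (end3 - loop_min) %/% 2L
    for (st in seq_len(max_stem)) {
      if (st < stem_min) next
      arm3 <- (end3 - st + 1L):end3       # 3' arm, 5'->3'
      for (i in 1:(end3 - st - loop_min - st + 1L)) {
        if (end3 - st - loop_min - st + 1L < 1L) break
        arm5 <- i:(i + st - 1L)
        # pairing: arm5[k] with arm3[st - k + 1]
        if (all(wc_pairs_vec(ch[arm5], ch[rev(arm3)]))) {
          cand <- list(flagged = TRUE, stem_length = st,
                       loop_length = arm3[1] - arm5[st] - 1L,
                       stem5_start = arm5[1], stem5_end = arm5[st],
                       stem3_start = arm3[1], stem3_end = arm3[st])
          if (is.null(best) || cand$stem_length > best$stem_length) {
            best <- cand
          }
        }
      }
    }
  }
  if (is.null(best)) list(flagged = FALSE) else best
}
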