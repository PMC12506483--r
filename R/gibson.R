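# Gibson assembly primer design: terminal primers per fragment with
# neighbor-derived 5' tails, overlap length/Tm constraints, optional
# vector inverse-PCR primers.

# Terminal annealing primer at one end of a fragment: length scanned over
# `len_range` for a Tm inside `tm_range`; when no length conforms, the
# closest Tm is taken and flagged.
terminal_primer <- function(res, where = c("start", "end"),
                            tm_range = c(60, 62), len_range = c(15L, 35L),
                            cond = thermo_conditions()) {
  where <- match.arg(where)
  L <- nchar(res)
  lens <- len_range[1]:min(len_range[2], L)
  seqs <- vapply(lens, function(l) {
    if (where == "start") substr(res, 1L, l)
    else reverse_complement(substr(res, L - l + 1L, L))
  }, character(1))
  tms <- vapply(seqs, melting_temperature, numeric(1), cond = cond)
  inwin <- tms >= tm_range[1] & tms <= tm_range[2]
  mid <- mean(tm_range)
  pick <- if (any(inwin)) which(inwin)[which.min(abs(tms[inwin] - mid))]
          else which.min(abs(tms - mid))
  list(sequence = seqs[pick], tm = tms[pick], length = lens[pick],
       tm_in_window = any(inwin))
}

# Tm of an overlap region: oligo NN model up to 25 bp, long-duplex
# formula beyond (NN validity range).
overlap_tm <- function(seq, cond = thermo_conditions()) {
  if (nchar(seq) <= 25L) melting_temperature(seq, cond)
  else product_tm(nchar(seq), gc_content(seq), cond)
}

#' Design Gibson assembly junction primers
#'
#' For each fragment, terminal primers are designed in the preferred
#' long-range PCR Tm window, then 5' tails are grown from the neighboring
#' fragment's terminal sequence until each junction overlap reaches the
#' required length and melting temperature (at least 20 bp and above
#' 50 degrees C by default; at most 40 bp).  The overlap is split
#' symmetrically across the two junction primers where possible and
#' single-sided when one oligo would exceed the synthesis length cap.
#' With a vector, the vector is amplified by an untailed inverse-PCR
#' primer pair and the terminal fragments carry vector-end tails; with
#' `circularize` the last fragment overlaps the first.
#'
#' @param fragments Named list/character vector of fragment sequences in
#'   assembly order (or a list of `nucleotide_sequence`).
#' @param vector Optional vector sequence (linearized at the insertion
#'   point, so the construct is vector-start ... fragments ... vector-end).
#' @param circularize Logical; overlap the last fragment back onto the
#'   first (ignored when a vector is given -- a vector implies a circular
#'   construct).
#' @param overlap Length-2 numeric, junction overlap bounds, bp.
#' @param overlap_tm_min Minimum overlap melting temperature, degrees C.
#' @param tm_range Terminal-primer Tm window, degrees C.
#' @param oligo_cap Hard cap on total oligo length, bases (warn above
#'   `oligo_warn`).
#' @param oligo_warn Soft oligo length threshold, bases.
#' @param cond [thermo_conditions()].
#' @return List of class `gibson_plan`: `primers` (data frame: fragment,
#'   direction, tail, anneal, sequence, length, anneal_tm,
#'   tm_in_window), `junctions` (data frame: left, right, overlap_len,
#'   overlap_tm, overlap_seq), `amplicons` (named character vector of
#'   predicted PCR products), `construct` (the assembled sequence),
#'   `circular`, `dimer_violations`.
#' @export
design_gibson <- function(fragments, vector = NULL, circularize = FALSE,
                          overlap = c(20L, 40L), overlap_tm_min = 50,
                          tm_range = c(60, 62), oligo_cap = 60L,
                          oligo_warn = 50L, cond = thermo_conditions()) {
  if (inherits(fragments, "nucleotide_sequence")) {
    fragments <- list(fragments)
  }
  frs <- vapply(fragments, as_residues, character(1))
  if (is.null(names(frs)) || any(!nzchar(names(frs)))) {
    names(frs) <- paste0("fragment", seq_along(frs))
  }
  has_vector <- !is.null(vector)
  if (has_vector) {
    frs <- c(stats::setNames(as_residues(vector), "vector"), frs)
    circularize <- TRUE
  }
  n <- length(frs)
  if (n < 2L) stop("need at least 2 fragments (or 1 fragment + vector)")
  min_len <- min(nchar(frs))
  if (min_len < overlap[2] + 35L) {
    stop("fragment shorter than primer + overlap requirements (",
         min_len, " bp)")
  }
  prim <- lapply(frs, function(f) {
    list(f = terminal_primer(f, "start", tm_range, cond = cond),
         r = terminal_primer(f, "end", tm_range, cond = cond))
  })
  # junction j joins fragment j and j + 1 (wrapping when circular)
  n_j <- if (circularize) n else n - 1L
  tails_f <- rep("", n)   # 5' tail of each fragment's forward primer
  tails_r <- rep("", n)   # 5' tail (revcomp of right overlap part)
  junctions <- list()
  for (j in seq_len(n_j)) {
    i <- j; k <- if (j == n) 1L else j + 1L
    left <- frs[[i]]; right <- frs[[k]]
    vector_side <- has_vector && (i == 1L || k == 1L)
    grow <- function(la, lb) {
      ovs <- paste0(substr(left, nchar(left) - la + 1L, nchar(left)),
                    substr(right, 1L, lb))
      list(la = la, lb = lb, seq = ovs, tm = overlap_tm(ovs, cond))
    }
    split_for <- function(total) {
      if (vector_side) {
        # tails only on the fragment primers: the vector stays untailed
        if (i == 1L) c(total, 0L) else c(0L, total)
      } else {
        la <- as.integer(ceiling(total / 2))
        c(la, total - la)
      }
    }
    ov <- NULL
    for (total in overlap[1]:overlap[2]) {
      sp <- split_for(total)
      # oligo length guard: move overlap onto the other side if needed
      if (sp[2] + prim[[i]]$r$length > oligo_cap) {
        sp <- c(total, 0L)
      }
      if (sp[1] + prim[[k]]$f$length > oligo_cap) {
        sp <- c(0L, total)
        if (sp[2] + prim[[i]]$r$length > oligo_cap) break
      }
      cand <- grow(sp[1], sp[2])
      ov <- cand
      if (cand$tm > overlap_tm_min) break
    }
    if (is.null(ov)) stop("junction ", j, ": no overlap satisfies the ",
                          "oligo length cap")
    tails_f[k] <- substr(left, nchar(left) - ov$la + 1L, nchar(left))
    tails_r[i] <- reverse_complement(substr(right, 1L, ov$lb))
    junctions[[j]] <- data.frame(
      left = names(frs)[i], right = names(frs)[k],
      overlap_len = ov$la + ov$lb, overlap_tm = ov$tm,
      overlap_seq = ov$seq, stringsAsFactors = FALSE)
  }
  primers <- do.call(rbind, lapply(seq_len(n), function(i) {
    fwd <- paste0(tails_f[i], prim[[i]]$f$sequence)
    rev <- paste0(tails_r[i], prim[[i]]$r$sequence)
    data.frame(
      fragment = names(frs)[i], direction = c("forward", "reverse"),
      tail = c(tails_f[i], tails_r[i]),
      anneal = c(prim[[i]]$f$sequence, prim[[i]]$r$sequence),
      sequence = c(fwd, rev), length = c(nchar(fwd), nchar(rev)),
      anneal_tm = c(prim[[i]]$f$tm, prim[[i]]$r$tm),
      tm_in_window = c(prim[[i]]$f$tm_in_window,
                       prim[[i]]$r$tm_in_window),
      stringsAsFactors = FALSE)
  }))
  rownames(primers) <- NULL
  if (any(primers$length > oligo_warn)) {
    warning("oligo(s) longer than ", oligo_warn, " nt: ",
            paste(primers$fragment[primers$length > oligo_warn],
                  primers$direction[primers$length > oligo_warn],
                  collapse = ", "))
  }
  amplicons <- vapply(seq_len(n), function(i) {
    paste0(tails_f[i], frs[[i]], reverse_complement(tails_r[i]))
  }, character(1))
  names(amplicons) <- names(frs)
  oligos <- stats::setNames(primers$sequence,
                            paste(primers$fragment, primers$direction,
                                  sep = "_"))
  viol <- audit_dimer_compatibility(oligos, cond)
  structure(list(
    primers = primers,
    junctions = do.call(rbind, junctions),
    amplicons = amplicons,
    construct = paste(frs, collapse = ""),
    circular = circularize,
    dimer_violations = viol), class = "gibson_plan")
}

#' @export
print.gibson_plan <- function(x, ...) {
  cat(sprintf("<gibson_plan> %d fragment(s), %d junction(s)%s; overlaps %s bp, Tm %.1f-%.1f\n",
              length(x$amplicons), nrow(x$junctions),
              if (x$circular) " (circular)" else "",
              paste(range(x$junctions$overlap_len), collapse = "-"),
              min(x$junctions$overlap_tm), max(x$junctions$overlap_tm)))
  invisible(x)
}

#' Stitch Gibson amplicons by exact overlap match
#'
#' Assembles the predicted amplicons by exact suffix/prefix overlap
#' merging (the in vitro exonuclease/annealing step idealized), useful to
#' audit that a plan reconstructs the intended construct byte-for-byte.
#'
#' @param plan A [design_gibson()] result.
#' @return The assembled sequence (linear concatenation; for circular
#'   plans the terminal overlap is trimmed from the end).
#' @export
stitch_gibson <- function(plan) {
  amps <- plan$amplicons
  jn <- plan$junctions
  n <- length(amps)
  out <- amps[[1]]
  for (j in seq_len(n - 1L)) {
    ov <- jn$overlap_len[j]
    nxt <- amps[[j + 1L]]
    stopifnot(substr(out, nchar(out) - ov + 1L, nchar(out)) ==
                substr(nxt, 1L, ov))
    out <- paste0(out, substr(nxt, ov + 1L, nchar(nxt)))
  }
  if (plan$circular) {
    ovn <- jn$overlap_len[n]
    stopifnot(substr(out, nchar(out) - ovn + 1L, nchar(out)) ==
                substr(amps[[1]], 1L, ovn))
    # trim the wrap overlap so the result is the linear construct
    la <- nchar(plan$primers$tail[
      plan$primers$fragment == names(amps)[1] &
        plan$primers$direction == "forward"][1])
    out <- substr(out, la + 1L, nchar(out) - (ovn - la))
  }
  out
}
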