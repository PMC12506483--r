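# Multiplex assay assembly over many targets (scarcity-first, running
# predesigned-oligo list) and custom tiling PCR panel construction.

#' Audit pairwise dimer compatibility of an oligo set
#'
#' Runs the dimer filter over all self and cross combinations.
#'
#' @param oligos Named character vector of oligo sequences.
#' @param cond [thermo_conditions()].
#' @param ... Passed to [passes_dimer_filter()].
#' @return Data frame of violations (zero rows when the set is clean):
#'   `oligo1`, `oligo2`, `reason`.
#' @export
audit_dimer_compatibility <- function(oligos, cond = thermo_conditions(),
                                      ...) {
  if (is.null(names(oligos))) names(oligos) <- paste0("o", seq_along(oligos))
  n <- length(oligos)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      fl <- passes_dimer_filter(oligos[[i]], oligos[[j]], cond = cond, ...)
      if (!fl$pass) {
        out[[length(out) + 1L]] <- data.frame(
          oligo1 = names(oligos)[i], oligo2 = names(oligos)[j],
          reason = fl$reason, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(oligo1 = character(0), oligo2 = character(0),
                      reason = character(0)))
  }
  do.call(rbind, out)
}

# Is `oligo` dimer-compatible with every member of `accepted`?
compatible_with_all <- function(oligo, accepted, cond) {
  for (o in accepted) {
    if (!passes_dimer_filter(oligo, o, cond = cond)$pass) return(FALSE)
  }
  TRUE
}

#' Design a multiplex assay panel across several targets
#'
#' Implements the predesigned-list strategy: targets are first ranked by
#' the size of their candidate primer pool (after all single-primer
#' filters, before pairing) and processed scarcest first, so
#' hard-to-design targets face the fewest constraints.  Each accepted
#' assay's oligos join the running predesigned list, and every new oligo
#' must pass the dimer filter against all previously accepted (and
#' user-supplied predesigned) oligos.  Product sizes within the panel are
#' kept within a maximum spread ratio.
#'
#' @param targets Named list of templates.
#' @param constraints [design_constraints()] applied to every target
#'   (its `tm_range` is the shared panel Tm window).
#' @param predesigned Named character vector of oligos that all new
#'   designs must be compatible with.
#' @param with_probes Also design a TaqMan probe per target and include
#'   probes in the compatibility list?
#' @param product_size_spread_max Maximum ratio of longest to shortest
#'   product in the panel.
#' @param cond [thermo_conditions()].
#' @param max_tries Ranked pairs tried per target before declaring it
#'   unsolvable.
#' @return List of class `multiplex_design`: `assays` (data frame, one
#'   row per solved target), `probes` (when requested), `oligos` (the
#'   final accepted list), `failures` (data frame: target, reason),
#'   `order` (processing order).
#' @export
design_multiplex <- function(targets, constraints = design_constraints(),
                             predesigned = character(0),
                             with_probes = FALSE,
                             product_size_spread_max = 3,
                             cond = thermo_conditions(), max_tries = 25L) {
  if (length(targets) < 2L) stop("multiplex design needs at least 2 targets")
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  # scarcity pre-analysis: candidate pool size per target
  pool <- vapply(targets, function(t) {
    nrow(generate_candidates(t, constraints, cond = cond))
  }, integer(1))
  ord <- names(targets)[order(pool, names(targets))]
  accepted <- as.list(predesigned)
  names(accepted) <- names(predesigned)
  assays <- list(); probes <- list(); failures <- list()
  sizes <- numeric(0)
  for (tn in ord) {
    pp <- design_pairs(targets[[tn]], constraints, cond = cond,
                       max_pairs = max_tries)
    solved <- FALSE
    if (nrow(pp)) {
      for (r in seq_len(nrow(pp))) {
        pr <- pp[r, ]
        if (length(sizes)) {
          rng <- range(c(sizes, pr$product_len))
          if (rng[2] / rng[1] > product_size_spread_max) next
        }
        if (!compatible_with_all(pr$f_sequence, accepted, cond)) next
        if (!compatible_with_all(pr$r_sequence, accepted, cond)) next
        probe <- NULL
        if (with_probes) {
          probe <- tryCatch(
            design_probe(targets[[tn]], pr, "TaqMan", cond),
            error = function(e) NULL)
          if (is.null(probe)) next
          if (!compatible_with_all(probe$sequence, accepted, cond)) next
        }
        pr$target <- tn
        assays[[tn]] <- pr
        accepted[[paste0(tn, "_F")]] <- pr$f_sequence
        accepted[[paste0(tn, "_R")]] <- pr$r_sequence
        if (!is.null(probe)) {
          probe$target <- tn
          probes[[tn]] <- probe
          accepted[[paste0(tn, "_P")]] <- probe$sequence
        }
        sizes <- c(sizes, pr$product_len)
        solved <- TRUE
        break
      }
    }
    if (!solved) {
      failures[[tn]] <- data.frame(
        target = tn,
        reason = if (!nrow(pp)) {
          paste("no pairs:", attr(pp, "reasons"))
        } else "no pair compatible with the accepted oligo set",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    assays = if (length(assays)) do.call(rbind, assays) else NULL,
    probes = if (length(probes)) do.call(rbind, probes) else NULL,
    oligos = unlist(accepted),
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(target = character(0), reason = character(0)),
    order = ord), class = "multiplex_design")
}

#' @export
print.multiplex_design <- function(x, ...) {
  n_ok <- if (is.null(x$assays)) 0L else nrow(x$assays)
  cat(sprintf("<multiplex_design> %d target(s) solved, %d failed; %d oligo(s) in the compatibility list\n",
              n_ok, nrow(x$failures), length(x$oligos)))
  invisible(x)
}

#' Design a tiling PCR panel over a long template
#'
#' Tiles the template with overlapping amplicons (default ~1.2 kb with
#' 500-1000 bp overlaps), designing one primer pair per amplicon with the
#' forward/reverse primers restricted to the amplicon's terminal zones.
#' Pairs are assigned to alternating pools so overlapping neighbors never
#' share a pool; within a pool every new pair must pass the dimer filter
#' against the pool's accepted primers.  A failed window triggers a local
#' re-search with a widened Tm window before a coverage gap is reported.
#'
#' @param genome Template (string or `nucleotide_sequence`),
#'   length >= 2 * `amplicon_len`.
#' @param amplicon_len Target amplicon length, bp.
#' @param overlap Length-2 numeric, allowed overlap range between
#'   adjacent amplicons, bp.
#' @param n_pools Number of pools (default 2, alternating).
#' @param pool_size_max Warn when a pool exceeds this many pairs.
#' @param constraints Base [design_constraints()]; product size and
#'   placement zones are derived per window.
#' @param size_tol Half-width of the per-amplicon product size window,
#'   bp.
#' @param cond [thermo_conditions()].
#' @return List of class `tiling_panel`: `amplicons` (data frame: index,
#'   pool, primer columns, product coordinates), `gaps` (data frame of
#'   uncovered intervals with `kind` `"internal"` or `"terminal"`;
#'   terminal slivers arise because no Tm-conforming primer can start at
#'   the extreme template ends), `covered` (logical: no internal gaps --
#'   the amplicon union is one contiguous block spanning all primer
#'   footprints).
#' @export
design_tiling_panel <- function(genome, amplicon_len = 1200L,
                                overlap = c(500L, 1000L), n_pools = 2L,
                                pool_size_max = 12L,
                                constraints = design_constraints(),
                                size_tol = 50L,
                                cond = thermo_conditions()) {
  res <- as_residues(genome)
  L <- nchar(res)
  if (L < 2L * amplicon_len) {
    stop("template shorter than two amplicon lengths; tiling not needed")
  }
  # geometry: windows slightly longer than the amplicon give the primers
  # placement slack; the stride targets an overlap near the lower bound
  # plus slack, and explicit checks keep every realized overlap within
  # bounds and pool-mates (every n_pools-th amplicon) disjoint
  span <- amplicon_len + size_tol
  zone_w <- 100L
  overlap_target <- overlap[1] + 80L
  product_bounds <- c(amplicon_len - size_tol, amplicon_len + size_tol)
  pools <- rep(seq_len(n_pools), length.out = 10000L)
  amps <- list(); gaps <- list()
  pool_oligos <- vector("list", n_pools)
  pool_last_end <- rep(0L, n_pools)
  prev_end <- NA_integer_
  cur <- 1L
  idx <- 0L
  repeat {
    idx <- idx + 1L
    if (cur + span - 1L > L) cur <- L - span + 1L
    wend <- cur + span - 1L
    zones <- data.frame(
      start = c(cur, wend - zone_w + 1L),
      end = c(cur + zone_w - 1L, wend),
      role = c("forward-zone", "reverse-zone"), stringsAsFactors = FALSE)
    pool <- pools[idx]
    found <- NULL
    for (widen in 0:2) {
      cns <- constraints
      cns$tm_range <- constraints$tm_range + c(-widen, widen)
      cns$product_size <- product_bounds
      pp <- design_pairs(res, cns, regions = zones, repeat_control = TRUE,
                         cond = cond, max_pairs = 10L)
      if (!nrow(pp)) next
      for (r in seq_len(nrow(pp))) {
        pr <- pp[r, ]
        if (!is.na(prev_end)) {
          ov <- prev_end - pr$f_start + 1L
          if (ov < overlap[1] || ov > overlap[2]) next
        }
        if (pr$f_start <= pool_last_end[pool]) next  # pool-mate overlap
        if (compatible_with_all(pr$f_sequence, pool_oligos[[pool]], cond) &&
            compatible_with_all(pr$r_sequence, pool_oligos[[pool]], cond)) {
          found <- pr
          break
        }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      gaps[[length(gaps) + 1L]] <- data.frame(start = cur, end = wend)
      nxt <- wend - overlap_target + 1L
      prev_end <- NA_integer_          # the chain is broken here
    } else {
      found$amplicon <- idx
      found$pool <- pool
      amps[[length(amps) + 1L]] <- found
      pool_oligos[[pool]] <- c(pool_oligos[[pool]],
                               found$f_sequence, found$r_sequence)
      pool_last_end[pool] <- found$r_end
      if (length(pool_oligos[[pool]]) / 2 > pool_size_max) {
        warning("pool ", pool, " exceeds ", pool_size_max, " pairs")
      }
      prev_end <- found$r_end
      nxt <- found$r_end - overlap_target + 1L
    }
    if (wend >= L) break
    cur <- nxt
  }
  amps <- if (length(amps)) {
    out <- do.call(rbind, amps)
    class(out) <- "data.frame"
    rownames(out) <- NULL
    out
  } else NULL
  # residual uncovered intervals; terminal slivers (template bases the
  # outermost primers cannot reach under the Tm constraints) are
  # distinguished from internal gaps, and coverage is judged on the span
  # between the outermost primer footprints
  gaps <- data.frame(start = integer(0), end = integer(0),
                     kind = character(0))
  covered <- FALSE
  if (!is.null(amps)) {
    cov <- rep(FALSE, L)
    for (i in seq_len(nrow(amps))) {
      cov[amps$f_start[i]:amps$r_end[i]] <- TRUE
    }
    r <- rle(cov)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    miss <- which(!r$values)
    if (length(miss)) {
      gaps <- data.frame(
        start = s[miss], end = e[miss],
        kind = ifelse(s[miss] == 1L | e[miss] == L, "terminal", "internal"),
        stringsAsFactors = FALSE)
    }
    covered <- !any(gaps$kind == "internal")
  }
  structure(list(
    amplicons = amps, gaps = gaps,
    covered = covered, amplicon_len = amplicon_len, overlap = overlap,
    n_pools = n_pools), class = "tiling_panel")
}

#' @export
print.tiling_panel <- function(x, ...) {
  cat(sprintf("<tiling_panel> %d amplicon(s) in %d pool(s); coverage %s; %d gap(s)\n",
              if (is.null(x$amplicons)) 0L else nrow(x$amplicons),
              x$n_pools, if (x$covered) "complete" else "incomplete",
              nrow(x$gaps)))
  invisible(x)
}
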