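# Allele-specific PCR (KASP-style) genotyping assay design: one
# allele-specific primer (ASP) per allele discriminating at (or near) the
# 3' terminus, plus one universal primer (UP) on the opposite flank.

#' Community-standard universal reporter tail sequences
#'
#' The two fluorescence-channel 5' tails commonly used with KASP-style
#' master mixes (FAM and HEX channel).
#' @export
kasp_reporter_tails <- c(
  FAM = "GAAGGTGACCAAGTTCATGCT",
  HEX = "GAAGGTCGGAGTCAACGGATT"
)

#' Parse inline variant notation
#'
#' A template with exactly one bracketed allele block, e.g.
#' `"ACGT[A/G]TTAA"`; `-` denotes a deletion allele.  The variant type is
#' inferred: single-base alleles are a SNP, length-varying sets (or a
#' deletion allele) an InDel, equal-length multi-base alleles an MNV --
#' phased haplotype alleles are expressed the same way, as one multi-base
#' block per phase.
#'
#' @param raw Annotated template string.
#' @return List of class `variant_template`: `left_flank`, `right_flank`,
#'   `alleles` (1-4, deletion as `""`), `variant_type`, `position`
#'   (1-based coordinate of the variant start).
#' @export
parse_variant_notation <- function(raw) {
  raw <- toupper(gsub("[\\s0-9]+", "", raw, perl = TRUE))
  m <- gregexpr("\\[[^][]*\\]", raw)[[1]]
  if (m[1] == -1L || length(m) != 1L) {
    stop("expected exactly one [x/y] variant block, found ",
         if (m[1] == -1L) 0L else length(m))
  }
  block <- regmatches(raw, m)[[1]]
  alleles <- strsplit(substr(block, 2L, nchar(block) - 1L), "/",
                      fixed = TRUE)[[1]]
  alleles[alleles == "-"] <- ""
  if (length(alleles) < 1L || length(alleles) > 4L) {
    stop("1 to 4 alleles supported, got ", length(alleles))
  }
  if (anyDuplicated(alleles)) stop("alleles must be pairwise distinct")
  left <- substr(raw, 1L, m[1] - 1L)
  right <- substr(raw, m[1] + attr(m, "match.length"), nchar(raw))
  lens <- nchar(alleles)
  type <- if (length(unique(lens)) > 1L || any(lens == 0L)) "InDel"
          else if (all(lens == 1L)) "SNP" else "MNV"
  structure(list(left_flank = left, right_flank = right,
                 alleles = alleles, variant_type = type,
                 position = nchar(left) + 1L),
            class = "variant_template")
}

#' @export
print.variant_template <- function(x, ...) {
  cat(sprintf("<variant_template> %s [%s] at %d; flanks %d/%d nt\n",
              x$variant_type,
              paste(ifelse(x$alleles == "", "-", x$alleles), collapse = "/"),
              x$position, nchar(x$left_flank), nchar(x$right_flank)))
  invisible(x)
}

#' Template sequence carrying one allele
#'
#' @param variant A [parse_variant_notation()] result.
#' @param allele One allele string (`""` for the deletion allele).
#' @return Character scalar.
#' @export
allele_template <- function(variant, allele) {
  paste0(variant$left_flank, allele, variant$right_flank)
}

common_suffix_len <- function(xs) {
  n <- min(nchar(xs))
  k <- 0L
  while (k < n) {
    ch <- substr(xs, nchar(xs) - k, nchar(xs) - k)
    if (length(unique(ch)) > 1L) break
    k <- k + 1L
  }
  k
}

common_prefix_len <- function(xs) {
  n <- min(nchar(xs))
  k <- 0L
  while (k < n) {
    ch <- substr(xs, k + 1L, k + 1L)
    if (length(unique(ch)) > 1L) break
    k <- k + 1L
  }
  k
}

# Build the per-allele ASP sequences for a shared 5' body length.  All
# ASPs start at the same template coordinate (common 5' body from the
# flank) and 3'-terminate `shift` bases beyond the last discriminating
# base; an allele whose variant-proximal core is empty (deletion, or
# fully shared with the others) is extended one base further so the 3'
# end spans the junction.  `side` "forward": ASPs on the plus strand;
# "reverse": on the minus strand (sequences returned primer-oriented).
asp_sequences <- function(variant, side, body_len, shift = 0L) {
  al <- variant$alleles
  if (side == "forward") {
    cs <- common_suffix_len(al)
    cores <- substr(al, 1L, nchar(al) - cs)
    cont <- paste0(substr(al[1], nchar(al[1]) - cs + 1L, nchar(al[1])),
                   variant$right_flank)   # continuation after the core
    body <- substr(variant$left_flank,
                   nchar(variant$left_flank) - body_len + 1L,
                   nchar(variant$left_flank))
    if (nchar(body) < body_len) return(NULL)
    ext <- shift + ifelse(nchar(cores) == 0L, 1L, 0L)
    if (any(ext > nchar(cont))) return(NULL)
    paste0(body, cores, substr(rep(cont, length(al)), 1L, ext))
  } else {
    cp <- common_prefix_len(al)
    cores <- substr(al, cp + 1L, nchar(al))
    cont <- paste0(variant$left_flank, substr(al[1], 1L, cp))
    body <- substr(variant$right_flank, 1L, body_len)
    if (nchar(body) < body_len) return(NULL)
    ext <- shift + ifelse(nchar(cores) == 0L, 1L, 0L)
    if (any(ext > nchar(cont))) return(NULL)
    plus <- paste0(substr(rep(cont, length(al)),
                          nchar(cont) - ext + 1L, nchar(cont)),
                   cores, body)
    vapply(plus, reverse_complement, character(1), USE.NAMES = FALSE)
  }
}

#' Design an allele-specific (KASP-style) genotyping assay
#'
#' For each allele an ASP is built from a shared flank-derived 5' body
#' so that its 3'-terminal base (or the near-terminal base, with
#' `placement = "penultimate"`) sits on the discriminating position: the
#' ASP anneals perfectly to its own allele and carries a 3'(-proximal)
#' mismatch on every other allele.  Deletion-allele ASPs span the
#' junction.  A universal primer is designed entirely within the opposite
#' flank, so it anneals identically to every allele, and product sizes
#' (which differ by the indel length) must fit the size bounds.  The
#' polymorphic site can ride on the forward or the reverse primer;
#' `"auto"` picks the best-ranked feasible combination.  All oligos are
#' screened jointly for dimers, G-quadruplexes and 3' hairpins.
#'
#' @param variant A [parse_variant_notation()] result.
#' @param constraints [design_constraints()]; `tm_range` applies to ASPs
#'   and UP, `product_size` to the assay products.
#' @param side `"auto"`, `"forward"` (ASPs on the plus strand) or
#'   `"reverse"`.
#' @param placement `"terminal"`, `"penultimate"` or `"auto"`.
#' @param cond [thermo_conditions()].
#' @return List of class `asp_assay`: `asps` (data frame: allele,
#'   sequence, length, tm, gc, lc, 3'-hairpin flag), `up` (one-row data
#'   frame), `side`, `placement`, `ta`, `product_len` (named per allele),
#'   `score`.
#' @export
design_asp_assay <- function(variant, constraints = design_constraints(),
                             side = c("auto", "forward", "reverse"),
                             placement = c("terminal", "penultimate",
                                           "auto"),
                             cond = thermo_conditions()) {
  side <- match.arg(side)
  placement <- match.arg(placement)
  sides <- if (side == "auto") c("forward", "reverse") else side
  placements <- if (placement == "auto") c("terminal", "penultimate")
                else placement
  best <- NULL
  for (sd in sides) {
    for (pl in placements) {
      cand <- asp_assay_one(variant, constraints, sd,
                            shift = if (pl == "terminal") 0L else 1L,
                            cond = cond)
      if (!is.null(cand) &&
          (is.null(best) || cand$score > best$score)) {
        cand$side <- sd
        cand$placement <- pl
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("no dimer-compatible allele-specific assay found ",
         "(flanks too short or constraints too tight)")
  }
  class(best) <- "asp_assay"
  best
}

asp_assay_one <- function(variant, constraints, side, shift, cond) {
  tm_mid <- mean(constraints$tm_range)
  alleles <- variant$alleles
  best_dev <- Inf; asp_set <- NULL
  for (body_len in 12L:34L) {
    seqs <- asp_sequences(variant, side, body_len, shift)
    if (is.null(seqs) || anyNA(seqs) || anyDuplicated(seqs)) next
    if (any(nchar(seqs) < 15L) || any(nchar(seqs) > 35L)) next
    tms <- vapply(seqs, melting_temperature, numeric(1), cond = cond,
                  USE.NAMES = FALSE)
    dev <- max(abs(tms - tm_mid))
    if (dev >= best_dev) next
    gcs <- vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
    lcs <- vapply(seqs, linguistic_complexity, numeric(1),
                  USE.NAMES = FALSE)
    if (any(gcs < constraints$gc_range[1] - 10) ||
        any(gcs > constraints$gc_range[2] + 10)) next
    if (any(lcs < constraints$lc_min - 15)) next
    if (any(vapply(seqs, function(s) nrow(find_gquad_intervals(s)) > 0L,
                   logical(1)))) next
    if (!all(vapply(seqs, function(s) {
      passes_dimer_filter(s, s, cond = cond)$pass
    }, logical(1)))) next
    best_dev <- dev
    asp_set <- data.frame(allele = ifelse(alleles == "", "-", alleles),
                          sequence = seqs, length = nchar(seqs), tm = tms,
                          gc = gcs, lc = lcs, row.names = NULL,
                          stringsAsFactors = FALSE)
  }
  if (is.null(asp_set)) return(NULL)
  # pairwise ASP compatibility (identical shared bodies do not pair --
  # the filter tests complementarity)
  for (i in seq_len(nrow(asp_set))) {
    for (j in seq_len(nrow(asp_set))[-seq_len(i)]) {
      if (!passes_dimer_filter(asp_set$sequence[i], asp_set$sequence[j],
                               cond = cond)$pass) {
        return(NULL)
      }
    }
  }
  # universal primer on the opposite flank
  up_tpl <- if (side == "forward") variant$right_flank
            else variant$left_flank
  cns <- constraints
  cns$mode <- "standard"
  upc <- generate_candidates(up_tpl, cns, cond = cond)
  upc <- upc[upc$strand == (if (side == "forward") "-" else "+"), ,
             drop = FALSE]
  if (!nrow(upc)) return(NULL)
  body_len <- if (side == "forward") {
    nchar(asp_set$sequence[1]) - nchar(alleles[1]) -
      (shift + (nchar(alleles[1]) == 0L))
  } else NA
  up_row <- NULL; product_len <- NULL
  for (r in seq_len(nrow(upc))) {
    plens <- if (side == "forward") {
      asp_start <- nchar(variant$left_flank) -
        (nchar(asp_set$sequence) - nchar(alleles) -
           (shift + (nchar(alleles) == 0L))) + 1L
      nchar(variant$left_flank) + nchar(alleles) + upc$end[r] -
        asp_start + 1L
    } else {
      asp_end <- nchar(variant$left_flank) + nchar(alleles) +
        (nchar(asp_set$sequence) - nchar(alleles) -
           (shift + (nchar(alleles) == 0L)))
      asp_end - upc$start[r] + 1L
    }
    if (!all(plens >= constraints$product_size[1] &
               plens <= constraints$product_size[2])) next
    ok <- all(vapply(asp_set$sequence, function(a) {
      passes_dimer_filter(a, upc$sequence[r], cond = cond)$pass
    }, logical(1)))
    if (ok) {
      up_row <- upc[r, ]
      product_len <- plens
      break
    }
  }
  if (is.null(up_row)) return(NULL)
  asp_set$hairpin_3prime <- vapply(asp_set$sequence, function(s) {
    three_prime_hairpin_check(s)$flagged
  }, logical(1), USE.NAMES = FALSE)
  ta <- annealing_temperature(min(asp_set$tm), up_row$tm,
                              max(product_len), 50, cond)
  score <- -best_dev - abs(up_row$tm - tm_mid) -
    0.5 * sum(asp_set$hairpin_3prime)
  list(asps = asp_set, up = up_row, ta = ta,
       product_len = stats::setNames(product_len,
                                     ifelse(alleles == "", "-", alleles)),
       score = score)
}

#' @export
print.asp_assay <- function(x, ...) {
  cat(sprintf("<asp_assay> %d ASP(s) + UP, %s side, %s placement; Ta %.1f\n",
              nrow(x$asps), x$side, x$placement, x$ta))
  print.data.frame(x$asps[, c("allele", "sequence", "tm", "lc")],
                   digits = 4)
  invisible(x)
}

#' Attach 5' reporter tails to an assay's allele-specific primers
#'
#' Tails are prepended to the ASPs (at most one per ASP); they do not
#' anneal to the template, so placement logic and the template-annealing
#' Tm are unchanged, but the tailed oligos are re-screened for dimer
#' compatibility and any violation rejects the tail set.
#'
#' @param assay An [design_asp_assay()] result.
#' @param tails Character vector of 5' tail sequences, one per ASP (or
#'   one recycled; empty strings allowed), e.g. [kasp_reporter_tails].
#' @param cond [thermo_conditions()].
#' @return The assay with `tailed_sequence` added to `asps`.
#' @export
attach_reporter_tails <- function(assay, tails,
                                  cond = thermo_conditions()) {
  stopifnot(inherits(assay, "asp_assay"))
  if (length(tails) == 1L) tails <- rep(tails, nrow(assay$asps))
  if (length(tails) != nrow(assay$asps)) {
    stop("need one tail per ASP (", nrow(assay$asps), "), got ",
         length(tails))
  }
  tailed <- paste0(toupper(tails), assay$asps$sequence)
  oligos <- c(tailed, assay$up$sequence)
  names(oligos) <- make.unique(c(paste0("ASP_", assay$asps$allele), "UP"))
  viol <- audit_dimer_compatibility(oligos, cond)
  if (nrow(viol)) {
    stop("reporter tail introduces a dimer violation: ",
         paste(sprintf("%s/%s (%s)", viol$oligo1, viol$oligo2,
                       viol$reason), collapse = "; "))
  }
  assay$asps$tailed_sequence <- tailed
  assay
}
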