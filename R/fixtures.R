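# Deterministic synthetic-sequence generator: repeat-laden templates,
# variant templates and fragment sets, with machine-readable ground truth.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random DNA sequence
#'
#' @param n Length in bases.
#' @param gc Target GC percent (expected, not exact).
#' @param seed Optional seed; when given the caller's RNG state is
#'   preserved.
#' @return Character scalar.
#' @export
random_dna <- function(n, gc = 50, seed = NULL) {
  draw <- function() {
    p <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200,
           T = (100 - gc) / 200)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Specify a planted sequence feature
#'
#' @param kind One of `"duplication"`, `"microsatellite"`, `"telomere"`,
#'   `"inverted"`, `"lowLC_tract"`, `"variant_block"`.
#' @param length Feature length in bases (per copy; ignored for
#'   `variant_block`; rounded to whole repeat units for tandem kinds).
#' @param copies Number of copies (duplication/inverted; the first copy is
#'   the source, subsequent copies are pasted elsewhere).
#' @param divergence Per-base substitution probability applied to
#'   non-source copies (0-1).
#' @param unit Repeat unit for microsatellites (default `"AC"`).
#' @param alleles Allele strings for `variant_block` (1-4; `"-"` for a
#'   deletion allele).
#' @return List describing the feature.
#' @export
planted_feature <- function(kind = c("duplication", "microsatellite",
                                     "telomere", "inverted", "lowLC_tract",
                                     "variant_block"),
                            length = 200L, copies = 2L, divergence = 0,
                            unit = "AC", alleles = c("A", "G")) {
  kind <- match.arg(kind)
  list(kind = kind, length = as.integer(length), copies = as.integer(copies),
       divergence = divergence, unit = unit, alleles = alleles)
}

#' Specify a synthetic template
#'
#' @param seed Integer seed; the same spec always yields byte-identical
#'   output.
#' @param length Template length, bp.
#' @param gc Background GC percent.
#' @param planted List of [planted_feature()] entries.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, length = 10000L, gc = 50,
                         planted = list()) {
  structure(list(seed = seed, length = as.integer(length), gc = gc,
                 planted = planted),
            class = "fixture_spec")
}

mutate_seq <- function(res, p) {
  if (p <= 0) return(res)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic template with planted features and ground truth
#'
#' Builds a random background at the requested GC and overwrites
#' non-overlapping stretches with the planted features (tandem repeats,
#' dispersed duplications -- optionally diverged or inverted --
#' low-complexity tracts, telomere-like arrays, variant blocks).  The
#' truth table records the exact coordinates of every planted copy,
#' enabling recall/precision audits of repeat detection and masking.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `fixture_template`: `sequence`
#'   (a `nucleotide_sequence`), `truth` (data frame: `kind`, `family`,
#'   `copy`, `start`, `end`, `strand`), and `raw` (the template with
#'   inline `[x/y]` variant notation when a `variant_block` was planted,
#'   else `NA`).
#' @export
generate_template <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    chars <- strsplit(random_dna(L, spec$gc), "", fixed = TRUE)[[1]]
    truth <- list()
    occupied <- data.frame(start = integer(0), end = integer(0))
    place <- function(len) {
      for (try in 1:200) {
        s <- sample.int(L - len + 1L, 1L)
        e <- s + len - 1L
        pad_s <- max(1L, s - 1L); pad_e <- min(L, e + 1L)
        if (!nrow(occupied) ||
            !any(intervals_overlap(occupied$start, occupied$end,
                                   pad_s, pad_e))) {
          occupied <<- rbind(occupied, data.frame(start = s, end = e))
          return(c(s, e))
        }
      }
      stop("planted features exceeding length: cannot place a ", len,
           " bp feature")
    }
    fam <- 0L
    variant_info <- NULL
    for (pf in spec$planted) {
      fam <- fam + 1L
      if (pf$kind %in% c("duplication", "inverted")) {
        unit <- random_dna(pf$length, spec$gc)
        for (cp in seq_len(pf$copies)) {
          pos <- place(pf$length)
          cseq <- if (cp == 1L) unit else mutate_seq(unit, pf$divergence)
          strand <- "+"
          if (pf$kind == "inverted" && cp > 1L) {
            cseq <- reverse_complement(cseq)
            strand <- "-"
          }
          chars[pos[1]:pos[2]] <- strsplit(cseq, "", fixed = TRUE)[[1]]
          truth[[length(truth) + 1L]] <- data.frame(
            kind = pf$kind, family = fam, copy = cp,
            start = pos[1], end = pos[2], strand = strand)
        }
      } else if (pf$kind %in% c("microsatellite", "telomere")) {
        unit <- if (pf$kind == "telomere") "TTTAGGG" else pf$unit
        n_units <- max(2L, pf$length %/% nchar(unit))
        tract <- strrep(unit, n_units)
        pos <- place(nchar(tract))
        chars[pos[1]:pos[2]] <- strsplit(tract, "", fixed = TRUE)[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          kind = pf$kind, family = fam, copy = 1L,
          start = pos[1], end = pos[2], strand = "+")
      } else if (pf$kind == "lowLC_tract") {
        base <- sample(c("A", "T"), 1L)
        tract <- paste(sample(c(base, "C"), pf$length, replace = TRUE,
                              prob = c(0.9, 0.1)), collapse = "")
        pos <- place(pf$length)
        chars[pos[1]:pos[2]] <- strsplit(tract, "", fixed = TRUE)[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          kind = pf$kind, family = fam, copy = 1L,
          start = pos[1], end = pos[2], strand = "+")
      } else if (pf$kind == "variant_block") {
        alleles <- pf$alleles
        ref <- alleles[alleles != "-"][1]
        pos <- place(max(nchar(ref), 1L))
        chars[pos[1]:pos[2]] <- strsplit(ref, "", fixed = TRUE)[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          kind = pf$kind, family = fam, copy = 1L,
          start = pos[1], end = pos[2], strand = "+")
        variant_info <- list(start = pos[1], end = pos[2],
                             alleles = alleles)
      }
    }
    res <- paste(chars, collapse = "")
    raw <- NA_character_
    if (!is.null(variant_info)) {
      raw <- paste0(
        substr(res, 1L, variant_info$start - 1L),
        "[", paste(variant_info$alleles, collapse = "/"), "]",
        substr(res, variant_info$end + 1L, L)
      )
    }
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      kind = character(0), family = integer(0), copy = integer(0),
      start = integer(0), end = integer(0), strand = character(0))
    structure(
      list(sequence = dna_sequence(res, name = paste0("fixture", spec$seed)),
           truth = truth, raw = raw, spec = spec),
      class = "fixture_template"
    )
  })
}

#' @export
print.fixture_template <- function(x, ...) {
  cat(sprintf(
    "<fixture_template> %d nt (seed %s), %d planted feature copy(ies) covering %.1f%%\n",
    length(x$sequence), format(x$spec$seed), nrow(x$truth),
    100 * sum(x$truth$end - x$truth$start + 1) / length(x$sequence)))
  invisible(x)
}
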