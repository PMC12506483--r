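# Sequence parsing, validation, topology and strand operations.

#' Construct a validated nucleotide sequence
#'
#' Creates the basic sequence container used across the package: a named,
#' validated string over the extended nucleotide alphabet (standard bases,
#' IUPAC degenerate codes, inosine `I`, and LNA bases `E`/`F`/`J`/`L` for
#' locked A/C/G/T).  Input is uppercased and stripped of whitespace and
#' digits before validation.
#'
#' @param residues Character scalar with the sequence.
#' @param name Record identifier.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param circular Logical; is the molecule circular?
#' @return An object of class `nucleotide_sequence` with fields `name`,
#'   `residues`, `alphabet`, `circular`.
#' @examples
#' dna_sequence("acg t12acgt", name = "demo")
#' @export
dna_sequence <- function(residues, name = "seq1", alphabet = c("DNA", "RNA"),
                         circular = FALSE) {
  alphabet <- match.arg(alphabet)
  residues <- clean_residues(residues)
  if (!nzchar(residues)) stop("no sequence: record '", name, "' is empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  allowed <- if (alphabet == "DNA") DNA_ALPHABET else RNA_ALPHABET
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    stop(sprintf(
      "invalid character '%s' at position %d in record '%s' (%s alphabet)",
      chars[bad[1]], bad[1], name, alphabet
    ))
  }
  if (alphabet == "DNA" && all(c("T", "U") %in% chars)) {
    stop("record '", name, "': U and T both present in a DNA-declared record")
  }
  structure(
    list(name = name, residues = residues, alphabet = alphabet,
         circular = isTRUE(circular)),
    class = "nucleotide_sequence"
  )
}

clean_residues <- function(x) {
  if (length(x) > 1L) x <- paste(x, collapse = "")
  # fast path: already clean (uppercase letters only)
  if (!grepl("[^A-Z]", x)) return(x)
  toupper(gsub("[\\s0-9]+", "", x, perl = TRUE))
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  head <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<nucleotide_sequence> %s: %d nt %s%s\n  %s\n",
              x$name, n, x$alphabet,
              if (x$circular) " (circular)" else "", head))
  invisible(x)
}

#' @export
length.nucleotide_sequence <- function(x) nchar(x$residues)

# Accept either a nucleotide_sequence or a bare string everywhere.
as_residues <- function(x) {
  if (inherits(x, "nucleotide_sequence")) x$residues
  else clean_residues(x)
}

seq_chars <- function(x) strsplit(as_residues(x), "", fixed = TRUE)[[1]]

#' Parse FASTA text into nucleotide sequences
#'
#' Accepts multi-record `>`-headed FASTA or a single bare sequence (which
#' is given the name `"seq1"`).  Characters are uppercased; whitespace and
#' digits are stripped; invalid characters raise a position-tagged error.
#'
#' @param text Character vector of lines, a single string, or a file path
#'   (existing file).
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param circular Logical flag applied to every record.
#' @return List of [dna_sequence()] objects.
#' @export
parse_fasta <- function(text, alphabet = "DNA", circular = FALSE) {
  if (length(text) == 1 && !grepl("[\n>]", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines)) | grepl("^>", lines)]
  if (!length(lines)) stop("no sequence: input is empty")
  is_header <- grepl("^>", lines)
  if (!any(is_header)) {
    return(list(dna_sequence(paste(lines, collapse = ""), "seq1",
                             alphabet, circular)))
  }
  idx <- cumsum(is_header)
  if (any(idx == 0 & nzchar(trimws(lines)))) {
    stop("sequence data before first '>' header")
  }
  out <- lapply(split(seq_along(lines), idx), function(ii) {
    hdr <- sub("^>\\s*", "", lines[ii[1]])
    name <- strsplit(trimws(hdr), "\\s+")[[1]][1]
    if (is.na(name) || !nzchar(name)) name <- "seq1"
    body <- paste(lines[ii[-1]], collapse = "")
    dna_sequence(body, name, alphabet, circular)
  })
  unname(out)
}

#' Write sequences as FASTA text
#'
#' @param seqs A `nucleotide_sequence`, a list of them, or a named
#'   character vector.
#' @param path Optional file path; when `NULL` the FASTA text is returned.
#' @param width Line wrap width.
#' @return Character vector of FASTA lines (invisibly when written).
#' @export
write_fasta <- function(seqs, path = NULL, width = 70) {
  if (inherits(seqs, "nucleotide_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) {
    nm <- names(seqs)
    if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
    seqs <- Map(function(s, n) dna_sequence(s, n), seqs, nm)
  }
  lines <- unlist(lapply(seqs, function(s) {
    res <- s$residues
    starts <- seq(1, nchar(res), by = width)
    c(paste0(">", s$name), substring(res, starts,
                                     pmin(starts + width - 1, nchar(res))))
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Extract bracketed design regions from a raw sequence
#'
#' Square brackets mark target regions for primer placement (e.g.
#' `"AAA[CCC]GGG"`).  Brackets are removed and each bracketed span is
#' reported in post-removal, 1-based inclusive coordinates.
#'
#' @param raw Raw sequence string, possibly containing balanced `[ ]`.
#' @param name,alphabet,circular Passed to [dna_sequence()].
#' @param role Role recorded for every region
#'   (`"forward-zone"`, `"reverse-zone"` or `"amplify-inside"`).
#' @return List with `sequence` (a `nucleotide_sequence`) and `regions`
#'   (data frame: `start`, `end`, `role`; zero rows when no brackets).
#' @export
extract_bracket_regions <- function(raw, name = "seq1", alphabet = "DNA",
                                    circular = FALSE,
                                    role = c("amplify-inside", "forward-zone",
                                             "reverse-zone")) {
  role <- match.arg(role)
  raw <- clean_residues(raw)
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  starts <- integer(0); ends <- integer(0)
  depth <- 0L; pos <- 0L; open_at <- NA_integer_
  for (ch in chars) {
    if (ch == "[") {
      if (depth > 0L) stop("unbalanced brackets: nested '['")
      depth <- 1L; open_at <- pos + 1L
    } else if (ch == "]") {
      if (depth == 0L) stop("unbalanced brackets: unmatched ']'")
      depth <- 0L
      if (pos >= open_at) {
        starts <- c(starts, open_at); ends <- c(ends, pos)
      }
    } else {
      pos <- pos + 1L
    }
  }
  if (depth != 0L) stop("unbalanced brackets: unmatched '['")
  stripped <- gsub("[][]", "", raw)
  list(
    sequence = dna_sequence(stripped, name, alphabet, circular),
    regions = data.frame(start = starts, end = ends,
                         role = rep(role, length(starts)),
                         stringsAsFactors = FALSE)
  )
}

#' Reverse complement
#'
#' Complements degenerate codes per IUPAC (R<->Y, S<->S, ...) and LNA codes
#' within the LNA set (E<->L, F<->J).  RNA sequences complement A<->U.
#'
#' @param seq A `nucleotide_sequence` or string.
#' @return Same type as the input.
#' @export
reverse_complement <- function(seq) {
  is_obj <- inherits(seq, "nucleotide_sequence")
  alphabet <- if (is_obj) seq$alphabet else "DNA"
  res <- as_residues(seq)
  map <- if (alphabet == "RNA") COMPLEMENT_RNA else COMPLEMENT_DNA
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  rc <- paste(rev(unname(map[chars])), collapse = "")
  if (is_obj) {
    out <- seq
    out$residues <- rc
    out$name <- paste0(seq$name, "_rc")
    out
  } else rc
}

#' Bisulfite conversion of a DNA sequence
#'
#' Emulates sodium-bisulfite treatment of unmethylated DNA assuming CpG
#' methylation: on the plus strand every cytosine *not* immediately
#' followed by guanine is converted to thymine, while CpG cytosines are
#' preserved (they carry the methylation signal).  `strand = "minus"`
#' converts the complementary strand and reports the result in plus-strand
#' coordinates: a G not immediately preceded by C becomes A.
#'
#' @param seq A DNA `nucleotide_sequence` or string (pure bases at all
#'   C/G-context positions; a degenerate base adjacent to a conversion
#'   site is an error).
#' @param strand `"plus"` or `"minus"`.
#' @return Same type as the input, converted.
#' @export
bisulfite_convert <- function(seq, strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  is_obj <- inherits(seq, "nucleotide_sequence")
  if (is_obj && seq$alphabet != "DNA") stop("bisulfite conversion is DNA-only")
  chars <- seq_chars(seq)
  n <- length(chars)
  amb <- !(chars %in% c("A", "C", "G", "T"))
  if (strand == "plus") {
    target <- chars == "C"
    ctx <- c(chars[-1], "")          # base following each position
  } else {
    target <- chars == "G"
    ctx <- c("", chars[-n])          # base preceding each position
  }
  near_amb <- amb | (target & ctx != "" & !(ctx %in% c("A", "C", "G", "T")))
  if (any(target & near_amb)) {
    stop("ambiguous conversion: degenerate base at a C/G-context position ",
         which(target & near_amb)[1])
  }
  convert <- if (strand == "plus") target & ctx != "G" else target & ctx != "C"
  chars[convert] <- if (strand == "plus") "T" else "A"
  res <- paste(chars, collapse = "")
  if (is_obj) {
    out <- seq
    out$residues <- res
    out
  } else res
}

# Interval helpers (1-based inclusive) used by several modules.
merge_intervals <- function(start, end, gap = 0L) {
  if (!length(start)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + gap + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

intervals_overlap <- function(s1, e1, s2, e2) {
  s1 <= e2 & s2 <= e1
}
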