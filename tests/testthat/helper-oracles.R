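# Independent oracles used across the suite.  Each re-derives its result
# directly from the published parameter values / definitions, separately
# from the package implementation.

ORC_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
            TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
            GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            CC = -8.0)
ORC_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
            TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
            GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            CC = -19.9)
ORC_COMP <- c(A = "T", T = "A", C = "G", G = "C")

# Literal hand-summed NN Tm: unified table + initiation + symmetry,
# CT/4 (or CT for self-complementary), monovalent correction at the
# sodium-equivalent concentration.
oracle_tm <- function(s, mono = 50, mg = 1.5, dntp = 0.8, ct_nM = 200) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  h <- 0; sv <- 0
  for (i in 1:(n - 1)) {
    k <- paste0(ch[i], ch[i + 1])
    h <- h + ORC_DH[[k]]; sv <- sv + ORC_DS[[k]]
  }
  for (t in c(ch[1], ch[n])) {
    if (t %in% c("G", "C")) { h <- h + 0.1; sv <- sv - 2.8 }
    else { h <- h + 2.3; sv <- sv + 4.1 }
  }
  rc <- paste(rev(unname(ORC_COMP[ch])), collapse = "")
  x <- if (rc == s) 1 else 4
  if (rc == s) sv <- sv - 1.4
  cf <- ct_nM * 1e-9 / x
  t1m <- 1000 * h / (sv + 1.9872 * log(cf))
  fgc <- mean(ch %in% c("G", "C"))
  na <- (mono + 120 * sqrt(max(mg - dntp, 0))) / 1000
  1 / (1 / t1m + (4.29 * fgc - 3.95) * 1e-5 * log(na) +
         9.40e-6 * log(na)^2) - 273.15
}

# Direct set-based linguistic complexity.
oracle_lc <- function(s, k_max = 5L) {
  L <- nchar(s)
  u <- 0; e <- 0
  for (k in 1:min(L, k_max)) {
    words <- character(0)
    for (i in 1:(L - k + 1)) words <- c(words, substr(s, i, i + k - 1))
    u <- u + length(unique(words))
    e <- e + min(4^k, L - k + 1)
  }
  100 * u / e
}

# Exhaustive gapless dimer scan: all maximal complementary runs >=
# min_run over all antiparallel offsets (triple loop, pure bases).
oracle_dimer_runs <- function(a, b, min_run = 2L) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  out <- NULL
  for (s in 2:(n + m)) {
    ii <- max(1, s - m):min(n, s - 1)
    if (length(ii) < min_run) next
    comp <- ca[ii] == unname(ORC_COMP[cb[s - ii]])
    r <- rle(comp)
    e <- cumsum(r$lengths); st <- e - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_run)) {
      out <- rbind(out, c(s, ii[st[k]], ii[e[k]]))
    }
  }
  out
}

# Exhaustive 3'-terminal hairpin fold enumeration.
oracle_hairpin <- function(s, stem_min = 4L, loop_min = 3L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  st_max <- (n - loop_min) %/% 2
  if (st_max < stem_min) return(FALSE)
  for (st in stem_min:st_max) {
    arm3 <- (n - st + 1):n
    up_max <- n - 2 * st - loop_min + 1
    if (up_max < 1) next
    for (i in 1:up_max) {
      arm5 <- i:(i + st - 1)
      if (all(ch[arm5] == unname(ORC_COMP[rev(ch[arm3])]))) return(TRUE)
    }
  }
  FALSE
}

# Exhaustive binding-site scan under the default in silico PCR policy
# with the seed sensitivity bound (<= 1 mismatch in the 3' 12-mer).
oracle_sites <- function(primer, tpl, max_total = 3L, max_3p = 1L) {
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  plen <- length(p)
  out <- NULL
  for (sgn in c("+", "-")) {
    tg <- if (sgn == "+") tpl else reverse_complement(tpl)
    tc <- strsplit(tg, "", fixed = TRUE)[[1]]
    L <- length(tc)
    for (e in seq_len(L)) {
      a_start <- e - plen + 1
      tail_len <- max(0, 1 - a_start)
      if (plen - tail_len < min(plen, 12)) next
      pal <- p[(tail_len + 1):plen]
      tal <- tc[(a_start + tail_len):e]
      ok <- pal == tal
      if (sum(!ok) > max_total) next
      k3 <- min(length(pal), 12)
      if (sum(!ok[(length(ok) - k3 + 1):length(ok)]) > max_3p) next
      if (!all(ok[(length(ok) - 1):length(ok)])) next
      st <- a_start + tail_len; en <- e
      if (sgn == "-") {
        st2 <- L - en + 1
        en <- st2 + (en - st)
        st <- st2
      }
      out <- rbind(out, data.frame(strand = sgn, start = st, end = en,
                                   mm = sum(!ok)))
    }
  }
  if (is.null(out)) return(data.frame(strand = character(0)))
  out[order(out$strand, out$start), , drop = FALSE]
}
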