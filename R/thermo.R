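# Oligonucleotide thermodynamics and physical quantities:
# nearest-neighbor Tm with degenerate-base averaging, salt/Mg correction,
# extinction coefficient, molecular weight, OD conversions, annealing
# temperature, and batch oligo reports.

#' Reaction conditions for thermodynamic calculations
#'
#' Default buffer follows common hot-start PCR chemistry: 50 mM monovalent
#' salt (K+), 1.5 mM Mg2+, 0.8 mM total dNTP, 200 nM oligo.
#'
#' @param monovalent Monovalent cation concentration, mM.
#' @param divalent_mg Mg2+ concentration, mM.
#' @param dntp Total dNTP concentration, mM (chelates Mg2+; the effective
#'   divalent concentration is `divalent_mg - dntp`).
#' @param oligo_conc Total oligo concentration, nM.
#' @param lna_dtm Tm increment per LNA base, degrees C.
#' @param inosine_dtm Tm increment per inosine, degrees C (negative:
#'   destabilizing).
#' @return A list of class `thermo_conditions`.
#' @export
thermo_conditions <- function(monovalent = 50, divalent_mg = 1.5,
                              dntp = 0.8, oligo_conc = 200,
                              lna_dtm = 2, inosine_dtm = -1.5) {
  if (any(c(monovalent, divalent_mg, dntp, oligo_conc) < 0)) {
    stop("thermo_conditions: concentrations must be >= 0")
  }
  if (dntp > 2 * divalent_mg) {
    warning("dNTP concentration exceeds twice the Mg2+ concentration; ",
            "Mg2+ is fully chelated")
  }
  structure(list(monovalent = monovalent, divalent_mg = divalent_mg,
                 dntp = dntp, oligo_conc = oligo_conc,
                 lna_dtm = lna_dtm, inosine_dtm = inosine_dtm),
            class = "thermo_conditions")
}

# Sodium-equivalent concentration (M): monovalent plus folded-in effective
# divalent (Mg minus chelating dNTP), 120*sqrt(mM) equivalence.
sodium_equivalent <- function(cond) {
  eff_mg <- max(cond$divalent_mg - cond$dntp, 0)
  (cond$monovalent + 120 * sqrt(eff_mg)) / 1000
}

# Map thermodynamic working alphabet: U->T, LNA -> underlying base
# (counted), inosine counted.  Returns list(chars, n_lna, n_inosine).
thermo_chars <- function(seq) {
  chars <- seq_chars(seq)
  chars[chars == "U"] <- "T"
  lna_map <- c(E = "A", F = "C", J = "G", L = "T")
  is_lna <- chars %in% names(lna_map)
  n_lna <- sum(is_lna)
  chars[is_lna] <- lna_map[chars[is_lna]]
  list(chars = chars, n_lna = n_lna, n_inosine = sum(chars == "I"))
}

expand_base <- function(ch) IUPAC_EXPANSION[[ch]]

# Mean NN dH/dS of one propagation step over all expansions of a
# (possibly degenerate) dinucleotide.
nn_step_mean <- function(b1, b2) {
  e1 <- expand_base(b1); e2 <- expand_base(b2)
  keys <- as.vector(outer(e1, e2, paste0))
  c(dh = mean(NN_DH[keys]), ds = mean(NN_DS[keys]))
}

# Duplex dH (kcal/mol) and dS (cal/mol/K) for a perfectly matched duplex
# of the given single-strand sequence, with degenerate positions averaged.
duplex_dh_ds <- function(chars) {
  n <- length(chars)
  pure <- all(chars %in% c("A", "C", "G", "T"))
  if (pure) {
    keys <- paste0(chars[-n], chars[-1])
    dh <- sum(NN_DH[keys]); ds <- sum(NN_DS[keys])
  } else {
    dh <- 0; ds <- 0
    for (i in seq_len(n - 1L)) {
      st <- nn_step_mean(chars[i], chars[i + 1L])
      dh <- dh + st[["dh"]]; ds <- ds + st[["ds"]]
    }
  }
  for (term in c(chars[1], chars[n])) {
    f_gc <- mean(expand_base(term) %in% c("G", "C"))
    dh <- dh + f_gc * NN_INIT_DH[["GC"]] + (1 - f_gc) * NN_INIT_DH[["AT"]]
    ds <- ds + f_gc * NN_INIT_DS[["GC"]] + (1 - f_gc) * NN_INIT_DS[["AT"]]
  }
  c(dh = dh, ds = ds)
}

# Owczarzy-style monovalent correction applied to a 1 M Tm (Kelvin).
salt_correct_tm <- function(tm_kelvin, f_gc, na_eq) {
  inv <- 1 / tm_kelvin + (4.29 * f_gc - 3.95) * 1e-5 * log(na_eq) +
    9.40e-6 * log(na_eq)^2
  1 / inv
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm of a short oligo (vs. its perfect complement) from the
#' unified nearest-neighbor DNA/DNA parameter set with initiation terms,
#' `Tm = dH / (dS + R ln Cf) - 273.15`, followed by a monovalent-salt
#' correction at the sodium-equivalent concentration of the buffer.
#' Degenerate positions contribute the arithmetic mean of enthalpy and
#' entropy over all expansions of each mixed-site step.  LNA bases add a
#' fixed per-base increment; inosine a fixed per-base decrement
#' (see [thermo_conditions()]).
#'
#' @param seq Oligo (string or `nucleotide_sequence`), length >= 6.
#' @param cond [thermo_conditions()].
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, cond = thermo_conditions()) {
  tc <- thermo_chars(seq)
  chars <- tc$chars
  n <- length(chars)
  if (n < 6) stop("too short for NN model (length ", n, " < 6)")
  n_options <- vapply(chars, function(ch) length(expand_base(ch)), integer(1))
  if (all(n_options > 1L)) stop("all-degenerate sequence: Tm undefined")
  hs <- duplex_dh_ds(chars)
  dh <- hs[["dh"]]; ds <- hs[["ds"]]
  self_comp <- all(n_options == 1L) &&
    paste(chars, collapse = "") ==
      reverse_complement(paste(chars, collapse = ""))
  x <- if (self_comp) 1 else 4
  if (self_comp) ds <- ds + NN_SYM_DS
  cf <- cond$oligo_conc * 1e-9 / x
  tm_1m <- 1000 * dh / (ds + GAS_CONSTANT * log(cf))
  f_gc <- gc_content(paste(chars, collapse = "")) / 100
  tm <- salt_correct_tm(tm_1m, f_gc, sodium_equivalent(cond)) - 273.15
  tm + tc$n_lna * cond$lna_dtm + tc$n_inosine * cond$inosine_dtm
}

#' GC content (percent)
#'
#' Degenerate codes contribute fractionally: the fraction of their IUPAC
#' expansions that are G or C (S counts 1, N counts 0.5, B counts 2/3,
#' ...).  LNA bases count as their underlying base.
#'
#' @param seq Sequence (string or `nucleotide_sequence`).
#' @return Percent G+C in `[0, 100]`.
#' @export
gc_content <- function(seq) {
  chars <- seq_chars(seq)
  if (!length(chars)) stop("gc_content: empty sequence")
  lna_map <- c(E = "A", F = "C", J = "G", L = "T")
  is_lna <- chars %in% names(lna_map)
  if (any(is_lna)) chars[is_lna] <- lna_map[chars[is_lna]]
  100 * sum(GC_FRACTION[chars]) / length(chars)
}

#' Molar extinction coefficient at 260 nm
#'
#' Nearest-neighbor method: the sum of dinucleotide values minus the sum
#' of internal mononucleotide values; mixed sites are averaged over their
#' expansions.
#'
#' @param seq Sequence (string or `nucleotide_sequence`).
#' @param alphabet `"DNA"` or `"RNA"` (taken from the object when given
#'   one).
#' @return Extinction coefficient, L mol-1 cm-1.
#' @export
extinction_coefficient <- function(seq, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- if (inherits(seq, "nucleotide_sequence")) seq$alphabet
                else "DNA"
  }
  mono <- if (alphabet == "RNA") EPS_MONO_RNA else EPS_MONO_DNA
  di <- if (alphabet == "RNA") EPS_DI_RNA else EPS_DI_DNA
  chars <- thermo_chars(seq)$chars
  n <- length(chars)
  if (!n) stop("extinction_coefficient: empty sequence")
  eps_mono <- function(ch) mean(mono[expand_base(ch)])
  if (n == 1L) return(eps_mono(chars))
  eps_di <- function(b1, b2) {
    mean(di[as.vector(outer(expand_base(b1), expand_base(b2), paste0))])
  }
  total <- 0
  for (i in seq_len(n - 1L)) total <- total + eps_di(chars[i], chars[i + 1L])
  if (n > 2L) {
    total <- total - sum(vapply(chars[2:(n - 1L)], eps_mono, numeric(1)))
  }
  total
}

#' Molecular weight, nmol/OD and ug/OD
#'
#' Molecular weight from standard residue masses (degenerate positions
#' averaged; LNA bases add a bridge-mass offset); `nmol/OD = 1e6 / eps260`
#' and `ug/OD = nmol/OD * MW / 1000`.
#'
#' @inheritParams extinction_coefficient
#' @return List with `mw` (g/mol), `nmol_per_od`, `ug_per_od`,
#'   `epsilon_260`.
#' @export
physical_quantities <- function(seq, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- if (inherits(seq, "nucleotide_sequence")) seq$alphabet
                else "DNA"
  }
  masses <- if (alphabet == "RNA") MW_RNA else MW_DNA
  chars <- seq_chars(seq)
  chars[chars == "U"] <- "T"
  lna_map <- c(E = "A", F = "C", J = "G", L = "T")
  res_mass <- vapply(chars, function(ch) {
    if (ch %in% names(lna_map)) {
      masses[[lna_map[[ch]]]] + MW_LNA_OFFSET
    } else if (ch == "I") {
      masses[["I"]]
    } else {
      mean(masses[expand_base(ch)])
    }
  }, numeric(1))
  mw <- sum(res_mass) + MW_BACKBONE_OFFSET
  eps <- extinction_coefficient(seq, alphabet)
  nmol <- 1e6 / eps
  list(mw = mw, nmol_per_od = nmol, ug_per_od = nmol * mw / 1000,
       epsilon_260 = eps)
}

#' Solvent volume for a target oligo concentration
#'
#' Converts a known amount of dry oligo (mass in mg, absorbance in OD260
#' units, or moles in nmol) to the solvent volume (uL) giving the
#' requested concentration.
#'
#' @param value Amount of oligo.
#' @param unit One of `"nmol"`, `"OD"`, `"mg"`.
#' @param target_conc Target concentration in uM.
#' @param seq Oligo sequence; required for `"OD"` (extinction coefficient)
#'   and `"mg"` (molecular weight).
#' @param alphabet Passed to [physical_quantities()].
#' @return Volume in uL.
#' @export
dilution_volume <- function(value, unit = c("nmol", "OD", "mg"),
                            target_conc, seq = NULL, alphabet = NULL) {
  unit <- match.arg(unit)
  if (value <= 0 || target_conc <= 0) {
    stop("dilution_volume: amount and target concentration must be > 0")
  }
  nmol <- switch(unit,
    nmol = value,
    OD = {
      if (is.null(seq)) stop("OD conversion needs the oligo sequence")
      value * 1e6 / extinction_coefficient(seq, alphabet)
    },
    mg = {
      if (is.null(seq)) stop("mass conversion needs the oligo sequence")
      value * 1e6 / physical_quantities(seq, alphabet)$mw
    }
  )
  nmol * 1000 / target_conc
}

#' Annealing temperature for a primer pair and product
#'
#' `Ta = 0.3 Tm_min + 0.7 Tm_product - 14.9`, where the product Tm uses
#' the long-duplex formula
#' `81.5 + 0.41 GC% - 675/len + 16.6 log10([Na+ eq])`.  Monotonically
#' non-decreasing in product length for fixed primers, and never above the
#' product Tm.
#'
#' @param tm_forward,tm_reverse Primer melting temperatures, degrees C.
#' @param product_len PCR product length, bp.
#' @param product_gc PCR product GC content, percent.
#' @param cond [thermo_conditions()].
#' @return Ta in degrees C.
#' @export
annealing_temperature <- function(tm_forward, tm_reverse, product_len,
                                  product_gc, cond = thermo_conditions()) {
  tm_prod <- product_tm(product_len, product_gc, cond)
  min(0.3 * min(tm_forward, tm_reverse) + 0.7 * tm_prod - 14.9, tm_prod)
}

product_tm <- function(product_len, product_gc, cond = thermo_conditions()) {
  81.5 + 0.41 * product_gc - 675 / product_len +
    16.6 * log10(sodium_equivalent(cond))
}

#' One-row physical/thermodynamic report for an oligo
#'
#' @param seq Oligo (string or `nucleotide_sequence`).
#' @param name Oligo name.
#' @param cond [thermo_conditions()].
#' @return One-row data frame: name, sequence, length, Tm, GC, LC,
#'   epsilon_260, MW, nmol_per_OD, ug_per_OD.
#' @export
oligo_report <- function(seq, name = "oligo", cond = thermo_conditions()) {
  res <- as_residues(seq)
  pq <- physical_quantities(seq)
  data.frame(
    name = name, sequence = res, length = nchar(res),
    tm = melting_temperature(seq, cond), gc = gc_content(seq),
    lc = linguistic_complexity(seq),
    epsilon_260 = pq$epsilon_260, mw = pq$mw,
    nmol_per_od = pq$nmol_per_od, ug_per_od = pq$ug_per_od,
    stringsAsFactors = FALSE
  )
}

#' Analyze a set of oligos: per-oligo reports plus pairwise dimer summary
#'
#' Every oligo is reported individually and all self- and cross-dimer
#' combinations (`n` self checks plus `C(n, 2)` cross checks) are screened
#' with the dimer filter.
#'
#' @param oligos Named character vector, or list of sequences.
#' @param cond [thermo_conditions()].
#' @return List with `reports` (data frame, one row per oligo) and
#'   `dimers` (data frame, one row per checked pair: names, pass/fail,
#'   reason, longest run, dimer Tm).
#' @export
analyze_oligo_set <- function(oligos, cond = thermo_conditions()) {
  if (is.list(oligos)) {
    nm <- names(oligos)
    oligos <- vapply(oligos, as_residues, character(1))
    names(oligos) <- nm
  }
  if (is.null(names(oligos)) || any(!nzchar(names(oligos)))) {
    names(oligos) <- paste0("oligo", seq_along(oligos))
  }
  reports <- do.call(rbind, Map(oligo_report, oligos, names(oligos),
                                MoreArgs = list(cond = cond)))
  rownames(reports) <- NULL
  pairs <- which(upper.tri(diag(length(oligos)), diag = TRUE), arr.ind = TRUE)
  dimers <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, "row"]; j <- pairs[r, "col"]
    fl <- passes_dimer_filter(oligos[[i]], oligos[[j]], cond = cond)
    data.frame(
      oligo1 = names(oligos)[i], oligo2 = names(oligos)[j],
      self = i == j, pass = fl$pass, reason = fl$reason,
      max_run = fl$max_run, dimer_tm = fl$dimer_tm,
      stringsAsFactors = FALSE
    )
  }))
  rownames(dimers) <- NULL
  list(reports = reports, dimers = dimers)
}
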