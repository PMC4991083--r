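# Unified nearest-neighbor duplex parameters (dH kcal/mol, dS cal/mol/K),
# indexed by the top-strand dinucleotide; complementary stacks share values.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex-initiation terms per terminal base pair
.NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_R <- 1.98717  # cal / (mol K)

# Tm (deg C) from summed dH (kcal/mol) and dS (cal/mol/K) with entropy salt
# correction and total-strand concentration ct (mol/L, non-self-complementary)
.tm_from_hs <- function(dh, ds, n, na_mol, ct) {
  ds_salt <- ds + 0.368 * (n - 1) * log(na_mol)
  1000 * dh / (ds_salt + .GAS_R * log(ct / 4)) - 273.15
}

#' Oligonucleotide melting temperature
#'
#' Two estimators: the Wallace rule `Tm = 2 (A+T) + 4 (G+C)` and a
#' nearest-neighbor thermodynamic sum over unified duplex parameters with an
#' entropy salt correction, evaluated at 50 mM monovalent salt and 0.25 uM
#' total oligonucleotide by default. Ambiguity codes are rejected.
#'
#' @param sequence character vector of primer sequences (A/C/G/T only).
#' @param mode `"nearest_neighbor"` (default) or `"wallace"`.
#' @param na_mol monovalent cation concentration, mol/L.
#' @param oligo_conc total strand concentration, mol/L.
#' @return numeric vector of melting temperatures in degrees C.
#' @export
melting_temp <- function(sequence, mode = c("nearest_neighbor", "wallace"),
                         na_mol = 0.05, oligo_conc = 0.25e-6) {
  mode <- match.arg(mode)
  sequence <- toupper(as.character(sequence))
  .check_dna_alphabet(sequence, "primer")
  n <- nchar(sequence)
  if (mode == "wallace") {
    at <- vapply(sequence, function(s) sum(strsplit(s, "")[[1]] %in% c("A", "T")),
                 1, USE.NAMES = FALSE)
    return(2 * at + 4 * (n - at))
  }
  if (any(n < 8L)) .abort("nearest-neighbor Tm needs length >= 8")
  vapply(sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    stacks <- paste0(ch[-length(ch)], ch[-1])
    dh <- sum(.NN_DH[stacks]) + .NN_INIT_DH[ch[1]] + .NN_INIT_DH[ch[length(ch)]]
    ds <- sum(.NN_DS[stacks]) + .NN_INIT_DS[ch[1]] + .NN_INIT_DS[ch[length(ch)]]
    .tm_from_hs(dh, ds, nchar(s), na_mol, oligo_conc)
  }, 1, USE.NAMES = FALSE)
}

# Precompute cumulative NN sums over a template string so the Tm of any
# all-ACGT substring is O(1); returns tm(start0, len) vectorized.
# Tm of a primer equals the Tm of its template footprint (duplex symmetry),
# so the same closure serves plus- and minus-strand candidates.
.tm_scan <- function(template, na_mol = 0.05, ct = 0.25e-6) {
  ch <- strsplit(template, "")[[1]]
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1])
  dh <- .NN_DH[stacks]; ds <- .NN_DS[stacks]
  dh[is.na(dh)] <- 0; ds[is.na(ds)] <- 0   # non-ACGT columns never used
  cdh <- c(0, cumsum(dh)); cds <- c(0, cumsum(ds))
  idh <- .NN_INIT_DH[ch]; ids <- .NN_INIT_DS[ch]
  function(start0, len) {
    s <- start0 + 1L; e <- start0 + len
    dh_tot <- cdh[e] - cdh[s] + idh[s] + idh[e]
    ds_tot <- cds[e] - cds[s] + ids[s] + ids[e]
    .tm_from_hs(dh_tot, ds_tot, len, na_mol, ct)
  }
}
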