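# Independent reference Tm implementation used for cross-validation.
#
# Same published unified duplex table, but a deliberately different code path:
# integer-indexed matrix lookup and positional summation instead of
# named-vector lookups, with its own inlined copy of the parameters.  The
# monovalent-salt treatment is selectable: the closed-form 16.6 log10[Na+]
# shift (default, the main model's convention) or the entropy-based
# dS' = dS + 0.368 (n-1) ln[Na+] correction (SantaLucia 1998, the convention
# Primer3's oligotm uses) for comparing across published conventions.

# 4x4 stack matrices indexed by (first base, second base) with A=1 C=2 G=3 T=4.
.ref_dH <- matrix(c(
  #      A      C      G      T     (second base)
  -7.9,  -8.4,  -7.8,  -7.2,   # A.
  -8.5,  -8.0, -10.6,  -7.8,   # C.
  -8.2,  -9.8,  -8.0,  -8.4,   # G.
  -7.2,  -8.2,  -8.5,  -7.9    # T.
), nrow = 4, byrow = TRUE)

.ref_dS <- matrix(c(
  -22.2, -22.4, -21.0, -20.4,
  -22.7, -19.9, -27.2, -21.0,
  -22.2, -24.4, -19.9, -22.4,
  -21.3, -22.2, -22.7, -22.2
), nrow = 4, byrow = TRUE)

.base_index <- function(seq) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  if (anyNA(idx)) stop_input("invalid DNA character in reference Tm input")
  idx
}

#' Reference nearest-neighbor melting temperature (cross-validation path)
#'
#' An independently coded melting-temperature calculation over the same
#' unified duplex parameters as [calc_tm()] (its own inlined table, an
#' integer-indexed summation), the second route when cross-checking that the
#' package's Tm values track an external nearest-neighbor implementation.
#' The monovalent-salt effect enters either as the closed-form
#' `16.6 log10[Na+]` shift (`"schildkraut"`, the main model's convention) or
#' as the entropic correction `dS + 0.368 (n-1) ln[Na+]` (`"santalucia"`,
#' the convention Primer3 uses), so agreement across published salt
#' conventions can be quantified as well.
#'
#' @inheritParams calc_tm
#' @param C_T Total oligo strand concentration, mol/L.
#' @param Na Monovalent cation concentration, mol/L.
#' @param salt_correction `"schildkraut"` or `"santalucia"`.
#' @return Melting temperature(s) in degrees C.
#' @export
calc_tm_reference <- function(seq, C_T = 2.5e-7, Na = 0.05,
                              salt_correction = c("schildkraut", "santalucia")) {
  salt_correction <- match.arg(salt_correction)
  if (length(seq) != 1L) {
    return(vapply(seq, calc_tm_reference, numeric(1), C_T = C_T, Na = Na,
                  salt_correction = salt_correction, USE.NAMES = FALSE))
  }
  idx <- .base_index(seq)
  n <- length(idx)
  if (n < 8L) stop_usage("sequence too short for a primer (need >= 8)")
  i <- idx[-n]
  j <- idx[-1L]
  dH <- sum(.ref_dH[cbind(i, j)])
  dS <- sum(.ref_dS[cbind(i, j)])
  for (t in idx[c(1L, n)]) {
    if (t == 2L || t == 3L) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                    { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  self_comp <- n %% 2L == 0L && all(idx + rev(idx) == 5L)
  x <- 4
  if (self_comp) { dS <- dS - 1.4; x <- 1 }
  if (salt_correction == "santalucia") {
    dS_salt <- dS + 0.368 * (n - 1L) * log(Na)
    1000 * dH / (dS_salt + 1.987 * log(C_T / x)) - 273.15
  } else {
    1000 * dH / (dS + 1.987 * log(C_T / x)) - 273.15 + 16.6 * log10(Na)
  }
}
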