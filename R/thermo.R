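# Nearest-neighbor duplex thermodynamics.
#
# Duplex stability is modeled as a sum over stacked dinucleotides of
# enthalpy/entropy increments, plus initiation terms that depend on the
# identity of each terminal base pair, plus an entropy penalty for
# self-complementary oligos.  The shipped table is the unified duplex
# parameter set (SantaLucia 1998); the schema is documented in the file
# header of extdata/nn_unified_1998.tsv so alternates can be swapped in.

.primap_env <- new.env(parent = emptyenv())

#' Nearest-neighbor thermodynamic parameters
#'
#' Loads a nearest-neighbor parameter table and bundles it with the physical
#' constants of the melting-temperature model.  The default table is the
#' unified duplex parameter set (SantaLucia 1998), read from a plain-text TSV
#' shipped with the package.
#'
#' @param table_path TSV with columns `key`, `dH` (kcal/mol), `dS`
#'   (cal/(mol*K)); keys are the 16 dinucleotide stacks plus `init_GC`,
#'   `init_AT` and `sym`.  Defaults to the bundled unified table.
#' @param C_T Total oligo strand concentration in mol/L (default 250 nM).
#' @param Na Monovalent cation concentration in mol/L (default 50 mM).
#' @return An object of class `thermo_params`: named vectors `nn_dH`, `nn_dS`
#'   over the 16 stacks, `init` (dH_GC, dS_GC, dH_AT, dS_AT), `sym_dS`, the
#'   gas constant `R` (1.987 cal/(mol*K)), `C_T` and `Na`.
#' @export
thermo_parameters <- function(table_path = NULL, C_T = 2.5e-7, Na = 0.05) {
  if (!is.numeric(C_T) || C_T <= 0) stop_usage("C_T must be > 0 mol/L")
  if (!is.numeric(Na) || Na <= 0) stop_usage("Na must be > 0 mol/L")
  default <- is.null(table_path)
  if (default && !is.null(.primap_env$nn_table)) {
    tab <- .primap_env$nn_table
  } else {
    if (default) {
      table_path <- system.file("extdata", "nn_unified_1998.tsv",
                                package = "primap", mustWork = TRUE)
    }
    tab <- read.delim(table_path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(all(c("key", "dH", "dS") %in% names(tab)))
    if (default) .primap_env$nn_table <- tab
  }
  stacks <- tab[!tab$key %in% c("init_GC", "init_AT", "sym"), ]
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  if (!setequal(stacks$key, dinucs)) {
    stop_usage("nearest-neighbor table must contain all 16 dinucleotide stacks")
  }
  nn_dH <- stats::setNames(stacks$dH, stacks$key)[dinucs]
  nn_dS <- stats::setNames(stacks$dS, stacks$key)[dinucs]
  pick <- function(k, col) tab[[col]][match(k, tab$key)]
  structure(list(
    nn_dH = nn_dH, nn_dS = nn_dS,
    init = c(dH_GC = pick("init_GC", "dH"), dS_GC = pick("init_GC", "dS"),
             dH_AT = pick("init_AT", "dH"), dS_AT = pick("init_AT", "dS")),
    sym_dS = pick("sym", "dS"), sym_dH = pick("sym", "dH"),
    R = 1.987, C_T = C_T, Na = Na
  ), class = "thermo_params")
}

.is_self_complementary <- function(seq) {
  nchar(seq) %% 2L == 0L && identical(seq, reverse_complement(seq))
}

#' Nearest-neighbor enthalpy and entropy sums
#'
#' Total duplex formation dH/dS for a sequence: initiation terms for both
#' terminal base pairs, one stack increment per adjacent dinucleotide, and the
#' symmetry entropy correction when the oligo equals its own reverse
#' complement.
#'
#' @param seq DNA string of length >= 2.
#' @param params A [thermo_parameters()] object.
#' @return Named numeric vector `c(dH = kcal/mol, dS = cal/(mol*K))`.
#' @export
nn_sums <- function(seq, params = thermo_parameters()) {
  .check_dna(seq)
  n <- nchar(seq)
  if (n < 2L) stop_usage("sequence too short for NN model (need length >= 2)")
  ends <- c(substr(seq, 1L, 1L), substr(seq, n, n))
  gc_ends <- sum(ends %in% c("G", "C"))
  at_ends <- 2L - gc_ends
  dH <- gc_ends * params$init[["dH_GC"]] + at_ends * params$init[["dH_AT"]]
  dS <- gc_ends * params$init[["dS_GC"]] + at_ends * params$init[["dS_AT"]]
  stacks <- substring(seq, 1:(n - 1L), 2:n)
  dH <- dH + sum(params$nn_dH[stacks])
  dS <- dS + sum(params$nn_dS[stacks])
  if (.is_self_complementary(seq)) {
    dH <- dH + params$sym_dH
    dS <- dS + params$sym_dS
  }
  c(dH = unname(dH), dS = unname(dS))
}

#' Nearest-neighbor melting temperature
#'
#' Two-state duplex melting temperature in degrees Celsius:
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/x)} - 273.15
#'       + 16.6 \log_{10}[\mathrm{Na}^+]}
#' where `x` is 4 for non-self-complementary oligos and 1 for
#' self-complementary ones, dH is in kcal/mol and dS in cal/(mol*K).
#'
#' @param seq DNA string (length >= 8; shorter oligos are not primers), or a
#'   character vector of such strings.
#' @param params A [thermo_parameters()] object.
#' @return Melting temperature(s) in degrees C.
#' @examples
#' calc_tm("AGCGTAAGCTTGGCACGTTA")
#' @export
calc_tm <- function(seq, params = thermo_parameters()) {
  if (length(seq) != 1L) {
    return(vapply(seq, calc_tm, numeric(1), params = params, USE.NAMES = FALSE))
  }
  if (nchar(seq) < 8L) {
    stop_usage(sprintf("sequence of length %d too short for a primer (need >= 8)",
                       nchar(seq)))
  }
  sums <- nn_sums(seq, params)
  x <- if (.is_self_complementary(seq)) 1 else 4
  tm <- 1000 * sums[["dH"]] / (sums[["dS"]] + params$R * log(params$C_T / x)) -
    273.15 + 16.6 * log10(params$Na)
  if (!is.finite(tm)) stop_usage("non-finite Tm (degenerate parameters)")
  tm
}
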