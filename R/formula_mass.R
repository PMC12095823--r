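## Molar mass from a chemical formula (Hill-notation style, e.g. C6H12O6,
## C3H8O3, H, HPO4).  Charged-formula suffixes used by BiGG (e.g. "C2H3O2")
## carry no charge symbol, so plain element counting is enough.

ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  K = 39.098, Na = 22.990, Ca = 40.078, Mg = 24.305, Cl = 35.45,
  Fe = 55.845, Zn = 65.38, Cu = 63.546, Mn = 54.938, Co = 58.933,
  Mo = 95.95, Se = 78.971, Ni = 58.693, W = 183.84, B = 10.811, I = 126.904)

#' Molar mass from a chemical formula
#'
#' Parses element counts from a formula string and sums atomic masses,
#' giving g/mol (equivalently g/mmol * 1e3).  Formulas with unknown
#' elements, generic "R" groups or polymer "X"/"(n)" notation return `NA`.
#'
#' @param formula character vector of formulas (may contain `NA` or "").
#' @return numeric vector of molar masses in g/mol.
#' @examples
#' molar_mass("C6H12O6")   # glucose, 180.156
#' molar_mass("C3H8O3")    # glycerol, 92.094
#' @export
molar_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    residue <- gsub("[A-Z][a-z]?[0-9]*", "", f)
    if (nzchar(residue) || length(toks) == 0) return(NA_real_)
    total <- 0
    for (tok in toks) {
      el <- gsub("[0-9]+", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(ATOMIC_MASS)) return(NA_real_)
      total <- total + ATOMIC_MASS[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}
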