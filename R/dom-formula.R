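# Molecular-formula arithmetic: exact masses, formula enumeration under
# CHNOSP constraints, aromaticity index, and van Krevelen classification.

#' The nine van Krevelen compound classes
#'
#' Class labels, in rule order: aromatics split by O/C, highly unsaturated
#' split by O/C, unsaturated split by O/C, unsaturated with N, saturated
#' split by O/C.
#'
#' @format Character vector of length 9.
#' @export
DOM_CLASSES <- c(
  "Aromatics O-poor",            # AI_mod > 0.5, O/C <= 0.5
  "Aromatics O-rich",            # AI_mod > 0.5, O/C >  0.5
  "Highly unsaturated O-poor",   # AI_mod <= 0.5, H/C < 1.5, O/C <= 0.5
  "Highly unsaturated O-rich",   # AI_mod <= 0.5, H/C < 1.5, O/C >  0.5
  "Unsaturated O-poor",          # 1.5 <= H/C <= 2, N = 0, O/C <= 0.5
  "Unsaturated O-rich",          # 1.5 <= H/C <= 2, N = 0, O/C >  0.5
  "Unsaturated with N",          # 1.5 <= H/C <= 2, N > 0
  "Saturated O-poor",            # H/C > 2, O/C <= 0.5
  "Saturated O-rich"             # H/C > 2, O/C >  0.5
)

formulaKey <- function(c, h, o, n, s, p) {
  sprintf("C%dH%dO%dN%dS%dP%d", c, h, o, n, s, p)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings over C, H, O, N, S, P such as `"C6H12O6"` or
#' `"C10H17NO3"` (an omitted count means 1).
#'
#' @param x character vector of formula strings.
#' @return `data.frame` with integer columns `c`, `h`, `o`, `n`, `s`, `p`.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(x) {
  one <- function(f) {
    m <- gregexpr("([CHONSP])([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f))
      stop("cannot parse formula: ", f)
    counts <- c(c = 0L, h = 0L, o = 0L, n = 0L, s = 0L, p = 0L)
    for (t in toks) {
      el <- tolower(substr(t, 1, 1))
      k <- substring(t, 2)
      counts[el] <- counts[el] + if (nzchar(k)) as.integer(k) else 1L
    }
    counts
  }
  out <- t(vapply(x, one, integer(6)))
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of exact light-isotope masses (12C = 12 exactly, 1H = 1.00782503,
#' 16O = 15.99491462, 14N = 14.00307401, 32S = 31.97207069,
#' 31P = 30.97376151).
#'
#' @param c,h,o,n,s,p element counts (vectorized).  `c` may instead be a
#'   `data.frame` with those columns (e.g. from [parseFormula()]).
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopicMass <- function(c, h = NULL, o = 0, n = 0, s = 0, p = 0) {
  if (is.data.frame(c)) {
    f <- c
    return(monoisotopicMass(f$c, f$h, f$o, f$n, f$s, f$p))
  }
  c * ISOTOPE_MASS[["c"]] + h * ISOTOPE_MASS[["h"]] +
    o * ISOTOPE_MASS[["o"]] + n * ISOTOPE_MASS[["n"]] +
    s * ISOTOPE_MASS[["s"]] + p * ISOTOPE_MASS[["p"]]
}

#' Neutral mass from a negative-mode m/z
#'
#' Assumes a singly charged deprotonated ion \[M-H\]-, so
#' `M = mz + 1.00727646` (the proton mass).  Multiply charged species and
#' adducts are not supported.
#'
#' @param mz mass-to-charge, Da (vectorized).
#' @param mode ionization mode; only `"negative"`.
#' @return Neutral monoisotopic mass, Da.
#' @export
neutralMass <- function(mz, mode = "negative") {
  if (!identical(mode, "negative"))
    stop("unsupported ionization mode: ", mode)
  mz + PROTON_MASS
}

#' Double-bond equivalents
#'
#' `DBE = 1 + C - H/2 + N/2 + P/2`.  For a valid even-electron neutral
#' molecule DBE is a non-negative integer (this encodes the nitrogen rule).
#'
#' @inheritParams monoisotopicMass
#' @return Numeric DBE (not rounded; validity checks are the caller's job).
#' @export
doubleBondEquivalents <- function(c, h = NULL, o = 0, n = 0, s = 0, p = 0) {
  if (is.data.frame(c)) {
    f <- c
    return(doubleBondEquivalents(f$c, f$h, f$o, f$n, f$s, f$p))
  }
  1 + c - h / 2 + n / 2 + p / 2
}

#' Modified aromaticity index
#'
#' `AI_mod = (1 + C - 0.5 O - S - 0.5 (H + N + P)) /
#'           (C - 0.5 O - S - N - P)`,
#' with half-weighted oxygen to account for carboxyl groups.  Clamped to 0
#' when the numerator is negative or the denominator is non-positive.
#'
#' @inheritParams monoisotopicMass
#' @return AI_mod, non-negative (vectorized).
#' @examples
#' f <- parseFormula("C6H6")
#' aiMod(f)   # 2/3: benzene is aromatic
#' @export
aiMod <- function(c, h = NULL, o = 0, n = 0, s = 0, p = 0) {
  if (is.data.frame(c)) {
    f <- c
    return(aiMod(f$c, f$h, f$o, f$n, f$s, f$p))
  }
  num <- 1 + c - 0.5 * o - s - 0.5 * (h + n + p)
  den <- c - 0.5 * o - s - n - p
  ai <- ifelse(num < 0 | den <= 0, 0, num / den)
  pmax(ai, 0)
}

#' Classify a formula into one of nine van Krevelen compound classes
#'
#' Decision order: aromatic tests first (`AI_mod > 0.5`, split by O/C at
#' 0.5); otherwise `H/C < 1.5` is highly unsaturated (split by O/C);
#' otherwise `H/C <= 2` with any nitrogen is "Unsaturated with N" (nitrogen
#' takes precedence over the O/C split); otherwise `H/C <= 2` is unsaturated
#' (split by O/C); and `H/C > 2` is saturated (split by O/C).  A boundary
#' `AI_mod` of exactly 0.5 is routed to the non-aromatic branch.  The rules
#' partition the whole constraint space: every formula receives exactly one
#' class.
#'
#' @inheritParams monoisotopicMass
#' @return Factor with levels [DOM_CLASSES].
#' @examples
#' classifyFormula(parseFormula(c("C6H6", "C6H12O6", "C10H17NO3")))
#' @export
classifyFormula <- function(c, h = NULL, o = 0, n = 0, s = 0, p = 0) {
  if (is.data.frame(c)) {
    f <- c
    return(classifyFormula(f$c, f$h, f$o, f$n, f$s, f$p))
  }
  stopifnot(all(c >= 1), all(h >= 1))
  ai <- aiMod(c, h, o, n, s, p)
  hc <- h / c
  oc <- o / c
  idx <- ifelse(ai > 0.5,
                ifelse(oc <= 0.5, 1L, 2L),
                ifelse(hc < 1.5,
                       ifelse(oc <= 0.5, 3L, 4L),
                       ifelse(hc <= 2,
                              ifelse(n > 0, 7L,
                                     ifelse(oc <= 0.5, 5L, 6L)),
                              ifelse(oc <= 0.5, 8L, 9L))))
  factor(DOM_CLASSES[idx], levels = DOM_CLASSES)
}

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Searches the CHNOSP constraint space (C 1-100, H 1-250, O up to 100,
#' N 0-4, S 0-2, P 0-1) for formulas whose monoisotopic mass matches
#' `neutralMass` within `tolPpm`.  Chemical filters: `H <= 2C + 2 + N` and
#' DBE (`1 + C - H/2 + N/2 + P/2`) a non-negative integer, which encodes the
#' nitrogen rule for even-electron neutral molecules.  Oxygen-free formulas
#' are excluded by default (`minOxygen = 1`), matching marine-DOM reporting
#' conventions.
#'
#' @param neutralMass neutral monoisotopic mass, Da (scalar).
#' @param tolPpm mass tolerance in ppm, default 0.5.
#' @param minOxygen minimum oxygen count, 0 or 1 (default 1).
#' @param limits element-count limits, a named list like `ELEMENT_LIMITS`.
#' @return `data.frame` with columns `c`, `h`, `o`, `n`, `s`, `p`, `mass`,
#'   `error_ppm`, `dbe`, sorted by `abs(error_ppm)`; zero rows when nothing
#'   matches.
#' @examples
#' m <- monoisotopicMass(parseFormula("C15H22O8"))
#' enumerateFormulas(m, tolPpm = 0.5)
#' @export
enumerateFormulas <- function(neutralMass, tolPpm = 0.5, minOxygen = 1,
                              limits = ELEMENT_LIMITS) {
  # tolPpm capped where the window stays well below one hydrogen mass, so
  # the single-H-per-combination search below is exhaustive
  stopifnot(length(neutralMass) == 1, tolPpm > 0, tolPpm <= 50,
            minOxygen %in% 0:1)
  tolDa <- neutralMass * tolPpm * 1e-6
  mUp <- neutralMass + tolDa

  empty <- data.frame(c = integer(), h = integer(), o = integer(),
                      n = integer(), s = integer(), p = integer(),
                      mass = numeric(), error_ppm = numeric(),
                      dbe = numeric())
  cMax <- min(limits$c[2], floor(mUp / ISOTOPE_MASS[["c"]]))
  if (cMax < limits$c[1]) return(empty)
  oMin <- max(limits$o[1], minOxygen)
  oMax <- min(limits$o[2], floor(mUp / ISOTOPE_MASS[["o"]]))
  if (oMax < oMin) return(empty)

  hetero <- expand.grid(n = limits$n[1]:limits$n[2],
                        s = limits$s[1]:limits$s[2],
                        p = limits$p[1]:limits$p[2])
  g <- expand.grid(c = limits$c[1]:cMax, o = oMin:oMax,
                   k = seq_len(nrow(hetero)))
  g$n <- hetero$n[g$k]
  g$s <- hetero$s[g$k]
  g$p <- hetero$p[g$k]

  base <- g$c * ISOTOPE_MASS[["c"]] + g$o * ISOTOPE_MASS[["o"]] +
    g$n * ISOTOPE_MASS[["n"]] + g$s * ISOTOPE_MASS[["s"]] +
    g$p * ISOTOPE_MASS[["p"]]
  # the ppm window (< 0.01 Da) is far narrower than one hydrogen, so at
  # most one integer H count can match per (C,O,N,S,P) combination
  h <- round((neutralMass - base) / ISOTOPE_MASS[["h"]])
  mass <- base + h * ISOTOPE_MASS[["h"]]
  errPpm <- (mass - neutralMass) / neutralMass * 1e6
  dbe <- 1 + g$c - h / 2 + g$n / 2 + g$p / 2
  keep <- h >= limits$h[1] & h <= limits$h[2] &
    h <= 2 * g$c + 2 + g$n &
    abs(errPpm) <= tolPpm &
    dbe >= 0 & abs(dbe - round(dbe)) < 1e-9
  if (!any(keep)) return(empty)

  out <- data.frame(c = g$c[keep], h = as.integer(h[keep]), o = g$o[keep],
                    n = g$n[keep], s = g$s[keep], p = g$p[keep],
                    mass = mass[keep], error_ppm = errPpm[keep],
                    dbe = dbe[keep])
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
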