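# Elemental-formula parsing and monoisotopic m/z arithmetic for the
# charge-tagged derivatization model.

.thioltrace_env <- new.env(parent = emptyenv())

#' Mass of the electron in Da
#'
#' Used for the electron-mass correction of every ion m/z. The correction is
#' always applied: the probe's printed cation m/z is only reproduced within
#' 1 ppm with it.
#' @export
ELECTRON_MASS <- 0.000548579909

#' Packaged monoisotopic atomic masses
#'
#' Returns the packaged table of most-abundant-isotope atomic masses
#' (CODATA/NIST values, >= 7 decimals). The table is fixed at build time so
#' every m/z in the package is bit-reproducible; no external service is ever
#' queried.
#'
#' @return Named numeric vector, element symbol -> monoisotopic mass in Da.
#' @export
atomic_masses <- function() {
  if (is.null(.thioltrace_env$atomic_masses)) {
    path <- system.file("extdata", "atomic_masses.csv", package = "thioltrace")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .thioltrace_env$atomic_masses <- stats::setNames(tab$mass, tab$element)
  }
  .thioltrace_env$atomic_masses
}

#' Parse a Hill-notation elemental formula
#'
#' Element symbols are one uppercase letter optionally followed by one
#' lowercase letter; an omitted count means 1. Only plain Hill notation is
#' accepted (no underscores, charges or isotope markup).
#'
#' @param text Formula string, e.g. `"C6H12N2O4S"`.
#' @return An `elemental_formula`: named integer vector of element counts.
#' @examples
#' parse_formula("C6H12N2O4S")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  if (grepl("_", text, fixed = TRUE))
    stop("formula '", text, "' contains underscores; use plain Hill notation ",
         "(e.g. C6H12N2O4S)", call. = FALSE)
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*|.", text))[[1]]
  bad <- toks[!grepl("^[A-Z][a-z]?[0-9]*$", toks)]
  if (length(bad))
    stop("cannot parse formula '", text, "' at token '", bad[1L], "'",
         call. = FALSE)
  known <- names(atomic_masses())
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% known)
      stop("unknown element symbol '", el, "' in formula '", text, "'",
           call. = FALSE)
    nstr <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    if (is.na(n) || n <= 0L)
      stop("element '", el, "' in formula '", text,
           "' has a non-positive count", call. = FALSE)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  structure(counts, class = "elemental_formula")
}

.as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f)))
    return(structure(as.integer(f[f > 0]), names = names(f)[f > 0],
                     class = "elemental_formula"))
  stop("not an elemental formula", call. = FALSE)
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (!length(x)) return("")
  els <- names(x)
  # Hill order: C, H, then remaining elements alphabetically
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (x[[e]] > 1L) x[[e]] else ""), character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Add or subtract elemental compositions
#'
#' `formula_add()` sums counts; `formula_subtract()` removes them and fails
#' if any count would go negative (compositional bookkeeping must close).
#'
#' @param a,b Formulas (strings or `elemental_formula`).
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) + (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  .as_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) - (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  if (any(out < 0L))
    stop("composition subtraction went negative for element(s): ",
         paste(els[out < 0L], collapse = ", "), call. = FALSE)
  .as_formula(out)
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses from the packaged table. An
#' empty formula has mass 0.
#'
#' @param f Formula string or `elemental_formula`.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return(0)
  masses <- atomic_masses()
  sum(masses[names(f)] * as.numeric(f))
}

#' m/z of a bare cation
#'
#' `(neutral-sum mass - charge * electron mass) / charge`. The composition is
#' the cation's own (the charge carrier is part of the formula); only the
#' missing electrons are corrected for.
#'
#' @param f Formula of the cation's composition.
#' @param charge Positive integer charge.
#' @return m/z in Th.
#' @export
cation_mz <- function(f, charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
      charge < 1 || charge != round(charge))
    stop("charge must be a positive integer", call. = FALSE)
  (monoisotopic_mass(f) - charge * ELECTRON_MASS) / charge
}

#' Derivatization probe specification
#'
#' Describes the charge-tagged thiol probe: the probe cation composition,
#' the neutral lost on conjugation, and the diagnostic (reporter) fragment
#' shared by all derivatives. Defaults describe the brominated
#' triphenylphosphonium tag: cation C25H28BrNP (+1), HBr leaving group, and
#' a sulfur-retaining tag fragment C25H29NPS whose cation computes to
#' m/z 406.1753 (consistent with the monitored reporter at m/z 406.17).
#'
#' @param cation_formula Probe cation composition (charge +1).
#' @param leaving_group Neutral lost when the thiol conjugates.
#' @param diagnostic_fragment_formula Tag-side fragment composition, or NULL.
#' @param diagnostic_fragment_mz Reporter m/z; computed from the fragment
#'   formula when one is given.
#' @return A `probe_spec` list.
#' @export
probe_spec <- function(cation_formula = "C25H28BrNP",
                       leaving_group = "HBr",
                       diagnostic_fragment_formula = "C25H29NPS",
                       diagnostic_fragment_mz = NULL) {
  cation <- .as_formula(cation_formula)
  leaving <- .as_formula(leaving_group)
  frag <- if (!is.null(diagnostic_fragment_formula))
    .as_formula(diagnostic_fragment_formula) else NULL
  if (is.null(diagnostic_fragment_mz)) {
    if (is.null(frag))
      stop("either diagnostic_fragment_formula or diagnostic_fragment_mz ",
           "must be given", call. = FALSE)
    diagnostic_fragment_mz <- cation_mz(frag, 1L)
  }
  structure(list(cation_formula = cation,
                 leaving_group = leaving,
                 diagnostic_fragment_formula = frag,
                 diagnostic_fragment_mz = diagnostic_fragment_mz),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat("<probe_spec>\n",
      "  cation:   ", format(x$cation_formula), " (m/z ",
      sprintf("%.4f", cation_mz(x$cation_formula, 1L)), ")\n",
      "  leaving:  ", format(x$leaving_group), "\n",
      "  reporter: m/z ", sprintf("%.4f", x$diagnostic_fragment_mz), "\n",
      sep = "")
  invisible(x)
}

#' Composition of a thiol derivative cation
#'
#' Derivative = probe cation + thiol - leaving group (strictly additive).
#'
#' @param thiol Thiol formula.
#' @param probe A [probe_spec()].
#' @return An `elemental_formula` for the singly charged derivative cation.
#' @export
derivative_formula <- function(thiol, probe = probe_spec()) {
  thiol <- .as_formula(thiol)
  if (!("S" %in% names(thiol)))
    warning("analyte formula ", format(thiol),
            " contains no sulfur; computing a derivative mass anyway")
  formula_subtract(formula_add(probe$cation_formula, thiol),
                   probe$leaving_group)
}

#' Theoretical m/z of a singly charged thiol derivative
#'
#' @inheritParams derivative_formula
#' @return m/z in Th (electron-mass corrected).
#' @examples
#' derivative_mz("C3H7NO2S") # cysteine derivative, 493.2073
#' @export
derivative_mz <- function(thiol, probe = probe_spec()) {
  cation_mz(derivative_formula(thiol, probe), 1L)
}

#' Registered ionization adducts
#'
#' Packaged registry (name, delta formula, charge). Only singly charged
#' adducts are packaged (`M+H`, `M+Na`), matching the library's charge-1
#' records.
#'
#' @return data.frame with columns name, delta_formula, charge.
#' @export
adduct_registry <- function() {
  if (is.null(.thioltrace_env$adducts)) {
    path <- system.file("extdata", "adducts.csv", package = "thioltrace")
    .thioltrace_env$adducts <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .thioltrace_env$adducts
}

#' m/z of a neutral molecule under a registered adduct
#'
#' `(mass(neutral) + mass(delta) - z * electron mass) / z`.
#'
#' @param neutral Neutral formula.
#' @param adduct Adduct name, e.g. `"M+H"`.
#' @return m/z in Th.
#' @export
adduct_mz <- function(neutral, adduct) {
  reg <- adduct_registry()
  i <- match(adduct, reg$name)
  if (is.na(i))
    stop("unknown adduct '", adduct, "'; registered: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  z <- reg$charge[i]
  (monoisotopic_mass(neutral) + monoisotopic_mass(reg$delta_formula[i]) -
     z * ELECTRON_MASS) / z
}

#' Signed mass error in parts per million
#'
#' `ppm = 1e6 * (observed - theoretical) / theoretical`; the theoretical
#' value is always the denominator, so swapping arguments flips the sign
#' only approximately.
#'
#' @param observed,theoretical m/z in Th; `theoretical` must be > 0.
#' @return A `mass_error` list with fields observed_mz, theoretical_mz, ppm.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("theoretical m/z must be positive", call. = FALSE)
  structure(list(observed_mz = observed, theoretical_mz = theoretical,
                 ppm = 1e6 * (observed - theoretical) / theoretical),
            class = "mass_error")
}

#' @export
print.mass_error <- function(x, ...) {
  cat(sprintf("<mass_error> obs %.4f vs theo %.4f: %+.2f ppm\n",
              x$observed_mz, x$theoretical_mz, x$ppm))
  invisible(x)
}

#' The seven targeted thiols
#'
#' Packaged monitored-transition list: analyte, elemental formula, printed
#' monitored precursor and product m/z. The printed values are experimental
#' observations; `transitions_table()` recomputes theory next to them.
#'
#' @return data.frame with one row per targeted thiol.
#' @export
thiol_targets <- function() {
  path <- system.file("extdata", "table1_transitions.csv",
                      package = "thioltrace")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Monitored-transition table computed from the probe model
#'
#' For each targeted thiol: theoretical derivative precursor m/z and the
#' shared diagnostic product m/z from the probe spec, alongside the printed
#' monitored values and the signed ppm deviation.
#'
#' @param probe A [probe_spec()].
#' @return data.frame with columns analyte, formula, theoretical_mz,
#'   product_mz, printed_mz, ppm_vs_printed.
#' @export
transitions_table <- function(probe = probe_spec()) {
  tt <- thiol_targets()
  theo <- vapply(tt$formula, function(f) derivative_mz(f, probe), numeric(1))
  data.frame(analyte = tt$analyte,
             formula = tt$formula,
             theoretical_mz = round(theo, 4),
             product_mz = round(probe$diagnostic_fragment_mz, 4),
             printed_mz = tt$precursor_mz,
             ppm_vs_printed = round(1e6 * (theo - tt$precursor_mz) /
                                      tt$precursor_mz, 2),
             row.names = NULL)
}
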