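# Molecular formulas, monoisotopic masses and m/z arithmetic for
# Girard-hydrazone derivative cations and the marker ions of the workflow.

# Monoisotopic (most abundant isotope) atomic masses, Da. CODATA/IUPAC,
# >= 6 decimals. Extend here if new target compounds need more elements.
.MONOISOTOPIC <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  Na = 22.9897692809,
  Mg = 23.985041700,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Fe = 55.93493750,
  Br = 78.9183371,
  I  = 126.904473
)

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- 1.007276466621

#' Molecular formula with monoisotopic-mass semantics
#'
#' A named map from element symbol to a non-negative integer count. Use
#' [parseFormula()] to construct one from a Hill-notation string.
#'
#' @slot counts Named integer vector of element counts.
#' @export
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
  cnt <- object@counts
  if (length(cnt) && is.null(names(cnt)))
    return("element counts must be named")
  bad <- setdiff(names(cnt), names(.MONOISOTOPIC))
  if (length(bad))
    return(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  if (any(cnt < 0)) return("element counts must be >= 0")
  if (anyDuplicated(names(cnt))) return("duplicated element symbols")
  TRUE
})

#' Parse a Hill-notation molecular formula
#'
#' Accepts strings such as `"C25H34O6"` or `"H2O"`. A trailing `"+"` (charge
#' annotation on a pre-charged cation) is tolerated and ignored; the charge is
#' carried by [ionMz()] / [derivativeMz()], not by the formula.
#'
#' @param text Formula string, e.g. `"C24H31FO6"`.
#' @return A [MolecularFormula-class] object.
#' @examples
#' parseFormula("C25H34O6")   # budesonide
#' parseFormula("H2O")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  s <- sub("\\+$", "", trimws(text))
  if (!nzchar(s)) return(new("MolecularFormula", counts = integer(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    covered <- unlist(Map(function(st, len) seq(st, st + len - 1L),
                          as.integer(m), attr(m, "match.length")))
    badpos <- setdiff(seq_len(nchar(s)), covered)[1]
    stop(sprintf("malformed formula '%s': unexpected token at '%s'",
                 text, substr(s, badpos, nchar(s))))
  }
  sym <- sub("[0-9]*$", "", tokens)
  num <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(num), as.integer(num), 1L)
  bad <- setdiff(sym, names(.MONOISOTOPIC))
  if (length(bad))
    stop(sprintf("unknown element symbol(s) in '%s': %s",
                 text, paste(unique(bad), collapse = ", ")))
  counts <- vapply(split(cnt, sym), sum, 0L)
  new("MolecularFormula", counts = counts[order(names(counts))])
}

.asFormula <- function(f) {
  if (is(f, "MolecularFormula")) f else parseFormula(f)
}

#' Canonical Hill-notation string of a formula
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (plain alphabetical order when no carbon is present). Zero-count elements
#' are dropped.
#'
#' @param f A [MolecularFormula-class] or a formula string.
#' @return A single character string.
#' @export
formulaToHill <- function(f) {
  cnt <- .asFormula(f)@counts
  cnt <- cnt[cnt > 0L]
  if (!length(cnt)) return("")
  els <- names(cnt)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste0(ord, ifelse(cnt[ord] > 1L, cnt[ord], ""), collapse = "")
}

#' Merge two molecular formulas by adding element counts
#'
#' @param f1,f2 [MolecularFormula-class] objects or formula strings.
#' @return A [MolecularFormula-class].
#' @export
combineFormulas <- function(f1, f2) {
  c1 <- .asFormula(f1)@counts
  c2 <- .asFormula(f2)@counts
  els <- union(names(c1), names(c2))
  out <- setNames(integer(length(els)), els)
  out[names(c1)] <- out[names(c1)] + c1
  out[names(c2)] <- out[names(c2)] + c2
  new("MolecularFormula", counts = out[order(names(out))])
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times most-abundant-isotope atomic masses. The empty
#' formula has mass 0.
#'
#' @param f A [MolecularFormula-class] or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("H2O")       # 18.010565
#' monoisotopicMass("C25H34O6")  # budesonide, 430.23554
#' @export
monoisotopicMass <- function(f) {
  cnt <- .asFormula(f)@counts
  if (!length(cnt)) return(0)
  sum(cnt * .MONOISOTOPIC[names(cnt)])
}

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", formulaToHill(object),
      sprintf("(monoisotopic %.6f Da)\n", monoisotopicMass(object)))
})

# Girard reagent cation compositions (the quaternary nitrogen carries the
# charge; the composition below is the cation's elemental composition).
.GIRARD_CATIONS <- list(
  GirP = "C7H10N3O",  # 1-(2-hydrazinyl-2-oxoethyl)pyridinium
  GirT = "C5H14N3O"   # (2-hydrazinyl-2-oxoethyl)trimethylammonium
)

#' m/z of a Girard hydrazone derivative cation
#'
#' The hydrazide of a Girard reagent condenses with a steroid ketone, losing
#' one water per condensation; the product is a pre-charged cation (the
#' pyridinium/trimethylammonium nitrogen carries the charge, no proton is
#' added). Only a single condensation of a singly charged derivative is
#' supported:
#' `m/z = mass(steroid) + mass(reagent cation) - mass(H2O) - electron`.
#'
#' @param steroid Steroid [MolecularFormula-class] or formula string; must
#'   contain at least one oxygen (a carbonyl is assumed; chemical validity is
#'   the caller's responsibility).
#' @param reagent `"GirP"` (default) or `"GirT"`.
#' @param nCondensations Number of hydrazone condensations; only 1 supported.
#' @return m/z of the derivative cation.
#' @examples
#' derivativeMz("C25H34O6")            # budesonide-GirP, 564.3068
#' derivativeMz("C24H31FO6")           # triamcinolone acetonide-GirP, 568.2817
#' @export
derivativeMz <- function(steroid, reagent = c("GirP", "GirT"),
                         nCondensations = 1L) {
  reagent <- match.arg(reagent)
  if (nCondensations != 1L)
    stop("unsupported operation: only a single condensation (nCondensations = 1) is supported")
  st <- .asFormula(steroid)
  nO <- st@counts["O"]
  if (is.na(nO) || nO < 1L)
    stop("steroid formula must contain at least one oxygen (carbonyl assumed)")
  monoisotopicMass(st) + monoisotopicMass(.GIRARD_CATIONS[[reagent]]) -
    monoisotopicMass("H2O") - .ELECTRON_MASS
}

#' m/z of an ion from its formula, charge and ion type
#'
#' * `protonated`: (M + z * proton) / z
#' * `radical-cation`: (M - z * electron) / z
#' * `pre-charged-cation`: (M - z * electron) / z, where the formula already
#'   contains the charge-carrying composition (e.g. a quaternary nitrogen).
#'
#' The electron-mass correction is always applied (Orbitrap-accuracy
#' arithmetic).
#'
#' @param formula [MolecularFormula-class] or formula string.
#' @param ionType One of `"protonated"`, `"pre-charged-cation"`,
#'   `"radical-cation"`.
#' @param charge Positive integer charge.
#' @return m/z.
#' @examples
#' ionMz("C34H32FeN4O4", "radical-cation")     # heme B, 616.1767
#' ionMz("C19H22NO4S2", "pre-charged-cation")  # tiotropium, 392.0985
#' ionMz("C10H10O4", "protonated")             # ferulic acid, 195.0652
#' @export
ionMz <- function(formula,
                  ionType = c("protonated", "pre-charged-cation",
                              "radical-cation"),
                  charge = 1L) {
  ionType <- match.arg(ionType)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer (>= 1)")
  M <- monoisotopicMass(formula)
  z <- as.numeric(charge)
  switch(ionType,
    "protonated"        = (M + z * .PROTON_MASS) / z,
    "radical-cation"    = (M - z * .ELECTRON_MASS) / z,
    "pre-charged-cation" = (M - z * .ELECTRON_MASS) / z
  )
}

#' Built-in extraction-target table of the budesonide workflow
#'
#' The five ions the pipeline extracts by default: the budesonide-GirP
#' derivative (analyte), the triamcinolone acetonide-GirP derivative
#' (internal standard), the tiotropium cation (calibration-spot marker),
#' heme B (tissue marker) and protonated ferulic acid (matrix lock mass).
#' All m/z values are computed from the elemental compositions, not typed in.
#'
#' @return `data.frame` with columns `name`, `formula`, `ion_type`, `mz`,
#'   `role`.
#' @export
defaultTargets <- function() {
  df <- data.frame(
    name = c("budesonide-GirP", "triamcinolone-acetonide-GirP",
             "tiotropium", "heme-B", "ferulic-acid"),
    formula = c("C25H34O6", "C24H31FO6", "C19H22NO4S2", "C34H32FeN4O4",
                "C10H10O4"),
    ion_type = c("girard-derivative", "girard-derivative",
                 "pre-charged-cation", "radical-cation", "protonated"),
    role = c("analyte", "internal_standard", "spot_marker", "tissue_marker",
             "lock_mass"),
    stringsAsFactors = FALSE
  )
  df$mz <- vapply(seq_len(nrow(df)), function(i) {
    if (df$ion_type[i] == "girard-derivative") derivativeMz(df$formula[i])
    else ionMz(df$formula[i], df$ion_type[i])
  }, 0)
  df[, c("name", "formula", "ion_type", "mz", "role")]
}

#' Read a target table from CSV
#'
#' Columns: `name`, `formula_or_mz`, `ion_type`, `role`. `formula_or_mz` may
#' be a Hill formula (m/z computed via `ion_type`, with `"girard-derivative"`
#' meaning the GirP hydrazone cation of the given steroid) or a fixed numeric
#' m/z (`ion_type` ignored).
#'
#' @param path CSV file path.
#' @return `data.frame` as [defaultTargets()].
#' @export
readTargetTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula_or_mz", "ion_type", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("target table misses column(s): ", paste(miss, collapse = ", "))
  mz <- suppressWarnings(as.numeric(df$formula_or_mz))
  form <- ifelse(is.na(mz), df$formula_or_mz, NA_character_)
  for (i in which(is.na(mz))) {
    mz[i] <- if (df$ion_type[i] == "girard-derivative")
      derivativeMz(form[i]) else ionMz(form[i], df$ion_type[i])
  }
  data.frame(name = df$name, formula = form, ion_type = df$ion_type,
             mz = mz, role = df$role, stringsAsFactors = FALSE)
}
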