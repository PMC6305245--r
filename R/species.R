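#' Physical constants used throughout the package
#'
#' Exact SI values (2019 redefinition) for the elementary charge and the
#' unified atomic mass unit, plus the electron mass in u.  All internal
#' computation is done in strict SI units (kg, m, s, V/m); nanoseconds,
#' millimetres and kilovolts appear only at file-format and configuration
#' boundaries.
#'
#' @format A named numeric vector with elements `elementary_charge` (C),
#'   `atomic_mass_unit` (kg) and `electron_mass_u` (u).
#' @export
physical_constants <- c(
  elementary_charge = 1.602176634e-19,
  atomic_mass_unit  = 1.66053906660e-27,
  electron_mass_u   = 5.48579909065e-4
)

## monoisotopic masses of the elements that occur in CHCA-related ions (u)
.monoisotopic <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  Na = 22.9897692809
)

#' Monoisotopic mass of an ion from its elemental formula
#'
#' Parses a Hill-style formula such as `"C10H8NO3"` and sums monoisotopic
#' element masses; for a charged species the mass of the removed electrons
#' is subtracted.
#'
#' @param formula Elemental formula, e.g. `"C10H8NO3"`.  Element symbols
#'   with optional counts; no parentheses or isotope labels.
#' @param charge Number of elementary positive charges (electrons removed).
#' @return Ion mass in unified atomic mass units.
#' @examples
#' monoisotopic_mass("C10H8NO3", charge = 1)  # protonated CHCA, ~190.05 u
#' @export
monoisotopic_mass <- function(formula, charge = 0) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (p in parts) {
    sym <- gsub("[0-9]", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.monoisotopic))
      stop("element not in mass table: ", sym)
    total <- total + n * .monoisotopic[[sym]]
  }
  total - charge * physical_constants[["electron_mass_u"]]
}

#' Define an ion species
#'
#' A light container for one plume ion: its label, monoisotopic mass and
#' charge.  The mass in kg (`mass_kg`) and the acceleration it experiences
#' per unit field are derived once here and reused by all kinematics.
#'
#' @param label Free-text label, e.g. `"(CHCA)H+"`.
#' @param mass Ion mass in unified atomic mass units.
#' @param charge Positive integer number of elementary charges.
#' @param nominal_mz Integer m/z used for display; defaults to
#'   `round(mass / charge)` and must lie within 1 of it.
#' @param formula Optional elemental formula kept for provenance.
#' @return An object of class `ion_species`.
#' @examples
#' ion_species("(CHCA)H+", monoisotopic_mass("C10H8NO3", 1))
#' @export
ion_species <- function(label, mass, charge = 1L, nominal_mz = NULL,
                        formula = NA_character_) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0)
  charge <- as.integer(charge)
  stopifnot(charge >= 1L)
  if (is.null(nominal_mz)) nominal_mz <- as.integer(round(mass / charge))
  if (abs(nominal_mz - mass / charge) > 1)
    stop("nominal_mz ", nominal_mz, " is more than 1 u from mass/charge")
  structure(
    list(label = label, mass = mass, charge = charge,
         nominal_mz = as.integer(nominal_mz), formula = formula,
         mass_kg = mass * physical_constants[["atomic_mass_unit"]]),
    class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s  m/z %d  (%.4f u, %d+)\n",
              x$label, x$nominal_mz, x$mass, x$charge))
  invisible(x)
}

#' CHCA-related ion species table
#'
#' The ions observed in a CHCA (alpha-cyano-4-hydroxycinnamic acid) MALDI
#' spectrum: the protonated monomer and proton-bound dimer, the sodium
#' adduct and the water-loss ion.  Masses are monoisotopic and read from
#' the species table shipped with the package; each is cross-checked
#' against its elemental formula at load time.
#'
#' @param path Optional path to an alternative species CSV with columns
#'   `label,formula,mass_u,charge,nominal_mz`.
#' @return Named list of [ion_species] objects, keyed by label.
#' @examples
#' chca_species()[["(CHCA)H+"]]
#' @export
chca_species <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chca_species.csv", package = "plumetrace",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "formula", "mass_u", "charge", "nominal_mz")
  if (!all(need %in% names(tab)))
    stop("species table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    sp <- ion_species(tab$label[i], tab$mass_u[i], tab$charge[i],
                      tab$nominal_mz[i], tab$formula[i])
    ref <- monoisotopic_mass(tab$formula[i], tab$charge[i])
    if (abs(ref - sp$mass) > 5e-4)
      stop("mass of ", sp$label, " disagrees with its formula by ",
           signif(abs(ref - sp$mass), 2), " u")
    sp
  })
  names(out) <- tab$label
  out
}
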