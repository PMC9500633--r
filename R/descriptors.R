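#' Canonical descriptor column order
#'
#' The eight electronic-structure descriptors used throughout the package, in
#' the fixed order that all design matrices and component panels follow:
#' highest occupied orbital energy (HOMO), lowest unoccupied orbital energy
#' (LUMO), ionization potential, electron affinity, absolute
#' electronegativity, absolute hardness, molecular energy, and adsorption
#' energy. Orbital-derived quantities are in eV; molecular and adsorption
#' energies are taken in whatever units the input supplies.
#'
#' @return Character vector of the eight descriptor column names.
#' @export
descriptor_names <- function() {
  c("homo", "lumo", "ionization_potential", "electron_affinity",
    "electronegativity", "hardness", "molecular_energy", "adsorption_energy")
}

#' Derive the eight-descriptor vector for a pure component
#'
#' From the two frontier orbital energies the remaining electronic descriptors
#' follow from the standard conceptual-DFT (Koopmans-theorem) identities:
#' ionization potential IP = -E_HOMO, electron affinity EA = -E_LUMO,
#' absolute electronegativity chi = (IP + EA)/2, and absolute hardness
#' eta = (IP - EA)/2. Molecular energy and adsorption energy are carried
#' through unchanged.
#'
#' @param name Component identifier (e.g. "CdCl2").
#' @param homo Highest occupied orbital energy, eV.
#' @param lumo Lowest unoccupied orbital energy, eV; must be >= `homo`.
#' @param molecular_energy Total molecular energy (input units).
#' @param adsorption_energy Adsorption energy on the nanomaterial surface
#'   (input units).
#' @return A one-row data frame with a `name` column followed by the eight
#'   descriptor columns in [descriptor_names()] order.
#' @examples
#' derive_electronic_descriptors("CdCl2", homo = -6, lumo = -2,
#'                               molecular_energy = -150,
#'                               adsorption_energy = -1.2)
#' @export
derive_electronic_descriptors <- function(name, homo, lumo,
                                          molecular_energy,
                                          adsorption_energy) {
  stopifnot(is.numeric(homo), is.numeric(lumo),
            is.numeric(molecular_energy), is.numeric(adsorption_energy))
  if (any(lumo < homo)) {
    stop("orbital ordering violated: lumo must be >= homo", call. = FALSE)
  }
  ip  <- -homo
  ea  <- -lumo
  out <- data.frame(
    name                 = as.character(name),
    homo                 = homo,
    lumo                 = lumo,
    ionization_potential = ip,
    electron_affinity    = ea,
    electronegativity    = (ip + ea) / 2,
    hardness             = (ip - ea) / 2,
    molecular_energy     = molecular_energy,
    adsorption_energy    = adsorption_energy,
    stringsAsFactors = FALSE
  )
  out
}

#' Cell viability from plate absorbances
#'
#' Survival rate relative to untreated controls from a colorimetric viability
#' assay read at a single wavelength:
#' S = (A_exp - A_blank) / (A_control - A_blank).
#' The statistic is invariant to a common positive scaling and a common shift
#' of all three absorbances.
#'
#' @param a_exp Absorbance of the exposed wells (vectorized).
#' @param a_control Absorbance of the untreated control wells.
#' @param a_blank Absorbance of the cell-free blank wells.
#' @return Numeric vector of survival rates (dimensionless; 1 means equal to
#'   control, values slightly above 1 can occur).
#' @export
compute_viability <- function(a_exp, a_control, a_blank) {
  if (any(a_control <= a_blank)) {
    stop("degenerate plate: a_control must exceed a_blank", call. = FALSE)
  }
  (a_exp - a_blank) / (a_control - a_blank)
}

#' Inverse of the viability formula: absorbance from survival rate
#'
#' @param s Survival rate(s).
#' @param a_control,a_blank Control and blank absorbances.
#' @return Experimental absorbance A_exp such that [compute_viability()]
#'   recovers `s` exactly.
#' @keywords internal
viability_to_absorbance <- function(s, a_control, a_blank) {
  if (any(a_control <= a_blank)) {
    stop("degenerate plate: a_control must exceed a_blank", call. = FALSE)
  }
  a_blank + s * (a_control - a_blank)
}

#' Concentration-addition mixing of component descriptors
#'
#' Combines the descriptor vectors of the components of a mixture into a
#' single mixture descriptor vector by concentration-addition weighting.
#' In `"fraction"` mode (the default) the weights are mole fractions
#' x_i = c_i / sum(c), making the result a convex combination that stays
#' componentwise inside the range spanned by the components. In
#' `"concentration"` mode the raw molar concentrations are used as weights,
#' so the result scales with total dose.
#'
#' @param components Data frame of component descriptor rows (as returned by
#'   [derive_electronic_descriptors()]); one row per component.
#' @param concentrations Numeric vector of molar concentrations (umol/L),
#'   one per row of `components`; all > 0.
#' @param weighting `"fraction"` (mole-fraction weights) or
#'   `"concentration"` (raw-concentration weights).
#' @return Named numeric vector of length 8 in [descriptor_names()] order.
#' @examples
#' a <- derive_electronic_descriptors("A", -6, -2, -100, -1)
#' b <- derive_electronic_descriptors("B", -8, -4, -200, -3)
#' mix_descriptors(rbind(a, b), c(50, 50))
#' @export
mix_descriptors <- function(components, concentrations,
                            weighting = c("fraction", "concentration")) {
  weighting <- match.arg(weighting)
  if (nrow(components) == 0L) {
    stop("empty composition: at least one component required", call. = FALSE)
  }
  if (length(concentrations) != nrow(components)) {
    stop("one concentration per component required", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("all concentrations must be > 0", call. = FALSE)
  }
  d <- as.matrix(components[, descriptor_names(), drop = FALSE])
  w <- if (weighting == "fraction") {
    concentrations / sum(concentrations)
  } else {
    concentrations
  }
  out <- drop(crossprod(d, w))
  names(out) <- descriptor_names()
  out
}

#' Mixture descriptors for a whole design table
#'
#' Applies [mix_descriptors()] to every sample of a binary-mixture design in
#' which a variable component (a heavy-metal compound) is combined with a
#' fixed co-component (the nanomaterial).
#'
#' @param panel Component descriptor panel: data frame with a `name` column
#'   and the eight descriptor columns, covering every component and
#'   co-component named in `design`.
#' @param design Design table with columns `sample_id`, `component`,
#'   `concentration_umol_L`, `co_component`, `co_concentration_umol_L`.
#' @param weighting Passed to [mix_descriptors()].
#' @return `design` with the eight mixture-descriptor columns appended and an
#'   attribute `weighting` recording the mode used.
#' @export
mix_design <- function(panel, design,
                       weighting = c("fraction", "concentration")) {
  weighting <- match.arg(weighting)
  need <- c("sample_id", "component", "concentration_umol_L",
            "co_component", "co_concentration_umol_L")
  if (!all(need %in% names(design))) {
    stop("design table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(c(design$component, design$co_component), panel$name)
  if (anyNA(idx)) {
    stop("component(s) missing from panel: ",
         paste(unique(c(design$component, design$co_component)[is.na(idx)]),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(design)
  dmix <- matrix(NA_real_, n, 8L, dimnames = list(NULL, descriptor_names()))
  for (i in seq_len(n)) {
    comps <- panel[match(c(design$component[i], design$co_component[i]),
                         panel$name), , drop = FALSE]
    dmix[i, ] <- mix_descriptors(
      comps, c(design$concentration_umol_L[i],
               design$co_concentration_umol_L[i]),
      weighting = weighting)
  }
  out <- cbind(design, as.data.frame(dmix))
  attr(out, "weighting") <- weighting
  out
}

#' Build a design matrix and response vector from mixed samples
#'
#' @param mixed Data frame of mixture samples carrying the eight mixture
#'   descriptor columns and a `viability` column (e.g. output of
#'   [mix_design()] joined with measured or simulated viabilities).
#' @param descriptors Character vector naming the descriptor columns to keep,
#'   in the returned column order; defaults to all eight.
#' @return List with `X` (numeric matrix, one row per sample, named columns),
#'   `y` (viability vector), `columns` (colnames of X) and `sample_id`.
#' @export
build_design_table <- function(mixed, descriptors = descriptor_names()) {
  if (length(descriptors) == 0L) {
    stop("descriptor subset must be non-empty", call. = FALSE)
  }
  if (!all(descriptors %in% names(mixed))) {
    stop("missing descriptor column(s): ",
         paste(setdiff(descriptors, names(mixed)), collapse = ", "),
         call. = FALSE)
  }
  if (!"viability" %in% names(mixed) || anyNA(mixed$viability)) {
    stop("incomplete samples: every row needs a viability", call. = FALSE)
  }
  X <- as.matrix(mixed[, descriptors, drop = FALSE])
  rownames(X) <- NULL
  list(X = X, y = mixed$viability, columns = descriptors,
       sample_id = if ("sample_id" %in% names(mixed)) mixed$sample_id
                   else seq_len(nrow(mixed)))
}
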