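#' Default physical constants for the PEG-peptide stiffening system
#'
#' Registry of the physical constants and default model parameters used
#' throughout the package: PEG backbone geometry, polymer and water densities,
#' tyrosinase transport parameters, and the reference simulation conditions
#' (1 mm slab, 3 uM enzyme bath, 10 mM immobilized tyrosine substrate).
#' Every value can be overridden by passing a replacement in `...` or through
#' a run configuration file.
#'
#' The in-gel diffusivities `D_gel_soft` (0.5 kPa gel) and `D_gel_stiff`
#' (5 kPa gel) are carried as direct inputs for transport simulations; see
#' the methods vignette for why they are not derived from the Lustig-Peppas
#' chain with the solution diffusivity listed here.
#'
#' @param ... named overrides for individual constants.
#'
#' @return A named list with elements:
#' \describe{
#'   \item{bond_length_A}{average backbone bond length of an ethylene glycol
#'     unit, Angstrom (1.47).}
#'   \item{flory_ratio}{Flory characteristic ratio C_n for PEG (4).}
#'   \item{repeat_unit_mw}{PEG repeat-unit molar mass, g/mol (44).}
#'   \item{rho_polymer}{PEG density at 37 C, g/cm^3 (1.087).}
#'   \item{rho_water}{water density at 37 C, g/cm^3 (0.994).}
#'   \item{D_sol}{tyrosinase diffusivity in solution, m^2/s (5.05e-10).}
#'   \item{R_E_nm}{tyrosinase hydrodynamic radius, nm (4.5).}
#'   \item{Y}{free-volume parameter of the Lustig-Peppas relation (1).}
#'   \item{D_gel_soft, D_gel_stiff}{in-gel diffusivities for ~0.5 and ~5 kPa
#'     gels, m^2/s (3.80e-11, 3.58e-11).}
#'   \item{macromer_mw, macromer_arms}{8-arm PEG-norbornene macromer:
#'     20000 g/mol, 8 arms.}
#'   \item{crosslinker_sequence}{default peptide crosslinker ("CYGGGYC").}
#'   \item{slab_thickness_m}{gel thickness, m (1e-3).}
#'   \item{enzyme_conc_uM}{bath enzyme concentration, uM (3).}
#'   \item{substrate_conc_mM}{initial immobilized substrate, mM (10).}
#' }
#' @examples
#' stiffsim_constants()$R_E_nm
#' stiffsim_constants(Y = 2)$Y
#' @export
stiffsim_constants <- function(...) {
  defaults <- list(
    bond_length_A     = 1.47,
    flory_ratio       = 4,
    repeat_unit_mw    = 44,
    rho_polymer       = 1.087,
    rho_water         = 0.994,
    D_sol             = 5.05e-10,
    R_E_nm            = 4.5,
    Y                 = 1,
    D_gel_soft        = 3.80e-11,
    D_gel_stiff       = 3.58e-11,
    macromer_mw       = 20000,
    macromer_arms     = 8,
    crosslinker_sequence = "CYGGGYC",
    slab_thickness_m  = 1e-3,
    enzyme_conc_uM    = 3,
    substrate_conc_mM = 10
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  defaults
}

#' Tyrosinase kinetic constants for the three assayed substrates
#'
#' Michaelis-Menten constants for tyrosinase acting on free l-tyrosine
#' (substrate-inhibited), l-DOPA, and the bis-tyrosine peptide crosslinker
#' CYGGGYC (both uninhibited), as determined from MBTH velocity assays.
#'
#' @param substrate one of `"l-tyr"`, `"l-dopa"`, `"cygggyc"`
#'   (case-insensitive).
#' @return A [kinetic_params()] object. Only l-tyrosine carries a substrate
#'   inhibition constant `K_i`.
#' @examples
#' tyrosinase_kinetics("cygggyc")
#' @export
tyrosinase_kinetics <- function(substrate = c("cygggyc", "l-tyr", "l-dopa")) {
  substrate <- match.arg(tolower(substrate[1]), c("cygggyc", "l-tyr", "l-dopa"))
  switch(substrate,
    "l-tyr"   = kinetic_params(k_cat = 0.93, K_M = 0.85, K_i = 19.85),
    "l-dopa"  = kinetic_params(k_cat = 8.63, K_M = 1.02),
    "cygggyc" = kinetic_params(k_cat = 0.60, K_M = 0.58)
  )
}

# run `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(name, " must be a single finite ",
         if (strict) "positive" else "non-negative", " number", call. = FALSE)
  invisible(x)
}
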