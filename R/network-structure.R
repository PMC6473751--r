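#' @title Hydrogel network structure
#' @description Structural descriptors of the swollen PEG-peptide network:
#'   mass and volumetric swelling ratios, molecular weight between
#'   crosslinks, mesh size, and the Lustig-Peppas in-gel diffusivity built
#'   from them.
#' @name network_structure
NULL

# average residue masses (g/mol), 20 standard amino acids; water 18.0153
.residue_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

#' Macromer specification
#'
#' @param number_average_mw number-average molecular weight, g/mol.
#' @param arm_functionality number of crosslinkable arms (>= 2).
#' @param repeat_unit_mw repeat-unit molar mass, g/mol (44 for PEG).
#' @param polymer_density dry polymer density, g/cm^3.
#' @return A `macromer_spec` object.
#' @examples
#' macromer_spec()  # defaults: 20 kDa 8-arm PEG-norbornene
#' @export
macromer_spec <- function(number_average_mw = stiffsim_constants()$macromer_mw,
                          arm_functionality = stiffsim_constants()$macromer_arms,
                          repeat_unit_mw = stiffsim_constants()$repeat_unit_mw,
                          polymer_density = stiffsim_constants()$rho_polymer) {
  stopifnot_scalar_pos(number_average_mw, "number_average_mw")
  stopifnot_scalar_pos(repeat_unit_mw, "repeat_unit_mw")
  stopifnot_scalar_pos(polymer_density, "polymer_density")
  if (arm_functionality < 2) stop("arm_functionality must be >= 2")
  structure(list(number_average_mw = number_average_mw,
                 arm_functionality = arm_functionality,
                 repeat_unit_mw = repeat_unit_mw,
                 polymer_density = polymer_density),
            class = "macromer_spec")
}

#' Peptide crosslinker specification
#'
#' If `sequence` is given and `molecular_weight` is not, the molecular
#' weight is computed from average residue masses. If both are given they
#' must agree within 0.1 g/mol.
#'
#' @param sequence one-letter amino-acid sequence (optional).
#' @param molecular_weight crosslinker molar mass, g/mol (optional if
#'   `sequence` is given).
#' @param functionality number of reactive termini (>= 2, default 2 for a
#'   bis-cysteine peptide).
#' @return A `crosslinker_spec` object.
#' @examples
#' crosslinker_spec("CYGGGYC")
#' @export
crosslinker_spec <- function(sequence = NULL, molecular_weight = NULL,
                             functionality = 2) {
  if (functionality < 2) stop("functionality must be >= 2")
  if (!is.null(sequence)) {
    seq_mw <- crosslinker_mw_from_sequence(sequence)
    if (is.null(molecular_weight)) molecular_weight <- seq_mw
    else if (abs(molecular_weight - seq_mw) > 0.1)
      stop(sprintf("molecular_weight (%.2f) disagrees with sequence mass (%.2f)",
                   molecular_weight, seq_mw))
  }
  if (is.null(molecular_weight))
    stop("either sequence or molecular_weight is required")
  stopifnot_scalar_pos(molecular_weight, "molecular_weight")
  structure(list(sequence = sequence, molecular_weight = molecular_weight,
                 functionality = functionality),
            class = "crosslinker_spec")
}

#' Molecular weight of a peptide from its one-letter sequence
#'
#' Sum of average residue masses plus one water (18.0153 g/mol).
#'
#' @param sequence one-letter amino-acid string (standard 20 codes).
#' @return Average molecular weight, g/mol.
#' @examples
#' crosslinker_mw_from_sequence("CYGGGYC")  # ~721.8
#' @export
crosslinker_mw_from_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty single string")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters1, names(.residue_masses))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  sum(.residue_masses[letters1]) + .water_mass
}

#' Mass swelling ratio from a swelling measurement
#'
#' @param swollen_mass mass of the equilibrium-swollen gel (any unit).
#' @param dry_mass mass of the dried gel (same unit).
#' @return q = swollen/dry, dimensionless, >= 1.
#' @examples
#' mass_swelling_ratio(27.5, 1)
#' @export
mass_swelling_ratio <- function(swollen_mass, dry_mass) {
  if (any(!is.finite(swollen_mass)) || any(!is.finite(dry_mass)) ||
      any(dry_mass <= 0))
    stop("invalid measurement: dry_mass must be positive and masses finite")
  if (any(swollen_mass < dry_mass))
    stop("invalid measurement: swollen_mass < dry_mass")
  swollen_mass / dry_mass
}

#' Volumetric swelling ratio from the mass swelling ratio
#'
#' Volume-additive conversion Q = 1 + (rho_polymer/rho_water) (q - 1).
#'
#' @param q mass swelling ratio (>= 1).
#' @param polymer_density polymer density, g/cm^3.
#' @param water_density water density, g/cm^3.
#' @return Q, dimensionless, >= 1. The polymer volume fraction is 1/Q.
#' @examples
#' volumetric_swelling_ratio(27.52)  # ~30
#' @export
volumetric_swelling_ratio <- function(q,
                                      polymer_density = stiffsim_constants()$rho_polymer,
                                      water_density = stiffsim_constants()$rho_water) {
  if (any(q < 1)) stop("invalid input: q must be >= 1")
  stopifnot_scalar_pos(polymer_density, "polymer_density")
  stopifnot_scalar_pos(water_density, "water_density")
  1 + (polymer_density / water_density) * (q - 1)
}

#' Mass swelling ratio implied by a volumetric swelling ratio
#'
#' Inverse of [volumetric_swelling_ratio()].
#'
#' @inheritParams volumetric_swelling_ratio
#' @param Q volumetric swelling ratio (>= 1).
#' @return q, dimensionless.
#' @export
mass_swelling_from_volumetric <- function(Q,
                                          polymer_density = stiffsim_constants()$rho_polymer,
                                          water_density = stiffsim_constants()$rho_water) {
  if (any(Q < 1)) stop("invalid input: Q must be >= 1")
  1 + (water_density / polymer_density) * (Q - 1)
}

#' Average molecular weight between crosslinks of a step-growth network
#'
#' For an A-B step-growth network, Mc = 2 (MW_A/f_A + MW_B/f_B).
#'
#' @param macromer a [macromer_spec()].
#' @param crosslinker a [crosslinker_spec()].
#' @return Mc, g/mol.
#' @examples
#' mw_between_crosslinks(macromer_spec(), crosslinker_spec("CYGGGYC"))
#' @export
mw_between_crosslinks <- function(macromer, crosslinker) {
  stopifnot(inherits(macromer, "macromer_spec"),
            inherits(crosslinker, "crosslinker_spec"))
  2 * (macromer$number_average_mw / macromer$arm_functionality +
       crosslinker$molecular_weight / crosslinker$functionality)
}

#' Mesh size of a swollen network
#'
#' Canal-Peppas form: xi = Q^(1/3) l sqrt(3 C_n Mc / M_r), with the bond
#' length l in Angstrom and the result in nm. Three backbone bonds per
#' repeat unit of mass `repeat_unit_mw`.
#'
#' @param Q volumetric swelling ratio.
#' @param Mc molecular weight between crosslinks, g/mol.
#' @param bond_length_A backbone bond length, Angstrom.
#' @param flory_ratio Flory characteristic ratio C_n.
#' @param repeat_unit_mw repeat-unit molar mass, g/mol.
#' @return Mesh size xi, nm.
#' @examples
#' mesh_size(18, 5721.8)  # ~15.2 nm
#' @export
mesh_size <- function(Q, Mc,
                      bond_length_A = stiffsim_constants()$bond_length_A,
                      flory_ratio = stiffsim_constants()$flory_ratio,
                      repeat_unit_mw = stiffsim_constants()$repeat_unit_mw) {
  if (any(Q <= 0) || any(Mc <= 0))
    stop("invalid input: Q and Mc must be positive")
  stopifnot_scalar_pos(bond_length_A, "bond_length_A")
  stopifnot_scalar_pos(flory_ratio, "flory_ratio")
  stopifnot_scalar_pos(repeat_unit_mw, "repeat_unit_mw")
  xi_A <- Q^(1 / 3) * bond_length_A * sqrt(3 * flory_ratio * Mc / repeat_unit_mw)
  xi_A / 10  # Angstrom -> nm
}

#' Solute transport specification
#'
#' @param D_sol solute diffusivity in solution, m^2/s.
#' @param R_E_nm solute hydrodynamic radius, nm.
#' @param Y free-volume parameter (default 1 for PEG gels).
#' @return A `transport_spec` object.
#' @export
transport_spec <- function(D_sol = stiffsim_constants()$D_sol,
                           R_E_nm = stiffsim_constants()$R_E_nm,
                           Y = stiffsim_constants()$Y) {
  stopifnot_scalar_pos(D_sol, "D_sol")
  stopifnot_scalar_pos(R_E_nm, "R_E_nm")
  stopifnot_scalar_pos(Y, "Y")
  structure(list(D_sol = D_sol, R_E_nm = R_E_nm, Y = Y),
            class = "transport_spec")
}

#' In-gel solute diffusivity by the Lustig-Peppas relation
#'
#' D_gel = D_sol (1 - R_E/xi) exp(-Y/(Q - 1)). When the solute radius
#' meets or exceeds the mesh size, transport is sterically excluded and
#' the function returns 0 with attribute `no_transport = TRUE`.
#'
#' @param transport a [transport_spec()].
#' @param xi_nm mesh size, nm.
#' @param Q volumetric swelling ratio (> 1).
#' @return D_gel, m^2/s, in [0, D_sol).
#' @examples
#' lustig_peppas_diffusivity(transport_spec(), xi_nm = 15.2, Q = 18)
#' @export
lustig_peppas_diffusivity <- function(transport, xi_nm, Q) {
  stopifnot(inherits(transport, "transport_spec"))
  if (any(xi_nm <= 0)) stop("invalid input: xi_nm must be positive")
  if (any(Q <= 1)) stop("invalid input: Q must be > 1")
  D <- transport$D_sol * (1 - transport$R_E_nm / xi_nm) * exp(-transport$Y / (Q - 1))
  excluded <- transport$R_E_nm >= xi_nm
  D[excluded] <- 0
  if (any(excluded)) attr(D, "no_transport") <- TRUE
  D
}

#' Gel structural state
#'
#' Bundles the structural descriptors of one gel formulation. Supply the
#' mass swelling ratio `q` (from which Q is derived) or `Q` directly.
#'
#' @param q mass swelling ratio (optional).
#' @param Q volumetric swelling ratio (optional; derived from `q` if absent).
#' @param Mc molecular weight between crosslinks, g/mol (optional).
#' @param xi_nm mesh size, nm (optional; derived from Q and Mc if absent).
#' @param G_prime_kPa shear modulus, kPa (optional).
#' @param constants a [stiffsim_constants()] list.
#' @return A `gel_state` with q, Q, polymer volume fraction nu = 1/Q,
#'   Mc, xi_nm, G_prime_kPa.
#' @examples
#' gel_state(Q = 18, Mc = 5721.8)
#' @export
gel_state <- function(q = NULL, Q = NULL, Mc = NULL, xi_nm = NULL,
                      G_prime_kPa = NULL, constants = stiffsim_constants()) {
  if (is.null(Q)) {
    if (is.null(q)) stop("one of q or Q is required")
    Q <- volumetric_swelling_ratio(q, constants$rho_polymer, constants$rho_water)
  } else if (is.null(q)) {
    q <- mass_swelling_from_volumetric(Q, constants$rho_polymer, constants$rho_water)
  }
  if (q < 1 || Q < 1) stop("swelling ratios must be >= 1")
  if (is.null(xi_nm) && !is.null(Mc))
    xi_nm <- mesh_size(Q, Mc, constants$bond_length_A, constants$flory_ratio,
                       constants$repeat_unit_mw)
  if (!is.null(xi_nm) && xi_nm <= 0) stop("xi_nm must be positive")
  structure(list(q = q, Q = Q, nu = 1 / Q, Mc = Mc, xi_nm = xi_nm,
                 G_prime_kPa = G_prime_kPa),
            class = "gel_state")
}

#' @export
print.gel_state <- function(x, ...) {
  cat("Gel structural state\n")
  cat(sprintf("  q = %.3g, Q = %.3g, nu_2s = %.4g\n", x$q, x$Q, x$nu))
  if (!is.null(x$Mc)) cat(sprintf("  Mc = %.4g g/mol\n", x$Mc))
  if (!is.null(x$xi_nm)) cat(sprintf("  mesh size = %.3g nm\n", x$xi_nm))
  if (!is.null(x$G_prime_kPa)) cat(sprintf("  G' = %.3g kPa\n", x$G_prime_kPa))
  invisible(x)
}

#' Interpolate gel structure from an empirical modulus calibration
#'
#' Linearly interpolates Q and mesh size at a given shear modulus from a
#' calibration table (columns `G_prime_kPa`, `Q`, `xi_nm`), as measured
#' for gels spanning the relevant stiffness range. Moduli outside the
#' table are clamped to the nearest row with a warning.
#'
#' @param G_prime_kPa shear modulus at which to evaluate, kPa.
#' @param calibration data.frame with columns `G_prime_kPa`, `Q`, `xi_nm`,
#'   monotone in `G_prime_kPa`, >= 2 rows.
#' @return A [gel_state()] carrying the interpolated Q and mesh size.
#' @export
gel_state_from_calibration <- function(G_prime_kPa, calibration) {
  if (is.null(calibration) || !is.data.frame(calibration) || nrow(calibration) < 2)
    stop("missing calibration: need a table with at least 2 rows")
  need <- c("G_prime_kPa", "Q", "xi_nm")
  if (!all(need %in% names(calibration)))
    stop("calibration must have columns ", paste(need, collapse = ", "))
  ord <- order(calibration$G_prime_kPa)
  calibration <- calibration[ord, ]
  g <- calibration$G_prime_kPa
  if (is.unsorted(g, strictly = TRUE))
    stop("calibration must be strictly monotone in G_prime_kPa")
  if (G_prime_kPa < min(g) || G_prime_kPa > max(g))
    warning("G' outside calibration range; clamping to nearest row")
  Q <- stats::approx(g, calibration$Q, xout = G_prime_kPa, rule = 2)$y
  xi <- stats::approx(g, calibration$xi_nm, xout = G_prime_kPa, rule = 2)$y
  gel_state(Q = Q, xi_nm = xi, G_prime_kPa = G_prime_kPa)
}
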