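#' Physical and analytical constants for seawater Cr work
#'
#' Returns the constant set used throughout the package: the quasi-conservative
#' background pool \eqn{[Cr(VI)+Cr(III)_{NR}]}, the O2:C stoichiometry used to
#' express net community production in carbon units, the bounding phytoplankton
#' and sinking-particle Cr:C ratios, molar masses, a fixed seawater density for
#' kg/m3 conversions, and the analytical precision of the concentration and
#' isotope measurements.
#'
#' @param ... named overrides for any constant (e.g. `density_sw = 1027`).
#' @param file optional path to a YAML file of overrides (requires the yaml
#'   package); values in `...` take precedence over the file.
#'
#' @return A named list of class `"cr_constants"` with elements:
#' \describe{
#'   \item{cr6nr_const}{background \eqn{[Cr(VI)+Cr(III)_{NR}]}, nmol/kg (2.9)}
#'   \item{o2c_ratio}{photosynthetic quotient, mol O2 per mol C (1.4)}
#'   \item{crc_low, crc_high}{Cr:C export ratios, umol Cr per mol C
#'     (0.555 from deep sediment traps; 2.7 from surface phytoplankton)}
#'   \item{molar_mass_c, molar_mass_cr}{g/mol}
#'   \item{density_sw}{seawater density for unit conversion, kg/m3 (1025)}
#'   \item{rsd_cr}{external reproducibility of [Cr], relative 1 SD (0.0082)}
#'   \item{cr3_default_unc}{relative 1 sigma applied to non-replicated
#'     [Cr(III)] (0.10)}
#'   \item{ext_2sd_d53cr}{external reproducibility of delta-53Cr, permil 2 SD
#'     (0.033)}
#' }
#' @export
#' @examples
#' cst <- cr_constants()
#' cst$cr6nr_const
cr_constants <- function(..., file = NULL) {
  cst <- list(
    cr6nr_const     = 2.9,
    o2c_ratio       = 1.4,
    crc_low         = 0.555,
    crc_high        = 2.7,
    molar_mass_c    = 12.011,
    molar_mass_cr   = 51.996,
    density_sw      = 1025,
    rsd_cr          = 0.0082,
    cr3_default_unc = 0.10,
    ext_2sd_d53cr   = 0.033
  )
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a constants file requires the 'yaml' package")
    ov <- yaml::read_yaml(file)
    cst[names(ov)] <- ov
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cst))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    cst[names(dots)] <- dots
  }
  bad <- vapply(cst, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                logical(1))
  if (any(bad))
    stop("constants must be positive scalars: ", paste(names(cst)[bad], collapse = ", "))
  if (cst$crc_low >= cst$crc_high)
    stop("crc_low must be < crc_high")
  structure(cst, class = "cr_constants")
}

#' Convert a concentration over a layer to an areal inventory
#'
#' nmol/kg over a layer of given thickness becomes umol/m2 using a fixed
#' seawater density: `conc * density * thickness * 1e-3`.
#'
#' @param conc concentration, nmol/kg. Vectorised.
#' @param thickness layer thickness, m (> 0).
#' @param density seawater density, kg/m3.
#' @return areal inventory, umol/m2.
#' @export
#' @examples
#' convert_conc_to_areal(0.27, 19.2)  # station-style mixed-layer deficit
convert_conc_to_areal <- function(conc, thickness, density = cr_constants()$density_sw) {
  stopifnot(is.numeric(conc), is.numeric(thickness), is.numeric(density))
  if (any(thickness <= 0)) stop("thickness must be positive")
  if (any(density <= 0)) stop("density must be positive")
  conc * density * thickness * 1e-3
}

#' Convert a carbon export flux to a chromium export flux
#'
#' Global carbon export in GT C/yr times a Cr:C ratio in umol Cr per mol C
#' gives mol Cr/yr: `c_export * 1e15 / molar_mass_c * crc * 1e-6`.
#'
#' @param c_export carbon export, GT C/yr (>= 0). Vectorised.
#' @param crc Cr:C ratio, umol Cr per mol C (>= 0).
#' @param molar_mass_c molar mass of carbon, g/mol.
#' @return chromium export, mol Cr/yr.
#' @export
#' @examples
#' gigatons_c_to_mol_cr(5, 0.555)   # ~2.3e8 mol Cr/yr
gigatons_c_to_mol_cr <- function(c_export, crc, molar_mass_c = cr_constants()$molar_mass_c) {
  stopifnot(is.numeric(c_export), is.numeric(crc))
  if (any(c_export < 0)) stop("c_export must be non-negative")
  if (any(crc < 0)) stop("crc must be non-negative")
  c_export * 1e15 / molar_mass_c * crc * 1e-6
}

#' Cr:C ratio from cellular dry-weight Cr content
#'
#' Converts a cellular Cr content in ug Cr per g dry weight and a carbon mass
#' fraction into a molar Cr:C ratio (umol Cr per mol C). The phytoplankton
#' endmember used in the export budgets (2.7 umol/mol) derives from 3.9 ug/g
#' dry weight at 33 wt% carbon.
#'
#' @param cr_ug_g Cr content, ug per g dry weight.
#' @param c_wtfrac carbon mass fraction of dry weight (0-1).
#' @param constants a [cr_constants()] list.
#' @return Cr:C, umol Cr per mol C.
#' @export
#' @examples
#' crc_from_dry_weight(3.9, 0.33)  # ~2.7
crc_from_dry_weight <- function(cr_ug_g, c_wtfrac, constants = cr_constants()) {
  stopifnot(cr_ug_g >= 0, c_wtfrac > 0, c_wtfrac <= 1)
  mol_cr_per_g <- cr_ug_g * 1e-6 / constants$molar_mass_cr
  mol_c_per_g <- c_wtfrac / constants$molar_mass_c
  mol_cr_per_g / mol_c_per_g * 1e6
}
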