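#' Energy parameters of the thermodynamic models
#'
#' Wild-type free energies and physical constants shared by both models.
#' Defaults are the study conditions: a moderately stable protein
#' (\eqn{\Delta G_{Folding,wt} = -2} kcal/mol; more and less stable variants
#' \eqn{-3.5} and \eqn{-0.5} are also examined), moderate binding affinity
#' (\eqn{\Delta G_{Binding,wt} = -5} kcal/mol), the gas constant in
#' kcal/(mol K) and 37 degrees C.
#'
#' @param dG_folding_wt wild-type folding free energy, kcal/mol (negative =
#'   stable).
#' @param dG_binding_wt wild-type binding free energy, kcal/mol (ignored by
#'   the folding-only model).
#' @param R gas constant, kcal/(mol K).
#' @param T absolute temperature, K.
#' @return an object of class `energy_params`.
#' @examples
#' p <- energy_params()
#' folded_fraction(-2, p)
#' @export
energy_params <- function(dG_folding_wt = -2, dG_binding_wt = -5,
                          R = 1.98e-3, T = 310.15) {
  .stop_if_not_number(dG_folding_wt, "dG_folding_wt")
  .stop_if_not_number(dG_binding_wt, "dG_binding_wt")
  .stop_if_not_number(R, "R")
  .stop_if_not_number(T, "T")
  if (R <= 0 || T <= 0) stop("R and T must be positive", call. = FALSE)
  structure(list(dG_folding_wt = dG_folding_wt,
                 dG_binding_wt = dG_binding_wt, R = R, T = T),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(
    "Energy parameters: dG_folding_wt = %g, dG_binding_wt = %g kcal/mol; RT = %.5g kcal/mol\n",
    x$dG_folding_wt, x$dG_binding_wt, .rt(x)))
  invisible(x)
}

#' One allele of a diploid gene
#'
#' An allele is a bundle of mutational free-energy changes relative to the
#' wild type plus an expression flag. A null allele (`expressed = FALSE`)
#' contributes nothing to any molecular species; it is deliberately not
#' represented as a large finite ddG, which would be both ambiguous and prone
#' to overflow.
#'
#' @param ddG_folding mutational change in folding free energy, kcal/mol.
#' @param ddG_binding mutational change in binding free energy, kcal/mol.
#' @param expressed logical; `FALSE` for a null (unexpressed) allele.
#' @return an object of class `allele`.
#' @export
allele <- function(ddG_folding = 0, ddG_binding = 0, expressed = TRUE) {
  .stop_if_not_number(ddG_folding, "ddG_folding")
  .stop_if_not_number(ddG_binding, "ddG_binding")
  stopifnot(is.logical(expressed), length(expressed) == 1L, !is.na(expressed))
  structure(list(ddG_folding = ddG_folding, ddG_binding = ddG_binding,
                 expressed = expressed), class = "allele")
}

#' @rdname allele
#' @export
null_allele <- function() allele(expressed = FALSE)

#' A diploid genotype: exactly two alleles
#'
#' Each expressed allele contributes half of the total protein concentration
#' (equal expression from the two gene copies).
#'
#' @param allele1,allele2 objects created by [allele()].
#' @return an object of class `genotype`.
#' @examples
#' wt <- genotype()                      # wild type / wild type
#' het <- genotype(allele(ddG_folding = 2), allele())
#' @export
genotype <- function(allele1 = allele(), allele2 = allele()) {
  stopifnot(inherits(allele1, "allele"), inherits(allele2, "allele"))
  structure(list(allele1 = allele1, allele2 = allele2), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  fmt <- function(a) {
    if (!a$expressed) return("null")
    if (a$ddG_folding == 0 && a$ddG_binding == 0) return("WT")
    sprintf("ddGf=%+g, ddGb=%+g", a$ddG_folding, a$ddG_binding)
  }
  cat(sprintf("Diploid genotype: [%s] / [%s]\n", fmt(x$allele1), fmt(x$allele2)))
  invisible(x)
}

#' Concentration scale of the binding model
#'
#' Total protein concentration and the ligand:protein ratio. Concentrations
#' are expressed in the Boltzmann-factor unit implied by the equilibrium
#' constants, so the default `X_T = 1` puts the system deep in the
#' tight-binding regime (K_D of the wild type is about 3e-4 of X_T), the
#' regime in which a 0.8 ligand ratio binds ~80% of the protein.
#'
#' @param X_T total protein concentration (> 0), concentration units.
#' @param ligand_ratio dimensionless ratio L_T / X_T (>= 0); the study
#'   examines 0.8, 1, 2 and 10.
#' @return an object of class `system_config` with fields `X_T`,
#'   `ligand_ratio` and the derived `L_T`.
#' @export
system_config <- function(X_T = 1, ligand_ratio = 1) {
  .stop_if_not_number(X_T, "X_T")
  .stop_if_not_number(ligand_ratio, "ligand_ratio")
  if (X_T <= 0) stop("X_T must be positive", call. = FALSE)
  if (ligand_ratio < 0) stop("ligand_ratio must be >= 0", call. = FALSE)
  structure(list(X_T = X_T, ligand_ratio = ligand_ratio,
                 L_T = ligand_ratio * X_T), class = "system_config")
}

#' Boltzmann folded fraction of a two-state protein
#'
#' \eqn{F = e^{-\Delta G/RT} / (1 + e^{-\Delta G/RT})}, the probability that a
#' protein with folding free energy `dG` is folded. Implemented with the
#' logistic function so it is numerically stable for |dG/RT| of several
#' hundred.
#'
#' @param dG folding free energy, kcal/mol (vectorized).
#' @param params [energy_params()].
#' @return folded fraction(s) in \[0, 1\]; strictly decreasing in `dG`.
#' @examples
#' folded_fraction(0)            # 0.5 by symmetry
#' folded_fraction(-2)           # ~0.963 at the defaults
#' @export
folded_fraction <- function(dG, params = energy_params()) {
  .stop_if_not_number(dG, "dG")
  stopifnot(inherits(params, "energy_params"))
  stats::plogis(-dG / .rt(params))
}

#' Dissociation constant from a binding free energy
#'
#' \eqn{K_D = e^{\Delta G/RT}} in the model's concentration unit. At the
#' defaults (\eqn{\Delta G = -5} kcal/mol, 310.15 K) the significand is 2.91,
#' matching a K_D of 291 nM when read on a nanomolar scale.
#'
#' @param dG binding free energy, kcal/mol (vectorized).
#' @param params [energy_params()].
#' @return dissociation constant(s), concentration units.
#' @export
kd_from_energy <- function(dG, params = energy_params()) {
  .stop_if_not_number(dG, "dG")
  stopifnot(inherits(params, "energy_params"))
  .eexp(dG / .rt(params))
}
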