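# Folding-only model, vectorized internal path.
# W = sum_i expressed_i * F(dG_wt + ddG_i) / (2 * F(dG_wt)).
.m1_w <- function(ddg1, ddg2, params, expr1 = TRUE, expr2 = TRUE) {
  rt <- .rt(params)
  Fwt <- stats::plogis(-params$dG_folding_wt / rt)
  F1 <- as.numeric(expr1) * stats::plogis(-(params$dG_folding_wt + ddg1) / rt)
  F2 <- as.numeric(expr2) * stats::plogis(-(params$dG_folding_wt + ddg2) / rt)
  (F1 + F2) / (2 * Fwt)
}

#' Phenotype under the two-state folding model
#'
#' The phenotype is the total folded-protein concentration of the genotype
#' normalized to the wild-type homozygote, so WT/WT is exactly 1 AU. Each
#' expressed allele contributes `0.5 * X_T` of protein whose folded fraction
#' follows the Boltzmann distribution; a null allele contributes nothing, so
#' a null/WT heterozygote scores exactly 0.5.
#'
#' @param genotype a [genotype()].
#' @param params [energy_params()]; only the folding energy is used.
#' @return phenotype W in arbitrary units (AU), non-increasing in each
#'   allele's `ddG_folding`.
#' @examples
#' model1_phenotype(genotype())                                  # 1
#' model1_phenotype(genotype(allele(ddG_folding = 2), allele())) # Eq.-level single het
#' model1_phenotype(genotype(null_allele(), allele()))           # 0.5
#' @export
model1_phenotype <- function(genotype, params = energy_params()) {
  stopifnot(inherits(genotype, "genotype"), inherits(params, "energy_params"))
  .m1_w(genotype$allele1$ddG_folding, genotype$allele2$ddG_folding, params,
        genotype$allele1$expressed, genotype$allele2$expressed)
}
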