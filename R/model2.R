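# Folding + one-to-one ligand binding under mass conservation.
#
# For allele i the lumped constant
#   K_i = exp((dGb_wt + ddGb_i)/RT) * (1 + exp((dGf_wt + ddGf_i)/RT))
# collects both equilibria: the bound concentration of an expressed allele at
# free ligand L is 0.5 * X_T * L / (L + K_i). The free ligand is the unique
# root of the increasing conservation function
#   g(L) = L + sum_i bound_i(L) - L_T   on [0, L_T].

.m2_K <- function(ddg_f, ddg_b, params) {
  rt <- .rt(params)
  .eexp((params$dG_binding_wt + ddg_b) / rt) *
    (1 + .eexp((params$dG_folding_wt + ddg_f) / rt))
}

# Vectorized bracketed bisection for the free ligand. w1/w2 are the protein
# amounts per allele (0 for a null allele). 200 iterations drive the bracket
# to adjacent doubles, far below the 1e-12 relative target.
.m2_free_ligand <- function(K1, K2, w1, w2, L_T) {
  n <- max(length(K1), length(K2), length(w1), length(w2))
  K1 <- rep_len(K1, n); K2 <- rep_len(K2, n)
  w1 <- rep_len(w1, n); w2 <- rep_len(w2, n)
  if (L_T == 0) return(numeric(n))
  lo <- numeric(n)
  hi <- rep(L_T, n)
  for (it in seq_len(200L)) {
    mid <- 0.5 * (lo + hi)
    g <- mid + mid * (w1 / (mid + K1) + w2 / (mid + K2)) - L_T
    up <- g > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (all(hi - lo <= 2 * .Machine$double.eps * hi)) break
  }
  L <- 0.5 * (lo + hi)
  resid <- abs(L + L * (w1 / (L + K1) + w2 / (L + K2)) - L_T) / L_T
  if (any(resid > 1e-10)) {
    i <- which.max(resid)
    stop(sprintf(
      "ligand conservation root did not converge: bracket [%.17g, %.17g], relative residual %.3g",
      lo[i], hi[i], resid[i]), call. = FALSE)
  }
  L
}

# Total bound concentration for one genotype-vector at its own equilibrium.
.m2_bound_total <- function(ddg_f1, ddg_b1, ddg_f2, ddg_b2,
                            params, config, expr1 = TRUE, expr2 = TRUE) {
  K1 <- .m2_K(ddg_f1, ddg_b1, params)
  K2 <- .m2_K(ddg_f2, ddg_b2, params)
  n <- max(length(K1), length(K2), length(expr1), length(expr2))
  w1 <- ifelse(rep_len(expr1, n), 0.5 * config$X_T, 0)
  w2 <- ifelse(rep_len(expr2, n), 0.5 * config$X_T, 0)
  L <- .m2_free_ligand(K1, K2, w1, w2, config$L_T)
  L * (w1 / (L + rep_len(K1, n)) + w2 / (L + rep_len(K2, n)))
}

# WT/WT reference bound concentration, cached per (params, config).
.ref_cache <- new.env(parent = emptyenv())

.m2_wt_bound <- function(params, config) {
  key <- paste(params$dG_folding_wt, params$dG_binding_wt, params$R, params$T,
               config$X_T, config$ligand_ratio, sep = "|")
  if (is.null(.ref_cache[[key]])) {
    .ref_cache[[key]] <- .m2_bound_total(0, 0, 0, 0, params, config)
  }
  .ref_cache[[key]]
}

# Vectorized phenotype (bound complex normalized to the WT/WT reference).
.m2_w <- function(ddg_f1, ddg_b1, ddg_f2, ddg_b2, params, config,
                  expr1 = TRUE, expr2 = TRUE) {
  .m2_bound_total(ddg_f1, ddg_b1, ddg_f2, ddg_b2, params, config,
                  expr1, expr2) / .m2_wt_bound(params, config)
}

#' Equilibrium species concentrations under the folding + binding model
#'
#' Solves the ligand mass-conservation equation for the free ligand and
#' returns all species concentrations. Per expressed allele the unfolded,
#' folded and ligand-bound concentrations sum to `0.5 * X_T`; free ligand
#' plus total bound ligand equals `L_T`. Both conservation identities are
#' verified to a relative 1e-10 before returning.
#'
#' @param genotype a [genotype()].
#' @param params [energy_params()].
#' @param config [system_config()].
#' @return an object of class `equilibrium_state`: a list with a 2 x 3
#'   `species` matrix (rows `allele1`, `allele2`; columns `unfolded`,
#'   `folded`, `bound`), `free_ligand`, `X_T` and `L_T`.
#' @examples
#' eq <- model2_equilibrium(genotype(), config = system_config(ligand_ratio = 0.8))
#' sum(eq$species[, "bound"])   # ~0.80: nearly all ligand is bound
#' @export
model2_equilibrium <- function(genotype, params = energy_params(),
                               config = system_config()) {
  stopifnot(inherits(genotype, "genotype"), inherits(params, "energy_params"),
            inherits(config, "system_config"))
  rt <- .rt(params)
  a <- list(genotype$allele1, genotype$allele2)
  K <- vapply(a, function(x) .m2_K(x$ddG_folding, x$ddG_binding, params), 0)
  w <- vapply(a, function(x) if (x$expressed) 0.5 * config$X_T else 0, 0)
  L <- .m2_free_ligand(K[1], K[2], w[1], w[2], config$L_T)
  species <- matrix(0, 2, 3,
                    dimnames = list(c("allele1", "allele2"),
                                    c("unfolded", "folded", "bound")))
  for (i in 1:2) {
    if (w[i] == 0) next
    bound <- w[i] * L / (L + K[i])
    Ffrac <- stats::plogis(-(params$dG_folding_wt + a[[i]]$ddG_folding) / rt)
    rest <- w[i] - bound
    species[i, ] <- c(rest * (1 - Ffrac), rest * Ffrac, bound)
  }
  # conservation checks (relative to the natural scale of each balance)
  for (i in 1:2) {
    if (w[i] > 0 &&
        abs(sum(species[i, ]) - w[i]) / w[i] > 1e-10)
      stop("per-allele protein conservation violated", call. = FALSE)
  }
  if (config$L_T > 0 &&
      abs(L + sum(species[, "bound"]) - config$L_T) / config$L_T > 1e-10)
    stop("ligand conservation violated", call. = FALSE)
  structure(list(species = species, free_ligand = L,
                 X_T = config$X_T, L_T = config$L_T),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("Equilibrium state (X_T = %g, L_T = %g):\n", x$X_T, x$L_T))
  print(signif(x$species, 6))
  cat(sprintf("free ligand: %.6g\n", x$free_ligand))
  invisible(x)
}

#' Phenotype under the folding + ligand-binding model
#'
#' The phenotype is the total protein-ligand complex concentration of the
#' genotype at its own equilibrium, normalized to twice the bound
#' concentration of one wild-type allele at the wild-type equilibrium
#' (computed with the same parameters and configuration, and cached).
#' WT/WT is exactly 1 AU.
#'
#' @inheritParams model2_equilibrium
#' @return phenotype W in AU.
#' @examples
#' cfg <- system_config(ligand_ratio = 0.8)
#' model2_phenotype(genotype(null_allele(), allele()), config = cfg)  # ~0.625
#' @export
model2_phenotype <- function(genotype, params = energy_params(),
                             config = system_config()) {
  stopifnot(inherits(genotype, "genotype"), inherits(params, "energy_params"),
            inherits(config, "system_config"))
  .m2_w(genotype$allele1$ddG_folding, genotype$allele1$ddG_binding,
        genotype$allele2$ddG_folding, genotype$allele2$ddG_binding,
        params, config,
        genotype$allele1$expressed, genotype$allele2$expressed)
}
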