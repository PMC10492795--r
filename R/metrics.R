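#' Expected double-mutant phenotype under additive and log-additive null models
#'
#' Given the single-mutant phenotypes `W_A`, `W_B` and the wild-type phenotype
#' `W_wt`, the additive expectation is `max(C, W_A + W_B - W_wt)` and the
#' log-additive expectation is `max(C, W_A * W_B / W_wt)`. The lower bound C
#' is 0.5 for within-allele combinations (the second allele is always
#' functional) and 0 for between-allele combinations.
#'
#' @param W_A,W_B single-mutant phenotypes, AU (vectorized).
#' @param W_wt wild-type phenotype, AU (> 0; 1 by construction of the models).
#' @param combination `"within"` or `"between"`.
#' @return a data.frame with columns `W_exp_add`, `W_exp_log`, `C`,
#'   `clamp_add`, `clamp_log` (the clamp flags record whether the Max bound).
#' @examples
#' expected_double(0.9, 0.8, combination = "within")   # 0.7 / 0.72
#' expected_double(0.6, 0.6, combination = "within")   # additive floored at 0.5
#' @export
expected_double <- function(W_A, W_B, W_wt = 1,
                            combination = c("within", "between")) {
  combination <- match.arg(combination)
  .stop_if_not_number(W_A, "W_A"); .stop_if_not_number(W_B, "W_B")
  .stop_if_not_number(W_wt, "W_wt")
  if (any(W_wt <= 0)) stop("invalid reference: W_wt must be > 0", call. = FALSE)
  if (any(W_A < 0) || any(W_B < 0))
    stop("phenotypes must be >= 0", call. = FALSE)
  C <- if (combination == "within") 0.5 else 0
  raw_add <- W_A + W_B - W_wt
  raw_log <- W_A * W_B / W_wt
  data.frame(W_exp_add = pmax(C, raw_add),
             W_exp_log = pmax(C, raw_log),
             C = C,
             clamp_add = raw_add < C,
             clamp_log = raw_log < C)
}

#' Interaction scores of an observed double mutant
#'
#' `e_add = W_obs - W_exp_add` on the phenotype scale and
#' `E_log = log(W_obs) - log(W_exp_log)` on the log scale. A negative score
#' means the double mutant is worse than expected. The log score is flagged
#' undefined (NA, `E_log_defined = FALSE`) whenever observed or expected
#' phenotype is not positive; nothing is raised.
#'
#' @param W_obs observed double-mutant phenotype, AU (>= 0, vectorized).
#' @param W_exp_add,W_exp_log expectations from [expected_double()].
#' @return a data.frame with columns `e_add`, `E_log`, `E_log_defined`.
#' @export
interaction_scores <- function(W_obs, W_exp_add, W_exp_log) {
  .stop_if_not_number(W_obs, "W_obs")
  if (any(W_obs < 0)) stop("W_obs must be >= 0", call. = FALSE)
  ok <- W_obs > 0 & W_exp_log > 0
  E_log <- ifelse(ok, log(W_obs) - log(W_exp_log), NA_real_)
  data.frame(e_add = W_obs - W_exp_add, E_log = E_log, E_log_defined = ok)
}

#' Degree of dominance of a compound heterozygote
#'
#' The heterozygote expectation is the midpoint of the homozygote phenotypes,
#' `W_exp_het = (W_AA + W_BB) / 2`; the degree of dominance is
#' `(W_het - W_exp_het) / |W_BB - W_exp_het|` with B the less-fit homozygote,
#' so that a positive value means the allele with better function is
#' dominant and |degree| = 1 means complete dominance/recessivity (the
#' heterozygote equals one of the parents). Because the denominator is the
#' absolute distance from the midpoint, the magnitude is invariant under
#' swapping the homozygote labels. When the homozygotes are equal within
#' `tol` the score is undefined and flagged, never dropped silently.
#'
#' @param W_AA,W_BB homozygote phenotypes, AU (vectorized).
#' @param W_het compound-heterozygote phenotype, AU.
#' @param tol absolute tolerance on the AU scale for calling the homozygotes
#'   equal (degree undefined).
#' @return a data.frame with columns `W_exp_het`, `degree`, `defined`.
#' @examples
#' degree_of_dominance(1, 0.4, 0.4)   # -1: the less-fit allele is dominant
#' degree_of_dominance(1, 0.4, 1)     # +1: the fitter allele is dominant
#' degree_of_dominance(1, 0.4, 0.7)   #  0: additivity
#' @export
degree_of_dominance <- function(W_AA, W_BB, W_het, tol = 1e-9) {
  .stop_if_not_number(W_AA, "W_AA"); .stop_if_not_number(W_BB, "W_BB")
  .stop_if_not_number(W_het, "W_het")
  if (any(W_AA < 0) || any(W_BB < 0) || any(W_het < 0))
    stop("phenotypes must be >= 0", call. = FALSE)
  mid <- (W_AA + W_BB) / 2
  less_fit <- pmin(W_AA, W_BB)     # explicit ordering: B = less-fit homozygote
  den <- abs(less_fit - mid)
  defined <- den > tol
  degree <- ifelse(defined, (W_het - mid) / den, NA_real_)
  data.frame(W_exp_het = mid, degree = degree, defined = defined)
}
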