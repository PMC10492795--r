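#' Scatter gate specification
#'
#' Rectangular FSC-A bounds plus an SSC-A band whose upper boundary is a
#' linear function of FSC-A. Defaults reproduce the analysis gate: FSC-A in
#' \[900, 9800\], SSC-A between 110 and `log10(0.93) * FSC-A + 530`. The
#' slope is read as log base 10 of 0.93 (a small negative slope selecting
#' the low-SSC sub-population); slope and intercept are explicit fields
#' because the boundary expression admits other readings.
#'
#' @param fsc_min,fsc_max FSC-A bounds, scatter units.
#' @param ssc_min lower SSC-A bound, scatter units.
#' @param ssc_slope_coeff,ssc_intercept upper SSC-A boundary
#'   `ssc_slope_coeff * FSC-A + ssc_intercept`.
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(fsc_min = 900, fsc_max = 9800, ssc_min = 110,
                      ssc_slope_coeff = log10(0.93), ssc_intercept = 530) {
  for (nm in c("fsc_min", "fsc_max", "ssc_min", "ssc_slope_coeff",
               "ssc_intercept"))
    .stop_if_not_number(get(nm), nm)
  if (fsc_min >= fsc_max) stop("need fsc_min < fsc_max", call. = FALSE)
  structure(list(fsc_min = fsc_min, fsc_max = fsc_max, ssc_min = ssc_min,
                 ssc_slope_coeff = ssc_slope_coeff,
                 ssc_intercept = ssc_intercept), class = "gate_spec")
}

.check_event_table <- function(events) {
  need <- c("FSC_A", "SSC_A", "GFP", "genotype", "replicate", "batch")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(events) == 0) stop("event table is empty", call. = FALSE)
  invisible(events)
}

#' Gate flow-cytometry events
#'
#' Keeps events inside the FSC-A window and the SSC-A band of a
#' [gate_spec()]. Gating is idempotent. If any genotype/replicate/batch
#' population present before gating is left empty, an error names it.
#'
#' @param events a data.frame with columns `FSC_A`, `SSC_A`, `GFP`,
#'   `genotype`, `replicate`, `batch`.
#' @param gate a [gate_spec()].
#' @return the retained events, with a per-population retention table in
#'   `attr(, "retention")` (columns `batch`, `genotype`, `replicate`,
#'   `n_before`, `n_after`).
#' @export
gate_events <- function(events, gate = gate_spec()) {
  stopifnot(inherits(gate, "gate_spec"))
  .check_event_table(events)
  keep <- events$FSC_A >= gate$fsc_min & events$FSC_A <= gate$fsc_max &
    events$SSC_A >= gate$ssc_min &
    events$SSC_A <= gate$ssc_slope_coeff * events$FSC_A + gate$ssc_intercept
  key <- interaction(events$batch, events$genotype, events$replicate,
                     drop = TRUE)
  n_before <- table(key)
  n_after <- table(key[keep])
  retention <- data.frame(
    population = names(n_before),
    n_before = as.integer(n_before),
    n_after = as.integer(n_after[names(n_before)]))
  retention$n_after[is.na(retention$n_after)] <- 0L
  empty <- retention$population[retention$n_after == 0L]
  if (length(empty))
    stop("gate left no events for population(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- retention
  out
}

#' Normalized GFP phenotype with its standard error
#'
#' From per-replicate mean GFP signals of a mutant, the wild type and the
#' autofluorescence-only control, all from the same batch:
#' \deqn{GFP_{obs} = (\mu_{mut} - \mu_{ctrl}) / (\mu_{wt} - \mu_{ctrl})}
#' with the standard error combining the replicate-level standard errors via
#' the nested-radical propagation formula
#' \deqn{SE_{obs} = \sqrt{\Big(\tfrac{\sqrt{SE_{mut}^2 + SE_{ctrl}^2}}{\mu_{mut}-\mu_{ctrl}}\Big)^2 + \Big(\tfrac{\sqrt{SE_{wt}^2 + SE_{ctrl}^2}}{\mu_{wt}-\mu_{ctrl}}\Big)^2}}
#' implemented exactly as printed, with no algebraic simplification. Each
#' population mean is the mean of its replicate means and each SE is the
#' standard error across replicate means.
#'
#' @param mut_means,wt_means,control_means numeric vectors of per-replicate
#'   mean GFP for the mutant, the wild type and the autofluorescence control
#'   (>= 2 replicates each for a finite SE).
#' @param batch optional batch label carried through.
#' @return an object of class `mutant_summary`: list with `gfp_obs`,
#'   `se_obs`, `n_replicates`, `batch`.
#' @examples
#' normalize_with_se(c(59, 60, 61), c(108, 110, 112), c(9, 10, 11))
#' @export
normalize_with_se <- function(mut_means, wt_means, control_means,
                              batch = NA) {
  .stop_if_not_number(mut_means, "mut_means")
  .stop_if_not_number(wt_means, "wt_means")
  .stop_if_not_number(control_means, "control_means")
  se <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  mu_m <- mean(mut_means); mu_w <- mean(wt_means); mu_c <- mean(control_means)
  if (mu_w <= mu_c)
    stop("degenerate reference: wild-type mean does not exceed the autofluorescence control",
         call. = FALSE)
  se_m <- se(mut_means); se_w <- se(wt_means); se_c <- se(control_means)
  gfp <- (mu_m - mu_c) / (mu_w - mu_c)
  se_obs <- sqrt((sqrt(se_m^2 + se_c^2) / (mu_m - mu_c))^2 +
                 (sqrt(se_w^2 + se_c^2) / (mu_w - mu_c))^2)
  structure(list(gfp_obs = gfp, se_obs = se_obs,
                 n_replicates = length(mut_means), batch = batch),
            class = "mutant_summary")
}

#' @export
print.mutant_summary <- function(x, ...) {
  cat(sprintf("GFP_obs = %.4f +/- %.4f (SE; %d replicates%s)\n",
              x$gfp_obs, x$se_obs, x$n_replicates,
              if (is.na(x$batch)) "" else paste0(", batch ", x$batch)))
  invisible(x)
}

#' Scored double-mutant record with propagated standard errors
#'
#' Combines two single-mutant summaries, the wild-type summary and the
#' observed double-mutant summary into additive and log-additive expectations
#' (with the C = 0.5 within-allele / 0 between-allele lower bound), the
#' interaction scores, and their standard errors:
#' `SE_exp_add = sqrt(SE_A^2 + SE_B^2 + SE_wt^2)`,
#' `SE_exp_log = sqrt((SE_A/W_A)^2 + (SE_B/W_B)^2)` (as printed), and
#' `SE_interaction = sqrt(SE_obs_AB^2 + SE_exp^2)` for each null model.
#' An undefined log score is flagged NA, never raised.
#'
#' @param A,B,WT,AB_obs [normalize_with_se()] summaries from the same batch
#'   normalization (singles A and B, wild type, observed double).
#' @param combination `"within"` or `"between"`.
#' @return one-row data.frame: phenotypes, expectations, scores and all
#'   propagated SEs.
#' @export
interaction_with_se <- function(A, B, WT, AB_obs,
                                combination = c("within", "between")) {
  combination <- match.arg(combination)
  for (s in list(A, B, WT, AB_obs))
    stopifnot(inherits(s, "mutant_summary"))
  ex <- expected_double(A$gfp_obs, B$gfp_obs, WT$gfp_obs, combination)
  sc <- interaction_scores(AB_obs$gfp_obs, ex$W_exp_add, ex$W_exp_log)
  se_exp_add <- sqrt(A$se_obs^2 + B$se_obs^2 + WT$se_obs^2)
  se_exp_log <- sqrt((A$se_obs / A$gfp_obs)^2 + (B$se_obs / B$gfp_obs)^2)
  data.frame(
    combination = combination,
    W_A = A$gfp_obs, W_B = B$gfp_obs, W_wt = WT$gfp_obs,
    W_obs = AB_obs$gfp_obs, SE_obs = AB_obs$se_obs,
    ex, sc,
    SE_exp_add = se_exp_add, SE_exp_log = se_exp_log,
    SE_interaction_add = sqrt(AB_obs$se_obs^2 + se_exp_add^2),
    SE_interaction_log = sqrt(AB_obs$se_obs^2 + se_exp_log^2))
}

#' Score a gated event table end to end
#'
#' Convenience wrapper for the full flow stage: computes per-replicate mean
#' GFP per genotype within each batch, normalizes every genotype against the
#' batch's wild type and autofluorescence control, and returns per-genotype
#' summaries.
#'
#' @param events a (typically gated) event table, see [gate_events()].
#' @param wt_genotype,control_genotype labels of the wild-type and
#'   autofluorescence-control populations (must exist in every batch).
#' @return a data.frame with one row per batch x genotype: `gfp_obs`,
#'   `se_obs`, `n_replicates`.
#' @export
summarize_genotypes <- function(events, wt_genotype = "WT",
                                control_genotype = "backbone") {
  .check_event_table(events)
  out <- list()
  for (b in unique(events$batch)) {
    eb <- events[events$batch == b, ]
    rep_means <- function(g) {
      d <- eb[eb$genotype == g, ]
      if (nrow(d) == 0)
        stop(sprintf("batch %s lacks genotype '%s'", b, g), call. = FALSE)
      vapply(split(d$GFP, d$replicate), mean, 0)
    }
    wt <- rep_means(wt_genotype)
    ctrl <- rep_means(control_genotype)
    for (g in setdiff(unique(eb$genotype), control_genotype)) {
      s <- normalize_with_se(rep_means(g), wt, ctrl, batch = b)
      out[[length(out) + 1L]] <- data.frame(
        batch = b, genotype = g, gfp_obs = s$gfp_obs, se_obs = s$se_obs,
        n_replicates = s$n_replicates)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
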