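#' Specification of a synthetic flow-cytometry experiment
#'
#' Describes the event generator used to exercise the scoring pipeline
#' without any external data: a panel of genotypes with known true
#' phenotypes, the replicate/batch structure of the emulated experiment
#' (5000 events per replicate, three biological replicates), two scatter
#' sub-populations (low and high SSC, the latter brighter in GFP so gating
#' matters) and multiplicative log-normal noise (additive Gaussian on the
#' log signal) with per-replicate colony effects and per-batch gain effects.
#'
#' @param genotypes named numeric vector of true phenotypes (AU, >= 0). A
#'   wild type (`"WT"`, truth 1) and an autofluorescence-only control
#'   (`"backbone"`) are added when absent.
#' @param events_per_replicate events recorded per replicate.
#' @param replicates biological replicates per genotype.
#' @param batches number of batches; every batch carries the full panel.
#' @param wt_signal mean GFP signal of the wild type above autofluorescence.
#' @param autofluorescence mean autofluorescence signal.
#' @param log_noise_sd per-event Gaussian noise sd on the log signal.
#' @param replicate_effect_sd per-replicate (colony) log-normal effect sd.
#' @param batch_effect_sd per-batch gain log-normal effect sd (cancelled by
#'   within-batch normalization).
#' @param fsc_meanlog,fsc_sdlog log-normal FSC-A parameters.
#' @param ssc_low_meanlog,ssc_high_meanlog,ssc_sdlog log-normal SSC-A
#'   parameters of the two scatter sub-populations.
#' @param high_ssc_fraction fraction of events in the high-SSC population.
#' @param high_ssc_gfp_factor GFP multiplier of the high-SSC population.
#' @param seed mandatory integer seed; generation is fully reproducible.
#' @return an object of class `flow_sim_spec`.
#' @export
flow_sim_spec <- function(genotypes = c(mutA = 0.9, mutB = 0.75,
                                        mutAB = 0.6),
                          events_per_replicate = 5000, replicates = 3,
                          batches = 1, wt_signal = 1000,
                          autofluorescence = 50, log_noise_sd = 0.25,
                          replicate_effect_sd = 0.02, batch_effect_sd = 0.05,
                          fsc_meanlog = log(3000), fsc_sdlog = 0.3,
                          ssc_low_meanlog = log(170),
                          ssc_high_meanlog = log(650), ssc_sdlog = 0.15,
                          high_ssc_fraction = 0.25,
                          high_ssc_gfp_factor = 1.3, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  .stop_if_not_number(genotypes, "genotypes")
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop("genotypes must be a named vector", call. = FALSE)
  if (any(genotypes < 0)) stop("true phenotypes must be >= 0", call. = FALSE)
  if (!("WT" %in% names(genotypes))) genotypes <- c(genotypes, WT = 1)
  truth <- genotypes
  spec <- list(genotypes = truth,
               events_per_replicate = as.integer(events_per_replicate),
               replicates = as.integer(replicates),
               batches = as.integer(batches), wt_signal = wt_signal,
               autofluorescence = autofluorescence,
               log_noise_sd = log_noise_sd,
               replicate_effect_sd = replicate_effect_sd,
               batch_effect_sd = batch_effect_sd,
               fsc_meanlog = fsc_meanlog, fsc_sdlog = fsc_sdlog,
               ssc_low_meanlog = ssc_low_meanlog,
               ssc_high_meanlog = ssc_high_meanlog, ssc_sdlog = ssc_sdlog,
               high_ssc_fraction = high_ssc_fraction,
               high_ssc_gfp_factor = high_ssc_gfp_factor,
               seed = as.integer(seed))
  stopifnot(spec$events_per_replicate >= 1, spec$replicates >= 1,
            spec$batches >= 1)
  structure(spec, class = "flow_sim_spec")
}

#' Generate a synthetic flow-cytometry event table
#'
#' Per event, the GFP signal is
#' `(autofluorescence + truth * wt_signal) * batch_gain * colony_effect *
#' exp(N(0, log_noise_sd))`; the autofluorescence-only `"backbone"` control
#' carries no construct signal. Scatter channels are drawn from a two-mode
#' SSC mixture over a common log-normal FSC so that the default
#' [gate_spec()] retains essentially only the low-SSC sub-population.
#'
#' @param spec a [flow_sim_spec()].
#' @return a data.frame with columns `FSC_A`, `SSC_A`, `GFP`, `genotype`,
#'   `replicate`, `batch`; the ground truth is attached as
#'   `attr(, "truth")` (columns `genotype`, `true_phenotype`).
#' @examples
#' ev <- gen_flow_events(flow_sim_spec(seed = 1))
#' head(attr(ev, "truth"))
#' @export
gen_flow_events <- function(spec) {
  stopifnot(inherits(spec, "flow_sim_spec"))
  set.seed(spec$seed)
  panel <- c(spec$genotypes, backbone = NA_real_)  # NA = no construct signal
  n <- spec$events_per_replicate
  rows <- vector("list", spec$batches * length(panel) * spec$replicates)
  k <- 0L
  for (b in seq_len(spec$batches)) {
    gain <- exp(stats::rnorm(1, 0, spec$batch_effect_sd))
    for (g in seq_along(panel)) {
      truth <- panel[g]
      base <- if (is.na(truth)) spec$autofluorescence
              else spec$autofluorescence + truth * spec$wt_signal
      for (r in seq_len(spec$replicates)) {
        colony <- exp(stats::rnorm(1, 0, spec$replicate_effect_sd))
        high <- stats::runif(n) < spec$high_ssc_fraction
        fsc <- stats::rlnorm(n, spec$fsc_meanlog, spec$fsc_sdlog)
        ssc <- stats::rlnorm(n, ifelse(high, spec$ssc_high_meanlog,
                                       spec$ssc_low_meanlog), spec$ssc_sdlog)
        gfp <- base * gain * colony *
          ifelse(high, spec$high_ssc_gfp_factor, 1) *
          exp(stats::rnorm(n, 0, spec$log_noise_sd))
        k <- k + 1L
        rows[[k]] <- data.frame(
          FSC_A = fsc, SSC_A = ssc, GFP = gfp,
          genotype = names(panel)[g], replicate = r, batch = b)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(
    genotype = names(spec$genotypes),
    true_phenotype = unname(spec$genotypes))
  out
}

#' Draw a random panel of mutant alleles
#'
#' Reproducible Gaussian draws of folding and binding free-energy changes for
#' stress-testing the scoring pipeline beyond the regular grids. Most draws
#' are destabilizing under the defaults, mirroring the empirical tendency of
#' random mutations.
#'
#' @param n number of alleles (>= 1; 0 is an error).
#' @param ddg_folding_mean,ddg_folding_sd Gaussian parameters for
#'   `ddG_folding`, kcal/mol.
#' @param ddg_binding_mean,ddg_binding_sd Gaussian parameters for
#'   `ddG_binding`, kcal/mol.
#' @param seed mandatory integer seed.
#' @return a data.frame with columns `id`, `ddG_folding`, `ddG_binding`.
#' @export
gen_mutation_panel <- function(n, ddg_folding_mean = 1, ddg_folding_sd = 2,
                               ddg_binding_mean = 1, ddg_binding_sd = 2,
                               seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  data.frame(id = sprintf("mut%03d", seq_len(n)),
             ddG_folding = stats::rnorm(n, ddg_folding_mean, ddg_folding_sd),
             ddG_binding = stats::rnorm(n, ddg_binding_mean, ddg_binding_sd))
}

#' Label fixture: the eight lambda-repressor CI point mutations
#'
#' Amino-acid substitution labels of the eight CI N-terminal-domain mutants
#' used in the experimental part of the study (labels only; no phenotype
#' values are claimed).
#'
#' @return character vector of eight substitution labels.
#' @export
ci_mutation_labels <- function() {
  c("M23L", "L33F", "K53N", "S55R", "V56I", "E57K", "E58D", "F59L")
}
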