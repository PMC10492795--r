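#' Mutation grid specification
#'
#' Evenly spaced, endpoint-inclusive grids of single mutants, either directly
#' in free-energy changes or as target phenotypes to be inverted back to
#' ddG. Defaults are the study grids: ddG from -2 to 13 kcal/mol in steps of
#' 0.125 (121 values), single-heterozygote phenotypes from 0.5 to 1.02 AU in
#' steps of 0.005 (105 values), homozygote phenotypes from 0 to 1.02 AU in
#' steps of 0.01 (103 values).
#'
#' @param mode `"ddg"`, `"phenotype_single"` or `"phenotype_homozygote"`.
#' @param start,stop,step grid limits and spacing (kcal/mol for `"ddg"`,
#'   AU otherwise). `start <= stop`, `step > 0`; both endpoints included.
#' @return an object of class `grid_spec` with a `values` vector.
#' @examples
#' length(build_grid("ddg")$values)    # 121
#' @export
build_grid <- function(mode = c("ddg", "phenotype_single",
                                "phenotype_homozygote"),
                       start = NULL, stop = NULL, step = NULL) {
  mode <- match.arg(mode)
  def <- switch(mode,
    ddg = c(-2, 13, 0.125),
    phenotype_single = c(0.5, 1.02, 0.005),
    phenotype_homozygote = c(0, 1.02, 0.01))
  start <- start %||% def[1]; stop <- stop %||% def[2]; step <- step %||% def[3]
  .stop_if_not_number(start, "start"); .stop_if_not_number(stop, "stop")
  .stop_if_not_number(step, "step")
  if (step <= 0 || start > stop)
    stop("degenerate grid: need step > 0 and start <= stop", call. = FALSE)
  n <- floor(round((stop - start) / step, 9)) + 1L
  values <- start + step * (seq_len(n) - 1L)
  structure(list(mode = mode, start = start, stop = stop, step = step,
                 values = values), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid [%s]: %d values from %g to %g (step %g)\n",
              x$mode, length(x$values), x$values[1],
              x$values[length(x$values)], x$step))
  invisible(x)
}

# Phenotype of one single mutant (vectorized over ddg) for a given model,
# mutation type and zygosity, on the raw (pre-linking) scale.
.single_w <- function(ddg, mutation_type, zygosity, model, params, config) {
  f <- mutation_type == "folding"
  d0 <- numeric(length(ddg))
  if (model == "model1") {
    if (!f) stop("binding mutations are undefined in the folding-only model",
                 call. = FALSE)
    if (zygosity == "heterozygous") .m1_w(ddg, d0, params)
    else .m1_w(ddg, ddg, params)
  } else {
    ddf <- if (f) ddg else d0
    ddb <- if (f) d0 else ddg
    if (zygosity == "heterozygous") .m2_w(ddf, ddb, d0, d0, params, config)
    else .m2_w(ddf, ddb, ddf, ddb, params, config)
  }
}

#' Invert a target phenotype to a mutational free-energy change
#'
#' The phenotype is strictly decreasing in ddG for both models, so the root
#' is unique when it exists. Targets outside the attainable range (above the
#' stabilizing-limit maximum, or at/below the asymptotic lower bound, e.g.
#' 0.5 for a single heterozygote in the folding-only model) are flagged
#' infeasible: the corresponding entry is NA and a warning reports the count;
#' no error is raised.
#'
#' @param W_target target phenotype(s), AU.
#' @param mutation_type `"folding"` or `"binding"` (binding requires the
#'   ligand-binding model).
#' @param zygosity `"heterozygous"` (mutation on one allele, other allele
#'   wild type) or `"homozygous"` (same mutation on both alleles).
#' @param model `"model1"` (folding only) or `"model2"` (folding + binding).
#' @param params [energy_params()].
#' @param config [system_config()] (ligand-binding model only).
#' @param bracket ddG search interval, kcal/mol.
#' @return numeric vector of ddG values (kcal/mol), NA where infeasible, with
#'   attribute `n_infeasible`. Residual |W(ddG) - W_target| <= 1e-9.
#' @examples
#' phenotype_to_ddg(1, model = "model1")   # 0: the wild type
#' @export
phenotype_to_ddg <- function(W_target,
                             mutation_type = c("folding", "binding"),
                             zygosity = c("heterozygous", "homozygous"),
                             model = c("model2", "model1"),
                             params = energy_params(),
                             config = system_config(),
                             bracket = c(-40, 60)) {
  mutation_type <- match.arg(mutation_type)
  zygosity <- match.arg(zygosity)
  model <- match.arg(model)
  .stop_if_not_number(W_target, "W_target")
  w_at <- function(d) .single_w(d, mutation_type, zygosity, model, params,
                                config)
  w_hi <- w_at(bracket[1])    # stabilizing limit: maximal phenotype
  w_lo <- w_at(bracket[2])    # destabilizing limit: asymptotic minimum
  out <- vapply(W_target, function(tgt) {
    if (!is.finite(tgt) || tgt > w_hi || tgt <= w_lo) return(NA_real_)
    if (tgt == w_hi) return(bracket[1])
    stats::uniroot(function(d) w_at(d) - tgt, interval = bracket,
                   tol = 1e-12)$root
  }, 0)
  bad <- is.na(out)
  if (any(bad))
    warning(sprintf("%d of %d phenotype targets outside the attainable range (%.6g, %.6g]; flagged NA",
                    sum(bad), length(out), w_lo, w_hi), call. = FALSE)
  structure(out, n_infeasible = sum(bad))
}

#' Run a full mutation-combination scenario
#'
#' Builds the single-mutant panel from a grid (inverting phenotypes to ddG
#' where the grid is phenotype-valued), forms all ordered pairs for the
#' requested combination kinds, computes observed phenotypes with the chosen
#' model, pushes every phenotype through the linking function, and scores the
#' pairs: additive/log-additive expectations and interaction scores for
#' within- and between-allele doubles (the C = 0.5 / 0 lower bound applied on
#' the transformed scale), midpoint expectation and degree of dominance for
#' compound heterozygotes built from homozygote-derived mutations.
#'
#' Within-allele pairs sum the two ddG values on allele 1 (allele 2 wild
#' type); between-allele pairs place one ddG on each allele; compound
#' heterozygotes pair mutations whose ddG reproduces the homozygote grid.
#' Infeasible grid points are dropped (counted in the result's summary), and
#' output ordering is deterministic.
#'
#' @param model `"model2"` or `"model1"`.
#' @param params [energy_params()].
#' @param config [system_config()].
#' @param grid a [build_grid()] spec for the single mutants (`"ddg"` or
#'   `"phenotype_single"`) used by within/between combinations.
#' @param homozygote_grid grid for the compound-heterozygote stage (`"ddg"`
#'   or `"phenotype_homozygote"`); defaults to `grid` when that is ddG-valued.
#' @param mutation_type `"folding"` or `"binding"` mutations.
#' @param linking a [linking_spec()].
#' @param combinations subset of `c("within", "between", "compound_het")`.
#' @return a data.frame of class `scenario_result`, one row per ordered pair
#'   per combination kind, with phenotypes (transformed scale), expectations,
#'   interaction scores, clamp flags and dominance columns, plus metadata in
#'   `attr(, "meta")` (model, parameters, linking, dropped-point and clamp
#'   counts).
#' @examples
#' res <- run_scenario("model1", grid = build_grid("ddg", -2, 13, 1),
#'                     combinations = "between")
#' max(abs(res$e_add))   # folding-only between-allele doubles are additive
#' @export
run_scenario <- function(model = c("model2", "model1"),
                         params = energy_params(),
                         config = system_config(),
                         grid = build_grid("ddg"),
                         homozygote_grid = NULL,
                         mutation_type = c("folding", "binding"),
                         linking = linking_spec("linear"),
                         combinations = c("within", "between",
                                          "compound_het")) {
  model <- match.arg(model)
  mutation_type <- match.arg(mutation_type)
  combinations <- match.arg(combinations, several.ok = TRUE)
  stopifnot(inherits(grid, "grid_spec"), inherits(linking, "linking_spec"),
            inherits(params, "energy_params"),
            inherits(config, "system_config"))
  if (model == "model1" && mutation_type == "binding")
    stop("binding mutations are undefined in the folding-only model",
         call. = FALSE)

  dropped <- c(single = 0L, homozygote = 0L)

  # single-mutant ddG panel for within/between
  singles_ddg <- NULL
  if (any(c("within", "between") %in% combinations)) {
    if (grid$mode == "phenotype_homozygote")
      stop("within/between combinations need a 'ddg' or 'phenotype_single' grid",
           call. = FALSE)
    if (grid$mode == "ddg") {
      singles_ddg <- grid$values
    } else {
      inv <- suppressWarnings(
        phenotype_to_ddg(grid$values, mutation_type, "heterozygous", model,
                         params, config))
      dropped["single"] <- attr(inv, "n_infeasible")
      singles_ddg <- inv[!is.na(inv)]
    }
  }

  # homozygote-derived ddG panel for compound heterozygotes
  homo_ddg <- NULL
  if ("compound_het" %in% combinations) {
    hg <- homozygote_grid %||% (if (grid$mode == "ddg") grid else
      stop("compound_het needs a 'ddg' or 'phenotype_homozygote' homozygote_grid",
           call. = FALSE))
    stopifnot(inherits(hg, "grid_spec"))
    if (hg$mode == "phenotype_single")
      stop("compound_het needs a 'ddg' or 'phenotype_homozygote' grid",
           call. = FALSE)
    if (hg$mode == "ddg") {
      homo_ddg <- hg$values
    } else {
      inv <- suppressWarnings(
        phenotype_to_ddg(hg$values, mutation_type, "homozygous", model,
                         params, config))
      dropped["homozygote"] <- attr(inv, "n_infeasible")
      homo_ddg <- inv[!is.na(inv)]
    }
  }

  w_pair <- function(dA, dB, arrangement) {
    # arrangement: "cis" = both on allele 1, "trans" = one per allele
    f <- mutation_type == "folding"
    if (model == "model1") {
      if (arrangement == "cis") .m1_w(dA + dB, numeric(length(dA)), params)
      else .m1_w(dA, dB, params)
    } else {
      z <- numeric(length(dA))
      if (arrangement == "cis") {
        s <- dA + dB
        .m2_w(if (f) s else z, if (f) z else s, z, z, params, config)
      } else {
        .m2_w(if (f) dA else z, if (f) z else dA,
              if (f) dB else z, if (f) z else dB, params, config)
      }
    }
  }
  tr <- function(w) apply_linking(w, linking)

  rows <- list()
  if (!is.null(singles_ddg)) {
    W_single <- tr(.single_w(singles_ddg, mutation_type, "heterozygous",
                             model, params, config))
    pair <- expand.grid(i = seq_along(singles_ddg),
                        j = seq_along(singles_ddg))
    for (kind in intersect(c("within", "between"), combinations)) {
      W_obs <- tr(w_pair(singles_ddg[pair$i], singles_ddg[pair$j],
                         if (kind == "within") "cis" else "trans"))
      ex <- expected_double(W_single[pair$i], W_single[pair$j], tr(1), kind)
      sc <- interaction_scores(W_obs, ex$W_exp_add, ex$W_exp_log)
      rows[[kind]] <- data.frame(
        combination = kind, mutation_type = mutation_type,
        ddG_A = singles_ddg[pair$i], ddG_B = singles_ddg[pair$j],
        W_A = W_single[pair$i], W_B = W_single[pair$j], W_obs = W_obs,
        ex, sc,
        W_AA = NA_real_, W_BB = NA_real_, W_exp_het = NA_real_,
        degree = NA_real_, degree_defined = NA)
    }
  }
  if (!is.null(homo_ddg)) {
    W_homo <- tr(.single_w(homo_ddg, mutation_type, "homozygous", model,
                           params, config))
    pair <- expand.grid(i = seq_along(homo_ddg), j = seq_along(homo_ddg))
    W_het <- tr(w_pair(homo_ddg[pair$i], homo_ddg[pair$j], "trans"))
    dom <- degree_of_dominance(W_homo[pair$i], W_homo[pair$j], W_het)
    rows[["compound_het"]] <- data.frame(
      combination = "compound_het", mutation_type = mutation_type,
      ddG_A = homo_ddg[pair$i], ddG_B = homo_ddg[pair$j],
      W_A = NA_real_, W_B = NA_real_, W_obs = W_het,
      W_exp_add = NA_real_, W_exp_log = NA_real_, C = NA_real_,
      clamp_add = NA, clamp_log = NA,
      e_add = NA_real_, E_log = NA_real_, E_log_defined = NA,
      W_AA = W_homo[pair$i], W_BB = W_homo[pair$j],
      W_exp_het = dom$W_exp_het, degree = dom$degree,
      degree_defined = dom$defined)
  }
  out <- do.call(rbind, rows[intersect(c("within", "between", "compound_het"),
                                       names(rows))])
  rownames(out) <- NULL
  attr(out, "meta") <- list(
    model = model, mutation_type = mutation_type, params = params,
    config = config, linking = linking, grid = grid,
    homozygote_grid = if ("compound_het" %in% combinations)
      (homozygote_grid %||% grid) else NULL,
    dropped = dropped,
    clamp_counts = c(add = sum(out$clamp_add, na.rm = TRUE),
                     log = sum(out$clamp_log, na.rm = TRUE)))
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  m <- attr(x, "meta")
  if (is.null(m)) return(print(as.data.frame(x), ...))   # subsets lose meta
  cat(sprintf("Scenario: %s, %s mutations, link %s (m = %g)\n",
              m$model, m$mutation_type, m$linking$kind, m$linking$m))
  if (m$model == "model2")
    cat(sprintf("  ligand ratio %g, X_T = %g\n", m$config$ligand_ratio,
                m$config$X_T))
  tab <- table(x$combination)
  cat("  rows:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  dropped grid points: %d singles, %d homozygotes; clamps: add %d, log %d\n",
              m$dropped["single"], m$dropped["homozygote"],
              m$clamp_counts["add"], m$clamp_counts["log"]))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Heatmap of a scenario result
#'
#' Draws an `image()` heatmap of one scored quantity over the two
#' single-mutant axes for one combination kind.
#'
#' @param x a [run_scenario()] result.
#' @param combination which combination kind to plot.
#' @param value column to colour by (`"e_add"`, `"E_log"`, `"W_obs"`, or
#'   `"degree"` for compound heterozygotes).
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.scenario_result <- function(x, combination = c("within", "between",
                                                    "compound_het"),
                                 value = "e_add", ...) {
  combination <- match.arg(combination)
  d <- x[x$combination == combination, ]
  if (nrow(d) == 0) stop("no rows for combination ", combination, call. = FALSE)
  a <- sort(unique(d$ddG_A)); b <- sort(unique(d$ddG_B))
  z <- matrix(NA_real_, length(a), length(b))
  z[cbind(match(d$ddG_A, a), match(d$ddG_B, b))] <- d[[value]]
  graphics::image(a, b, z, xlab = "ddG mutant A (kcal/mol)",
                  ylab = "ddG mutant B (kcal/mol)",
                  main = sprintf("%s: %s", combination, value), ...)
  invisible(z)
}
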