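# Boltzmann factors are clipped at exp(+-500): beyond that the species is
# numerically absent/saturated anyway and exp() would overflow to Inf.
.eexp <- function(z) exp(pmin(pmax(z, -500), 500))

.rt <- function(params) params$R * params$T

.stop_if_not_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
      (finite && any(!is.finite(x)))) {
    stop(sprintf("'%s' must be finite numeric, got: %s", name,
                 paste(utils::head(x, 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
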