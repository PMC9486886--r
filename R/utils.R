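#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed RNG seed when `seed` is given, otherwise use the
## current RNG stream. All stochastic entry points funnel through this.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_config <- function(...) {
  stop(structure(class = c("polypaint_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_ploidy <- function(...) {
  stop(structure(class = c("polypaint_ploidy_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
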