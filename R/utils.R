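# Physical and assay constants used across modules.

# Boltzmann constant, J/K (2019 SI exact value).
.kB <- 1.380649e-23

# Molar masses; HSA from its amino-acid sequence (~66.5 kDa), ApoM ~21 kDa.
.HSA_KDA <- 66.5
.APOM_KDA <- 21

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' that seeded package functions do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Positive-scalar check with a domain-error message.
.checkPositive <- function(...) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("'%s' must be a positive finite number", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Relative difference helper used in validity methods.
.relDiff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)
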