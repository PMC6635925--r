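#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate anova ave complete.cases lm optimize p.adjust
#'   pf quantile rbeta rchisq reshape residuals rnorm runif sd setNames var
#' @importFrom utils read.table write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched so seeded estimators compose deterministically.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

qfk_log <- function(..., verbose = getOption("qstfstkit.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[qstfstkit] ", ...)
  invisible(NULL)
}

qfk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qstfstkit_error")))
}
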