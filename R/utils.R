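#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov binomial chisq.test coef complete.cases cor cov
#'   cov2cor fisher.test glm lm median model.matrix na.omit p.adjust pchisq
#'   plogis pnorm predict pt qnorm quantile rbinom rnorm runif sd setNames
#'   shapiro.test t.test var wilcox.test glm.control
#' @importFrom utils head read.delim write.table
NULL

# Derive a per-stage substream seed from one global seed. Keeps results
# reproducible while letting stages (truth, subjects, genotypes, QC) be
# re-run independently. Result stays inside 32-bit integer range.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (abs(as.integer(seed)) + 104729L * as.integer(stage)) %% 2147483587L
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
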