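#' @importFrom stats cor var coef predict plogis rbinom rnorm runif sd
#'   binomial glm logLik pnorm lm as.formula setNames complete.cases
#'   cmdscale cutree hclust as.dist quantile step
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_netpls <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "netpls_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Derive a reproducible stage seed from a master seed
#'
#' A single user-facing seed fans out to per-stage seeds so that each
#' pipeline stage is independently reproducible. The derivation hashes the
#' (seed, stage label) pair; results are stable across sessions and always
#' below 2^31.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- rlang::hash(list(as.integer(seed), as.character(stage)))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

# lexicographically smallest name among those attaining the max; `warn_tie`
# logs ties because representative choice must be auditable
argmax_lex <- function(x, names, label = "score") {
  stopifnot(length(x) == length(names))
  top <- which(x >= max(x) - 1e-12)
  if (length(top) > 1L) {
    pick <- top[order(names[top])][1L]
    message("tie on ", label, " among {", paste(names[top], collapse = ", "),
            "}; picked '", names[pick], "' (lexicographic)")
    return(pick)
  }
  top
}
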