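contexts <- c("CG", "CHG", "CHH")
domain_levels <- c("centromere", "h3k9me3", "h3k27me3", "euchromatin")
annotation_levels <- c("gene", "promoter", "TE", "intergenic")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("%s must be in [0, 1]", name)
  invisible(x)
}

#' Derive a stream-specific seed from a master seed
#'
#' Keeps independent stochastic components (simulation, fitting starts,
#' permutations, bootstrap) decoupled while remaining reproducible from a
#' single integer. The result stays below 2^31.
#'
#' @param seed master integer seed
#' @param stream small non-negative integer identifying the consumer
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}
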