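#' @useDynLib bowdti, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict qnorm rbinom rnorm runif sd binom.test glm
#'   binomial rmultinom
#' @importFrom utils read.table write.csv write.table packageVersion
NULL

# Classed conditions so callers/tests can distinguish failure modes without
# string-matching messages.
bow_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "bow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_invalid <- function(msg) bow_stop(msg, "bow_invalid_input")
stop_degenerate <- function(msg) bow_stop(msg, "bow_degenerate_training")
stop_signature <- function(msg) bow_stop(msg, "bow_signature_error")
stop_infeasible <- function(msg) bow_stop(msg, "bow_infeasible_request")
stop_dangling <- function(msg) bow_stop(msg, "bow_dangling_reference")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds derived from one user seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483647L
}
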