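#' @keywords internal
"_PACKAGE"

#' @useDynLib stepwedge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize lm coef median quantile pnorm rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Typed conditions: every user-facing failure carries a stepwedge_* class so
# callers (and the CLI) can distinguish parse errors, contract violations and
# fit-quality rejections.
sw_error <- function(message, class = "stepwedge_contract_error", data = NULL) {
  stop(errorCondition(message, data = data,
                      class = c(class, "stepwedge_error", "error")))
}

sw_warning <- function(message, class = "stepwedge_warning") {
  warning(warningCondition(message, class = c(class, "warning")))
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    sw_error(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    sw_error(sprintf("'%s' must be strictly positive", name))
  invisible(x)
}
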