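#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort %||% .data
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head modifyList write.csv read.csv
#' @useDynLib ellipseg, .registration = TRUE
NULL

abort_config <- function(msg, field = NULL) {
  abort(msg, class = "ellipseg_config_error", field = field)
}

abort_input <- function(msg) {
  abort(msg, class = "ellipseg_input_error")
}

abort_io <- function(msg) {
  abort(msg, class = "ellipseg_io_error")
}

abort_metric <- function(msg) {
  abort(msg, class = "ellipseg_metric_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, config = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || !is.finite(x) ||
    x < lower || x > upper || (integer && x != round(x))
  if (bad) {
    msg <- sprintf("`%s` must be a %s in [%s, %s], got %s", name,
                   if (integer) "whole number" else "number",
                   format(lower), format(upper),
                   paste(format(x), collapse = ","))
    if (config) abort_config(msg, field = name) else abort_input(msg)
  }
  invisible(x)
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

check_mask <- function(m, name = "mask") {
  if (!is.matrix(m) || !is.numeric(m) && !is.logical(m))
    abort_input(sprintf("`%s` must be a numeric or logical matrix", name))
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (!all(m %in% c(0, 1)))
    abort_input(sprintf("`%s` must be binary (values 0/1)", name))
  m
}

# Evaluate `expr` under a private RNG stream so package randomness neither
# consumes nor disturbs the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seeds below 2^31
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}
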