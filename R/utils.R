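#' @importFrom stats rnorm runif rbinom qt pt sd cor coef plogis qlogis
#'   dgamma convolve
#' @importFrom rlang abort warn `%||%`
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible child seed from a master seed and a stage/subject tag.
# Keeps every stochastic stage independently re-runnable. Result < 2^31.
child_seed <- function(master, ...) {
  tags <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147483563L
  as.integer(h) + 1L
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Shared affine check for co-registered volumes.
same_grid <- function(a, b) {
  identical(dim(a), dim(b))
}
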