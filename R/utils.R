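# Internal helpers shared across modules.

# Deterministic sub-seed derivation: all randomness in the package flows
# from one integer master seed; per-unit seeds are derived with a
# Weyl-style integer mix kept strictly below 2^31 so they are valid R
# seeds on all platforms.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1
  s <- (as.double(seed) %% m)
  for (k in seq_len(max(1L, length(index)))) {
    s <- (s * 48271 + as.double(index[[min(k, length(index))]]) * 2654435761) %% m
  }
  as.integer(floor(s))
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "relfun_invalid_argument")
  }
  if (x < min || x > max || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(min), format(max)),
          class = "relfun_invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %s.", name, min),
          class = "relfun_invalid_argument")
  }
  invisible(as.integer(x))
}

check_columns <- function(data, cols, name = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste0("`", missing, "`", collapse = ", ")),
          class = "relfun_invalid_argument")
  }
  invisible(data)
}

# mean-1 multiplicative log-normal noise at a given coefficient of variation
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
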