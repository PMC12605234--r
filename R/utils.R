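# internal helpers shared across modules

# centred moving average; edges fall back to the original samples so that
# length and alignment are preserved
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- (h + 1L):(n - h)
  s <- x
  s[i] <- (cs[i + h + 1L] - cs[i - h]) / k
  s
}

# trapezoidal integral with uniform spacing dx
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside its valid range %s%g, %g%s.",
      field, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# truncated standard normal draws on [-3, 3] via inverse-CDF (vectorised,
# deterministic sample count for a given RNG state)
rtnorm3 <- function(n) {
  p <- runif(n, pnorm(-3), pnorm(3))
  qnorm(p)
}

# log-normal draw with mean `m` and coefficient of variation `cv`
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0 || m == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  m * exp(rnorm(n, 0, sdlog)) / sqrt(1 + cv^2)
}
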