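# internal helpers

# population SD (divide by n): fixed convention for tolerance calibration
.popSD <- function(x) sqrt(mean((x - mean(x))^2))

.gcd <- function(a, b) {
  while (b > 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# deterministic sub-seed derivation; stays below 2^31
.subSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in seq_along(idx))
    s <- (s * 48271 + as.double(idx[i]) * 9973 + 1) %% 2147483647
  as.integer(s)
}

.fileSlug <- function(label) gsub("[^A-Za-z0-9._-]", "_", label)

.stopifnotScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}
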