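# Internal helpers: classed error conditions, seed hygiene, seed derivation.

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ephapsim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_with("ephapsim_domain_error", "`%s` must be a finite numeric scalar", name)
  if (positive && x <= 0)
    stop_with("ephapsim_domain_error", "`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0)
    stop_with("ephapsim_domain_error", "`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-(frequency, repeat, damage) seed stream below 2^31.
# Mixing uses a small-multiplier linear congruence so every intermediate stays
# exactly representable in a double; the master seed enters through xor.
derive_seed <- function(seed0, f, rep, dp) {
  vals <- c(round(f * 1000), rep, round(dp$b * 1e6), round(dp$h * 1e6))
  a <- 0
  for (v in vals) a <- (a * 69069 + v + 1) %% 2147483647
  s <- bitwXor(as.integer(seed0 %% 2147483647L), as.integer(a))
  if (s < 0L) s <- -s
  s
}
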