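# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

# Two-sided normal p from a z statistic.
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# 1-df chi-square upper tail.
chisq1_tail <- function(x) stats::pchisq(x, df = 1, lower.tail = FALSE)

# Stage offsets of the seed-splitting scheme: every stochastic stage derives
# its own seed as base seed + offset, so stages are independently reproducible.
.seed_offsets <- c(panel = 1L, mqtl = 2L, gwas = 3L, probe = 100L)

stage_seed <- function(seed, stage, k = 0L) {
  seed <- as.integer(seed)
  off <- .seed_offsets[[stage]]
  s <- seed + off + as.integer(k) * 7L
  s %% .Machine$integer.max
}

# Uniform condition checks for exported functions.
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_cfg("'%s' must be a single number in [%s, %s]", name, lower, upper)
  x
}
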