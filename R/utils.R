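# internal helpers shared across modules

# round half away from zero; base round() rounds half to even
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a locally scoped RNG seed; NULL means use the
# ambient RNG stream (non-reproducible)
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x)
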