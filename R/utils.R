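# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a master seed and an index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629
  as.integer(s)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("'%s' must be a single probability in [0, 1], got %s",
                name, paste(format(x), collapse = ","))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_config("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# Contiguous block assignment of M items into n_blocks blocks of near-equal
# size (used by the delete-a-block jackknife and block LD construction).
block_index <- function(M, n_blocks) {
  sort(rep_len(seq_len(n_blocks), M))
}
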