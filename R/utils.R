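# Derive n child seeds from one base seed (kept within 32-bit signed range).
derive_seeds <- function(base_seed, n) {
  withr::with_seed(as.integer(base_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

# %||% for defaults
`%||%` <- function(a, b) if (is.null(a)) b else a
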