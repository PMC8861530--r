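# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Non-negative whole-number check (counts, depths, positions).
is_count <- function(x, allow_zero = TRUE) {
  is.numeric(x) && all(is.finite(x)) && all(x == floor(x)) &&
    all(x >= if (allow_zero) 0 else 1)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
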