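# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("`%s` must be a single number", name)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    .stopf("`%s` = %s is outside the allowed range %s%s, %s%s", name,
           format(x), if (lower_open) "(" else "[", format(lower),
           format(upper), if (upper_open) ")" else "]")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")
.BASE_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L)

# Random DNA string of length n with P(G) + P(C) = gc.
.rand_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  intToUtf8(unname(.BASE_CODES)[idx])
}

.rand_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.gc_fraction <- function(contigs) {
  x <- Biostrings::BStringSet(contigs)
  gc <- sum(Biostrings::letterFrequency(x, "GC"))
  tot <- sum(Biostrings::width(x))
  if (tot == 0) return(NA_real_)
  gc / tot
}
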