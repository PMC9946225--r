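# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so simulators never perturb user code.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# i.i.d. DNA string at a given GC fraction
randomDna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc > 0, gc < 1)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementBase <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- map[x]
  out[is.na(out)] <- "N"
  unname(out)
}

# sample from the elements of x (never from 1:x when x is a scalar)
resampleFrom <- function(x, size = 1L, ...) {
  x[sample.int(length(x), size, ...)]
}

# strict input check helper
.assertScalarNum <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}
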