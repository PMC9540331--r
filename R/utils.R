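# internal helpers shared across modules

# centered moving average, width 3; edges use the available neighbours
sma3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[2:(n - 1L)] <- (v[1:(n - 2L)] + v[2:(n - 1L)] + v[3:n]) / 3
  out[1L] <- mean(v[1:2])
  out[n] <- mean(v[(n - 1L):n])
  out
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# derive a bounded child seed (R integers are 32-bit)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
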