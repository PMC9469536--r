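## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
c2s <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#' @param x DNA string over {A,C,G,T,N}.
#' @return reverse-complemented string.
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## substring of a circular sequence; start > end means the interval wraps
## the origin
circ_substr <- function(seq, start, end, circular = TRUE) {
  n <- nchar(seq)
  stopifnot(start >= 1L, end >= 1L, start <= n, end <= n)
  if (start <= end) return(substr(seq, start, end))
  if (!circular) stop("wrapped interval (start > end) on a linear sequence")
  paste0(substr(seq, start, n), substr(seq, 1L, end))
}

## 1-based positions covered by a (possibly wrapping) interval, in 5'->3'
## order along the forward strand
interval_positions <- function(start, end, n) {
  if (start <= end) return(seq.int(start, end))
  c(seq.int(start, n), seq.int(1L, end))
}

interval_length <- function(start, end, n) {
  if (start <= end) end - start + 1L else (n - start + 1L) + end
}

## random DNA of length n at a target GC fraction (drawn from the active RNG)
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  c2s(sample(names(p), n, replace = TRUE, prob = p))
}

## run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
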