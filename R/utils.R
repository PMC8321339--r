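# Internal helpers shared across modules.

# Round half away from zero (positive inputs only in practice). base::round()
# rounds half to even, which disagrees with how dataset percentages are
# conventionally reported (e.g. 81.08 -> 81 but 54.5 -> 55, not 54).
round_half_up <- function(x) floor(x + 0.5)

stop_input <- function(...) stop(..., call. = FALSE)

# Map out-of-range indices back into 1..n by half-sample symmetric reflection
# (edge value repeated: ... b a | a b c ... | c b). Valid for offsets up to n.
mirror_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

# Correlate a 1-D kernel along one dimension of a 3-D array with reflect
# padding. Kernel origin is tap floor(L/2)+1, so an even-length kernel looks
# one step further into the past than into the future.
conv_along <- function(a, kernel, along) {
  d <- dim(a)
  n <- d[along]
  L <- length(kernel)
  centre <- L %/% 2L + 1L
  if (L - centre >= n || centre - 1L >= n) {
    stop_input("kernel of length ", L, " is too large for dimension ", along,
               " of size ", n)
  }
  perm <- c(along, setdiff(seq_along(d), along))
  m <- matrix(aperm(a, perm), nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  base <- seq_len(n)
  for (j in seq_len(L)) {
    idx <- mirror_index(base + (j - centre), n)
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
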