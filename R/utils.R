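# internal helpers shared across modules

# canonical key for an unordered gene pair: (min, max) by string order
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# put gene_a/gene_b of a pair table into canonical (min, max) order
canonicalise_pairs <- function(df, a = "gene_a", b = "gene_b") {
  ga <- pmin(df[[a]], df[[b]])
  gb <- pmax(df[[a]], df[[b]])
  df[[a]] <- ga
  df[[b]] <- gb
  df
}

# run `code` under a fixed RNG seed when one is supplied, untouched otherwise
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# empirical upper-tail p with a pseudo-count, so p is never exactly 0:
# p_i = (1 + #{null >= x_i}) / (1 + |null|)
empirical_p_ge <- function(null, x) {
  n <- length(null)
  null <- sort(null)
  # #{null >= x} = n - #{null < x}
  hits <- n - findInterval(x, null, left.open = TRUE)
  (1 + hits) / (1 + n)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
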