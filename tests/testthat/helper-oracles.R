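# Independent oracles, kept deliberately naive.

# All permutations of a vector, by recursive insertion.
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

mk_s_statistic <- function(v) {
  d <- outer(v, v, "-")
  sum(sign(d[lower.tri(d)]))
}

# Null distribution of S under random order: S for every permutation of 1:n.
mk_null_distribution <- function(n) {
  vapply(all_perms(seq_len(n)), mk_s_statistic, numeric(1))
}

# Two-sided p by direct tail counting over the enumerated null.
mk_bruteforce_p <- function(v, null_s = mk_null_distribution(length(v))) {
  s <- mk_s_statistic(v)
  min(1, 2 * min(mean(null_s >= s), mean(null_s <= s)))
}
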