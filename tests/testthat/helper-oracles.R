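# brute-force exact Mann-Whitney oracle, written independently of the
# implementation: recursively enumerate which pooled positions belong to
# group A and tabulate the U distribution over midranks
mwu_brute <- function(a, b, alternative = "two.sided") {
  r <- rank(c(a, b))
  na <- length(a)
  n <- length(r)
  us <- numeric(0)
  rec <- function(start, chosen) {
    if (length(chosen) == na) {
      us <<- c(us, sum(r[chosen]) - na * (na + 1) / 2)
      return()
    }
    if (start > n) return()
    rec(start + 1L, c(chosen, start))
    if (n - start >= na - length(chosen)) rec(start + 1L, chosen)
  }
  rec(1L, integer(0))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  p <- switch(alternative,
    two.sided = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9),
    greater = mean(us >= u_obs - 1e-9),
    less = mean(us <= u_obs + 1e-9))
  list(U = u_obs, p = p)
}

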