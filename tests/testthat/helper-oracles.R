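# Independent oracles used across tests. These deliberately avoid the
# package's closed-form eigendecomposition path.

# Taylor-series matrix exponential with scaling and squaring
series_expm <- function(A) {
  s <- max(0L, ceiling(log2(max(1e-300, norm(A, "1")))))
  B <- A / 2^s
  term <- diag(nrow(A))
  out <- term
  for (k in 1:60) {
    term <- term %*% B / k
    out <- out + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) out <- out %*% out
  out
}

# scripted evaluation of the two-pool recovery, straight from the matrix form
oracle_mz <- function(p, ti, td) {
  A <- matrix(c(-(p$r1f + p$psr * p$kmf), p$psr * p$kmf,
                p$kmf, -(p$r1m + p$kmf)), 2, 2)
  S <- diag(c(p$sf, p$sm))
  M0 <- c(p$m0f, p$psr * p$m0f)
  E1 <- series_expm(A * ti)
  E2 <- series_expm(A * td)
  as.vector((E1 %*% S %*% (diag(2) - E2) + (diag(2) - E1)) %*% M0)
}

oracle_signal <- function(p, scheme, magnitude = TRUE) {
  s <- vapply(seq_len(nrow(scheme)),
              function(i) oracle_mz(p, scheme$ti[i], scheme$td[i])[1],
              numeric(1))
  if (magnitude) abs(s) else s
}

# random valid tissue parameter draws spanning the biological box and beyond
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sir_params(psr = runif(1, 0, 0.5),
               r1f = runif(1, 0.2, 3),
               r1m = runif(1, 0.2, 3),
               sf = runif(1, -1, -0.7),
               sm = runif(1, 0.6, 1),
               m0f = runif(1, 0.3, 3),
               kmf = runif(1, 0.5, 60))
  })
}

paper_scheme <- function() sir_default_scheme()
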