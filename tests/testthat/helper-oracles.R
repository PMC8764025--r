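## Independent brute-force oracles shared across test files.

## independent brute-force oracle: posterior by exhaustive path enumeration
bruteForcePosterior <- function(obs, founderCalls, pos, chromLen, eps, G,
                                xoverPerChrom, K = ncol(founderCalls)) {
  S <- length(obs)
  emit <- function(o, f) {
    if (is.na(o) || is.na(f)) return(1)
    if (o == 1L || f == 1L) return(0.5 * (1 - eps) + 0.5 * eps)
    if (o == f) 1 - eps else eps
  }
  cRate <- xoverPerChrom / chromLen
  r <- 1 - exp(-G * cRate * diff(pos))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), S)))
  wts <- apply(paths, 1L, function(st) {
    w <- (1 / K) * emit(obs[1L], founderCalls[1L, st[1L]])
    for (i in seq_len(S - 1L)) {
      tr <- if (st[i + 1L] == st[i]) 1 - r[i] else r[i] / (K - 1)
      w <- w * tr * emit(obs[i + 1L], founderCalls[i + 1L, st[i + 1L]])
    }
    w
  })
  post <- matrix(0, S, K)
  for (i in seq_len(S)) for (k in seq_len(K))
    post[i, k] <- sum(wts[paths[, i] == k])
  post / rowSums(post)
}

## independent oracle: exact conditional P by enumeration over tables with
## the observed margins (2 x c case)
fisherOracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  cols <- lapply(seq_along(cs), function(j) 0:cs[j])
  grid <- expand.grid(cols)
  probs <- apply(grid, 1L, function(r1) {
    if (sum(r1) != rs[1L]) return(NA_real_)
    r2 <- cs - r1
    if (any(r2 < 0)) return(NA_real_)
    exp(sum(lchoose(cs, r1)) - lchoose(N, rs[1L]))
  })
  pObs <- exp(sum(lchoose(cs, tab[1L, ])) - lchoose(N, rs[1L]))
  sum(probs[!is.na(probs) & probs <= pObs + 1e-12])
}

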