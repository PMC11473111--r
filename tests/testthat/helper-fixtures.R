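# shared fixtures and independent oracles

# single-species exponential-decay model: x(t) = x0 exp(-d t)
decay_model <- function(x0 = 2, d = 0.7, src = 0) {
  kinetic_model(
    "X",
    reactions = list(list(name = "src", type = "source", target = "X",
                          k = "s"),
                     list(name = "snk", type = "sink", target = "X",
                          k = "d")),
    params = c(s = src, d = d), initial = c(X = x0))
}

# brute-force hypergeometric upper tail P(X >= k) by exhaustive summation
# over the support -- independent of phyper
hyper_tail_oracle <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# DE table for a single entity with a given 5-timepoint log2FC profile
de_row <- function(id, profile, adj_p = 0.01) {
  data.frame(id = id, timepoint = c("D1", "D3", "D6", "D10", "D14"),
             log2fc = profile, adj_p = adj_p, stringsAsFactors = FALSE)
}

# small synthetic study reused across tests (cached per session)
small_study <- local({
  cache <- new.env()
  function(noise_sd = 0.1, seed = 3) {
    key <- paste(noise_sd, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_synthetic_study(noise_sd = noise_sd,
                                               seed = seed)
    cache[[key]]
  }
})
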