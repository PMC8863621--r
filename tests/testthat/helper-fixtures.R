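# shared fixtures, built in code

shipped_anchors <- function() load_anchors()

# a minimal synthetic two-parameter anchor catalog for structural tests
toy_anchors <- function() {
  tibble::tibble(
    tps = "ToyTPS",
    parameter = rep(c("alpha", "beta"), each = 5),
    units = "cm",
    shared_group = NA_character_,
    median_source = "configured",
    percentile = rep(c(2.5, 10, 50, 90, 97.5), 2),
    value = c(0, 1, 2, 3, 4, 10, 10, 15, 20, 20),
    effect_pct = c(-2, -1, 0, 1, 2, -1, -1, 0, 1, 1)
  )
}

toy_survey <- function(n = 40, seed = 11) {
  cm <- community_model(toy_anchors(), "ToyTPS")
  sample_institutions(cm, n, seed = seed)
}

# independent hypergeometric enumeration oracle for Fisher's exact test,
# written directly from the definition using choose()
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(N, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force percentile rank: share of sample at or below the value
rank_percentile <- function(x, v) {
  vapply(v, function(vi) 100 * mean(x <= vi), numeric(1))
}

lookup_fixture_model <- function(models, tps, parameter) {
  models$model[[which(models$tps == tps & models$parameter == parameter)]]
}
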