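# helper: simulate a clustered binary outcome with a phase covariate via a
# cluster random intercept (no phase effect unless beta1 != 0)
simClusteredLog <- function(K = 26, ni = 16, beta0 = -1, beta1 = 0,
                            sd_re = 1, seed = 1) {
  set.seed(seed)
  re <- rnorm(K, 0, sd_re)
  id <- rep(seq_len(K), each = ni)
  phase <- if (ni == 1) rep_len(0:1, K) else
    rep(rep_len(rep(0:1, each = ceiling(ni / 2)), ni), K)
  eta <- beta0 + beta1 * phase + re[id]
  data.frame(y = rbinom(K * ni, 1, plogis(eta)), phase = phase, id = id)
}

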