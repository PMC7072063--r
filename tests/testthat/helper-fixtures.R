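# Shared fixture builders; everything is generated in code.

# singlet scatter columns that pass the default gate
singlet_scatter <- function(n) {
  data.frame("FSC-A" = rep(5e5, n), "FSC-H" = rep(5e5, n),
             "SSC-A" = rep(4e5, n), check.names = FALSE)
}

# a tiny raw case-I sample with given channel intensities
rgb_sample <- function(mCherry, Venus, Cerulean, compensated = FALSE) {
  n <- max(length(mCherry), length(Venus), length(Cerulean))
  ev <- cbind(singlet_scatter(n),
              data.frame(mCherry = rep_len(mCherry, n),
                         Venus = rep_len(Venus, n),
                         Cerulean = rep_len(Cerulean, n)))
  flow_sample(ev, compensated = compensated)
}

# binomial 3-standard-error band (percent scale) for a percentage p at n
three_se_pct <- function(p_pct, n) {
  p <- p_pct / 100
  3 * sqrt(p * (1 - p) / n) * 100
}

# two-clone replicator closed form, fraction of the second clone
replicator2 <- function(f0, mu, t) {
  w <- f0 * exp(mu * t)
  w / sum(w)
}
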