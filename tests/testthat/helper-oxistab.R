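# Shared test helpers.

# mean silhouette width of labelled points in a score space
mean_silhouette <- function(labels, scores) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(scores))
  mean(sil[, "sil_width"])
}

# noiseless Boltzmann series on the standard 0-200 min grid
boltzmann_series <- function(I1 = 0, I2 = 1e6, t0 = 100, dt = 16,
                             time = seq(0, 200, by = 5), temperature = 90) {
  kinetic_series(time, I1 + (I2 - I1) / (1 + exp((t0 - time) / dt)),
                 temperature = temperature)
}

# the transient MNP adduct seen in the first minute of heating of
# hexane-extracted oil
mnp_adduct <- function() {
  spin_system("MNP-adduct", g = 2.0057, a_N = 14.95, a_H = 4.65)
}
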