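# Published rate-constant series for the doxorubicin / VP-AA copolymer
# system, used as fixtures throughout the suite.

ref_temp <- c(278, 298, 310, 323)
ref_k1_T <- c(2.80e-3, 1.27e-2, 1.65e-2, 3.52e-2)   # release, 1/h
ref_km1_T <- c(0.119, 0.137, 0.153, 0.166)          # binding, 1/h

# 310 K / pH 7 / 1e-2 g/mL / 3.9 mol% AA pair
ref_pair <- c(k1 = 0.0165, k_minus1 = 0.153)
# pH 4 / 310 K pair (equilibrium conversion > 1/2)
ref_pair_ph4 <- c(k1 = 0.123, k_minus1 = 0.093)

# random (k1, k-1) pairs, log-uniform on [1e-3, 1] 1/h
random_pairs <- function(n, seed) {
  set.seed(seed)
  matrix(10^runif(2 * n, -3, 0), ncol = 2)  # columns: k1, k_minus1
}

max_rel_diff <- function(a, b, floor = 1e-10) {
  max(abs(a - b) / pmax(abs(b), floor))
}
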