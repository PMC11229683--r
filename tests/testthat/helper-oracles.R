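# Independent oracles and shared fixtures for the test suite.

# Literal O(m^2) Benjamini-Hochberg step-up: for each observation, scan
# every rank j >= its own and take the smallest m * p_(j) / j, clipped
# at 1. Kept deliberately naive and separate from the package path.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q_sorted[i] <- min(1, min(m * p_sorted[j] / j))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Published hydrotime parameter sets for the two leaf-mustard cultivars
# (drought-tolerant WL, drought-sensitive SD) used as generating truth
# in simulation-and-refit experiments.
wl_params <- function() hydrotime_params(psi_b50 = -1.073, sigma = 0.339,
                                         theta_h = 43.054)
sd_params <- function() hydrotime_params(psi_b50 = -0.437, sigma = 0.195,
                                         theta_h = 16.695)

# Small germination observation table builder.
germ_obs <- function(psi, time_h, n_germ_cum, n_total, replicate = "r1") {
  tibble::tibble(psi = psi, replicate = replicate, time_h = time_h,
                 n_germ_cum = n_germ_cum, n_total = n_total)
}

# Recall / false-discovery proportion of predicted target pairs against
# a planted-truth pair table.
pair_recovery <- function(pairs, truth) {
  key <- paste(pairs$lnc_id, pairs$mrna_id)
  tkey <- paste(truth$lnc_id, truth$mrna_id)
  passed <- key[pairs$passed]
  list(
    recall = mean(tkey %in% passed),
    fdp = if (length(passed)) mean(!passed %in% tkey) else 0
  )
}
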