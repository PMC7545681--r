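# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately brute-force and kept separate from the
# implementation paths it checks.

make_cells <- function(patient, cluster, pattern, field = "F1") {
  n <- length(pattern)
  data.frame(patient_id = rep_len(patient, n),
             field_id = rep_len(field, n),
             cluster_id = rep_len(cluster, n),
             cell_id = paste0("cell", seq_len(n)),
             ecad_pattern = pattern)
}

# nested-loop tally of cells into clusters, independent of buildClusterCensus
brute_cluster_tally <- function(cells) {
  key <- unique(cells[c("patient_id", "field_id", "cluster_id")])
  out <- NULL
  for (i in seq_len(nrow(key))) {
    sub <- cells[cells$patient_id == key$patient_id[i] &
                 cells$field_id == key$field_id[i] &
                 cells$cluster_id == key$cluster_id[i], ]
    out <- rbind(out, data.frame(
      patient_id = key$patient_id[i], field_id = key$field_id[i],
      cluster_id = key$cluster_id[i], size = nrow(sub),
      n_membranous = sum(sub$ecad_pattern == "membranous"),
      n_mixed = sum(sub$ecad_pattern == "mixed"),
      n_cytoplasmic = sum(sub$ecad_pattern == "cytoplasmic")))
  }
  out[order(out$patient_id, out$cluster_id, out$field_id), ]
}

# explicit Breslow partial log-likelihood, written independently of the
# package internals (plain R loop over event times)
breslow_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# 1-D maximizer of the Breslow partial likelihood by coarse grid followed by
# golden-section refinement
golden_cox_1d <- function(x, time, event, lower = -5, upper = 5, tol = 1e-9) {
  f <- function(b) -breslow_loglik(b, cbind(x), time, event)
  grid <- seq(lower, upper, length.out = 401)
  b0 <- grid[which.min(vapply(grid, f, numeric(1)))]
  optimize(f, interval = c(b0 - 0.1, b0 + 0.1), tol = tol)$minimum
}

# penalized objective on the standardized scale used by the path solver:
# -loglik/n + lambda * sum(alpha|b| + (1-alpha) b^2 / 2)
coxnet_objective <- function(beta_std, Xs, time, event, lambda, alpha = 1) {
  -breslow_loglik(beta_std, Xs, time, event) / nrow(Xs) +
    lambda * sum(alpha * abs(beta_std) + (1 - alpha) * beta_std^2 / 2)
}

standardize_cols <- function(X) {
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  list(Xs = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# random right-censored survival fixture with a known signal column
random_surv_fixture <- function(n, p, beta, seed, base = 0.05, cmax = 40) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  tt <- rexp(n, base * exp(drop(X %*% beta)))
  cens <- runif(n, 1, cmax)
  list(X = X, time = pmin(tt, cens), event = as.integer(tt <= cens))
}
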