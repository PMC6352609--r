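# shared fixtures: small SPD matrices, toy epoch sets, constructed sessions

random_spd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  regularize_spd(crossprod(A) / p + diag(0.1, p)) * scale
}

# epochs drawn from a zero-mean Gaussian with a given spatial covariance
gaussian_epochs <- function(sigmas_by_class, n_per_class, T_ = 200, fs = 256) {
  C <- nrow(sigmas_by_class[[1]])
  n <- n_per_class * length(sigmas_by_class)
  data <- array(0, c(n, C, T_))
  labels <- character(n)
  i <- 0
  for (cl in names(sigmas_by_class)) {
    L <- chol(sigmas_by_class[[cl]])
    for (k in seq_len(n_per_class)) {
      i <- i + 1
      data[i, , ] <- t(L) %*% matrix(rnorm(C * T_), C, T_)
      labels[i] <- cl
    }
  }
  epoch_set(data, labels, fs, paste0("ch", seq_len(C)))
}

cov_set_of <- function(covs, labels)
  structure(list(covs = covs, labels = as.character(labels)), class = "cov_set")

# deterministic session: given channel signals and a regular trial protocol
protocol_events <- function(n_trials, t_rest = 6, t_warn = 2, t_kmi = 4, iti = 2, lead = 1) {
  red <- lead + (seq_len(n_trials) - 1) * (t_rest + t_warn + t_kmi + iti)
  data.frame(onset_s = c(rbind(red, red + t_rest, red + t_rest + t_warn)),
             code = rep(c("RED", "ORANGE", "GREEN"), n_trials))
}

# reduced montage around the motor strip (plus EMG) for fast simulations
small_montage <- c("FC3", "C5", "C3", "C1", "Cz", "CP3", "CP1", "P3", "O1", "C4")

# profile with forced ground-truth ERD parameters
forced_profile <- function(cfg, mu = 0, beta = 0, rebound = 0) {
  p <- generate_profile(cfg)
  p$erd_mu_depth <- mu
  p$erd_beta_depth <- beta
  p$rebound_gain <- rebound
  p
}
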