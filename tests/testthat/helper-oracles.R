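# Independent oracles, kept deliberately naive: direct arithmetic on
# printed counts and brute-force likelihood maximization.  They share no
# code with the package internals they check.

# Contingency oracle for one binary covariate.  `n` is a named vector of
# the eight E x C x D cell counts, names like "e1c0d1".
bross_oracle <- function(n) {
  cell <- function(e, c, d) n[[paste0("e", e, "c", c, "d", d)]]
  n_e1 <- sum(sapply(0:1, function(c) sapply(0:1, function(d) cell(1, c, d))))
  n_e0 <- sum(sapply(0:1, function(c) sapply(0:1, function(d) cell(0, c, d))))
  n_e1c1 <- cell(1, 1, 0) + cell(1, 1, 1)
  n_e0c1 <- cell(0, 1, 0) + cell(0, 1, 1)
  P_C1 <- n_e1c1 / n_e1
  P_C0 <- n_e0c1 / n_e0
  RR_CE <- P_C1 / P_C0
  # outcome RR among the unexposed
  risk_c1 <- cell(0, 1, 1) / n_e0c1
  risk_c0 <- cell(0, 0, 1) / (n_e0 - n_e0c1)
  RR_CD <- risk_c1 / risk_c0
  rr <- if (RR_CD < 1) 1 / RR_CD else RR_CD
  bias <- (P_C1 * (rr - 1) + 1) / (P_C0 * (rr - 1) + 1)
  list(P_C1 = P_C1, P_C0 = P_C0, RR_CE = RR_CE, RR_CD = RR_CD,
       bias_mult = bias, abs_log_bias = abs(log(bias)))
}

# Expand cell counts into patient-level vectors.
cells_to_vectors <- function(n) {
  e <- c(); cc <- c(); d <- c()
  for (ei in 0:1) for (ci in 0:1) for (di in 0:1) {
    k <- n[[paste0("e", ei, "c", ci, "d", di)]]
    e <- c(e, rep(ei, k)); cc <- c(cc, rep(ci, k)); d <- c(d, rep(di, k))
  }
  list(exposure = e, covariate = cc, outcome = d)
}

# Weighted Cox partial log-likelihood (Breslow form; exact when event
# times are distinct) maximized by golden-section search.
cox_oracle_loghr <- function(time, event, x, w) {
  nll <- function(b) {
    val <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      val <- val - w[i] * (b * x[i] - log(sum(w[risk] * exp(b * x[risk]))))
    }
    val
  }
  stats::optimize(nll, c(-8, 8), tol = 1e-10)$minimum
}
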