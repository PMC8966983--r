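# Independent oracles used across tests; kept deliberately naive.

# brute-force Benjamini-Hochberg step-up: walk the sorted p-values from the
# largest down, taking the running minimum of p * m / rank
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  adj
}

# Spearman rho from first principles: Pearson correlation of average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# pooled-variance two-sample t from the closed form
student_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# noise-free dose-response curve from known Hill parameters
make_hill_curve <- function(ic50, slope = 1, e0 = 1, e_inf = 0,
                            top = 10, n = 13, dilution = 3,
                            noise_sd = 0, drug = "d", line = "l") {
  s <- build_single_agent_series(drug, top, n, dilution)
  v <- hill_viability(s$concentrations, ic50, slope, e0, e_inf)
  if (noise_sd > 0) v <- pmax(0, v + rnorm(length(v), 0, noise_sd))
  dose_response_curve(drug, line, s$concentrations, v)
}

# a small complete 7x7 well table for one drug pair, from a viability matrix
wells_from_matrix <- function(doses_a, doses_b, viab, drug_a = "A", drug_b = "B",
                              scale = 2) {
  grid <- expand.grid(ia = seq_along(doses_a), ib = seq_along(doses_b))
  data.frame(
    plate_id = "p1",
    well = paste0("A", seq_len(nrow(grid))),
    row = "A", col = seq_len(nrow(grid)),
    drug_a = ifelse(doses_a[grid$ia] > 0, drug_a, NA_character_),
    conc_a = doses_a[grid$ia],
    drug_b = ifelse(doses_b[grid$ib] > 0, drug_b, NA_character_),
    conc_b = doses_b[grid$ib],
    raw_signal = scale * viab[cbind(grid$ia, grid$ib)],
    is_control = doses_a[grid$ia] == 0 & doses_b[grid$ib] == 0,
    viability = viab[cbind(grid$ia, grid$ib)],
    stringsAsFactors = FALSE
  )
}
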