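# Independent oracles used to check the package's statistics and
# predictions. Deliberately naive implementations (streaming updates,
# element-wise loops, explicit formulas) kept separate from the code paths
# they verify.

# Welford streaming moments: mean, sample sd (n-1), min, max
oracle_moments <- function(x) {
  n <- 0; mean <- 0; m2 <- 0; mn <- Inf; mx <- -Inf
  for (xi in x) {
    n <- n + 1
    d <- xi - mean
    mean <- mean + d / n
    m2 <- m2 + d * (xi - mean)
    mn <- min(mn, xi); mx <- max(mx, xi)
  }
  c(mean = mean, sd = if (n > 1) sqrt(m2 / (n - 1)) else NA_real_,
    min = mn, max = mx)
}

oracle_rmsep <- function(obs, pred) {
  acc <- 0
  for (i in seq_along(obs)) acc <- acc + (obs[i] - pred[i])^2
  sqrt(acc / length(obs))
}

oracle_pop_moments <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / length(x)
  list(mean = m, var = v)
}

oracle_ccc <- function(obs, pred) {
  o <- oracle_pop_moments(obs); p <- oracle_pop_moments(pred)
  sxy <- sum((obs - o$mean) * (pred - p$mean)) / length(obs)
  2 * sxy / (o$var + p$var + (o$mean - p$mean)^2)
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_msep_components <- function(obs, pred) {
  o <- oracle_pop_moments(obs); p <- oracle_pop_moments(pred)
  r <- oracle_pearson(obs, pred)
  c(ect = (p$mean - o$mean)^2,
    er = (sqrt(p$var) - r * sqrt(o$var))^2,
    ed = (1 - r^2) * o$var)
}

# explicit per-form prediction formulas (coefficients in design order)
oracle_predict <- function(form_id, data, coefs) {
  a <- data$acetate; p <- data$propionate; b <- data$butyrate
  switch(form_id,
    M1c = 16 * (0.50 * a - 0.25 * p + 0.50 * b) * coefs[1] / 100,
    M2 = coefs[1] * a - coefs[2] * p + coefs[3] * b,
    M3 = coefs[1] * (a / p) + coefs[2],
    M4 = coefs[1] * (a + b) / p + coefs[2],
    M5 = coefs[1] * p + coefs[2],
    M6 = coefs[1] * data$propionate_conc + coefs[2],
    M7 = coefs[1] / p + coefs[2],
    stop("bad form")
  )
}

# ordinary least squares via the normal equations
oracle_ols <- function(x, y) {
  drop(solve(t(x) %*% x, t(x) %*% y))
}

# random valid profiles (uniform over a comfortably interior box)
random_profiles <- function(n) {
  tibble::tibble(
    acetate = runif(n, 52, 70),
    propionate = runif(n, 13, 28),
    butyrate = runif(n, 1, 15),
    propionate_conc = runif(n, 10, 40)
  ) -> d
  # keep closure: shrink any profile whose sum exceeds 100
  s <- d$acetate + d$propionate + d$butyrate
  over <- s > 99
  d[over, c("acetate", "propionate", "butyrate")] <-
    d[over, c("acetate", "propionate", "butyrate")] * 99 / s[over]
  d
}

# small valid dataset around the development-data means
toy_dataset <- function(n_exp = 2, n_trt = 2, n_cow = 3, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(e = seq_len(n_exp), t = seq_len(n_trt),
                      c = seq_len(n_cow))
  prof <- random_profiles(nrow(grid))
  tibble::tibble(
    experiment_id = paste0("E", grid$e),
    treatment_id = paste0("T", grid$t),
    cow_id = paste0("C", grid$c),
    acetate = prof$acetate,
    propionate = prof$propionate,
    butyrate = prof$butyrate,
    methane_yield = pmax(3.28 * (prof$acetate + prof$butyrate) /
                           prof$propionate + 7.6 + rnorm(nrow(grid), 0, 2), 3)
  )
}
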