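# Straight-line arithmetic oracle for the four disproportionality statistics,
# written independently of the package's vectorized implementation: scalar
# input, explicit formulas, same Haldane rule for zero cells.
oracle_stats <- function(a, b, c, d) {
  a <- as.double(a)
  b <- as.double(b)
  c <- as.double(c)
  d <- as.double(d)
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + 0.5
    b <- b + 0.5
    c <- c + 0.5
    d <- d + 0.5
  }
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- ((a * d - b * c)^2 * N) / ((a + b) * (c + d) * (a + c) * (b + d))
  obs_exp <- a * N / ((a + c) * (a + b))
  ic <- log(obs_exp) / log(2)
  vic <- (1 / log(2))^2 * (1 / a - 1 / (a + b) - 1 / (a + c) + 1 / N)
  vic <- max(vic, 0)
  c(ror = ror, ror_low = ror * exp(-1.96 * se),
    ror_high = ror * exp(1.96 * se),
    prr = prr, chi2 = chi2,
    ic = ic, ic025 = ic - 2 * sqrt(vic),
    ebgm = obs_exp, ebgm05 = exp(log(obs_exp) - 1.96 * se))
}

random_tables <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      event_label = paste0("pt", seq_len(n)), level = "PT",
      a = sample(0:80, n, replace = TRUE),
      b = sample(1:500, n, replace = TRUE),
      c = sample(0:2000, n, replace = TRUE),
      d = sample(100:50000, n, replace = TRUE))
  })
}
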