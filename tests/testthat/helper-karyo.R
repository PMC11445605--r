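# Shared fixtures and independent oracles for the test suite.

# Toy plates used throughout (normalized orientation, ploidy 2).
toy_symmetric <- tibble::tibble(
  long_arm = c(2, 2, 2, 2), short_arm = c(2, 2, 2, 2)
)
toy_mixed <- tibble::tibble(
  long_arm = c(3, 3, 2, 2), short_arm = c(1, 1, 2, 2)
)
toy_asym <- tibble::tibble(
  long_arm = c(4, 4, 3, 3), short_arm = c(2, 2, 1, 1)
)

# Independent direct-summation oracle for the plate descriptors: explicit
# loops and textbook formulas, no shared code with the package internals.
oracle_params <- function(long, short, ploidy = 2) {
  n <- length(long)
  cl <- numeric(n); ci <- numeric(n); ca <- numeric(n)
  for (i in seq_len(n)) {
    cl[i] <- long[i] + short[i]
    ci[i] <- short[i] / cl[i]
    ca[i] <- 100 * (long[i] - short[i]) / cl[i]
  }
  samp_sd <- function(x) {
    m <- sum(x) / length(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
  }
  list(
    THL = sum(cl) / ploidy,
    M_CA = sum(ca) / n,
    CV_CL = 100 * samp_sd(cl) / (sum(cl) / n),
    CV_CI = 100 * samp_sd(ci) / (sum(ci) / n)
  )
}

# Random plate in normalized orientation.
rand_plate <- function(n = 8) {
  cl <- runif(n, 1, 10)
  ci <- runif(n, 0.05, 0.5)
  tibble::tibble(long_arm = cl * (1 - ci), short_arm = cl * ci)
}

# Pearson r/p oracle by explicit product-moment sums + t transform;
# cross-checked against stats::cor.test where used.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  r <- sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

expect_params_equal <- function(got, want, tol = 1e-9) {
  for (trait in c("THL", "M_CA", "CV_CL", "CV_CI")) {
    expect_equal(got[[trait]], want[[trait]], tolerance = tol,
                 label = paste0("trait ", trait))
  }
}
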