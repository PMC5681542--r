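# Shared fixtures: hand-built networks, random linear-Gaussian data with a
# known generating structure, and independent textbook oracles.

# A -> B -> C chain with configurable slopes and residual sd.
chain_net <- function(b1 = 5, b2 = 5, sd = 1) {
  gbn_network(list(
    A = list(intercept = 0, coefficients = numeric(0), residual_sd = 1),
    B = list(intercept = 0, coefficients = c(A = b1), residual_sd = sd),
    C = list(intercept = 0, coefficients = c(B = b2), residual_sd = sd)
  ))
}

# Random DAG + linear-Gaussian parameters over N generic nodes.
rand_net <- function(seed, N = 6, p_arc = 0.4) {
  set.seed(seed)
  nodes <- paste0("X", seq_len(N))
  locals <- list()
  for (i in seq_len(N)) {
    pa <- nodes[seq_len(i - 1L)][stats::runif(i - 1L) < p_arc]
    beta <- stats::setNames(
      stats::runif(length(pa), 0.5, 2) *
        sample(c(-1, 1), length(pa), replace = TRUE), pa)
    locals[[nodes[i]]] <- list(intercept = stats::runif(1, -1, 1),
                               coefficients = beta,
                               residual_sd = stats::runif(1, 0.5, 1.5))
  }
  gbn_network(locals)
}

# Random linear-Gaussian dataset with its generating network attached.
rand_lingauss_data <- function(seed, N = 4, n = 500, p_arc = 0.5) {
  set.seed(seed)
  nodes <- paste0("X", seq_len(N))
  locals <- list()
  for (i in seq_len(N)) {
    pa <- nodes[seq_len(i - 1L)][stats::runif(i - 1L) < p_arc]
    beta <- stats::setNames(
      stats::runif(length(pa), 1, 5) *
        sample(c(-1, 1), length(pa), replace = TRUE), pa)
    locals[[nodes[i]]] <- list(intercept = 0, coefficients = beta,
                               residual_sd = 1)
  }
  net <- gbn_network(locals)
  data <- logic_sample(net, n, seed = seed + 1000L)
  attr(data, "truth") <- net
  data
}

# Textbook two-pass Pearson correlation (independent of pearson_r).
two_pass_cor <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

# Brute-force L1 threshold oracle: grid over candidate fractions of the
# ideal {0, 1} step CDF, integrating |F_hat - f| exactly over [0, 1].
l1_fraction_oracle <- function(strengths, grid = seq(0, 1, by = 1e-3)) {
  s <- sort(strengths)
  knots <- c(0, s, 1)
  widths <- diff(knots)
  levels <- seq(0, length(s)) / length(s)
  l1 <- vapply(grid, function(f) sum(widths * abs(levels - f)), numeric(1))
  grid[which.min(l1)]
}

# Cohort data frame builder for loader tests (two visits, wide layout).
make_cohort_df <- function(n = 3, seed = 1) {
  set.seed(seed)
  df <- data.frame(id = sprintf("P%02d", seq_len(n)),
                   treated = rep_len(c(1, 0), n))
  df$growth <- ifelse(df$treated == 1, NA_real_, 1)
  df$age_t1 <- 8 + seq_len(n) / 10
  df$age_t2 <- df$age_t1 + 6
  for (f in ceph_features()) {
    df[[paste0(f, "_t1")]] <- round(stats::rnorm(n, 50, 5), 1)
    df[[paste0(f, "_t2")]] <- df[[paste0(f, "_t1")]] + round(stats::rnorm(n), 1)
  }
  df
}

as_cohort_file <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
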