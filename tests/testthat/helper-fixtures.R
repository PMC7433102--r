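# Shared fixtures and independent oracles, all built in code.

# star phylogeny with unit branches (independence limit)
star_tree <- function(n) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

# small complete synthetic study, memoised per option set within a test file
small_study <- function(seed = 7, n_species = 30, n_years = 6, grid = 10,
                        ...) {
  simulate_study(sim_config(n_species = n_species, n_years = n_years,
                            grid_rows = grid, grid_cols = grid,
                            n_families = 6, seed = seed, ...))
}

# --- independent brute-force oracles for the window statistics -------------

oracle_range_series <- function(arr, mask) {
  ny <- dim(arr)[1]
  out <- matrix(0, ny, 12)
  for (y in seq_len(ny)) for (m in 1:12) {
    vals <- numeric(0)
    for (i in seq_len(nrow(mask)))
      vals <- c(vals, arr[y, m, mask[i, 1], mask[i, 2]])
    out[y, m] <- mean(vals)
  }
  out
}

oracle_months <- function(start, len) ((start - 1 + seq_len(len) - 1) %% 12) + 1

oracle_median <- function(series, months) {
  pool <- numeric(0)
  for (y in seq_len(nrow(series))) for (m in months)
    pool <- c(pool, series[y, m])
  pool <- sort(pool)
  n <- length(pool)
  if (n %% 2 == 1) pool[(n + 1) / 2] else mean(pool[n / 2 + c(0, 1)])
}

# two-pass sample variance, written independently of stats::var
oracle_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

oracle_seasonality <- function(series, months) {
  if (length(months) == 1) return(0)
  vs <- numeric(nrow(series))
  for (y in seq_len(nrow(series))) vs[y] <- oracle_var(series[y, months])
  mean(vs)
}

oracle_interannual <- function(series, months) {
  vs <- numeric(length(months))
  for (i in seq_along(months)) vs[i] <- oracle_var(series[, months[i]])
  mean(vs)
}

# direct Firth-penalized logistic log-likelihood maximization (independent
# oracle for the star-tree reduction of the phylogenetic logistic fit)
oracle_firth_logistic <- function(y, X) {
  pll <- function(b) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    sum(y * eta - log(1 + exp(eta))) +
      0.5 * determinant(crossprod(X * W, X))$modulus
  }
  o <- stats::optim(rep(0, ncol(X)), function(b) -pll(b), method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 2000))
  o$par
}

# chain data simulated under hypothesis A: sds -> temp -> length, OU noise
simulate_hypothesis_a <- function(tree, b_temp = 1.5, b_len = 1,
                                  ou_alpha = 2, dist = NULL) {
  mk <- simulate_binary_mk(tree, c(1, 1) / sdsclim:::.tree_depth(tree))
  s <- as.numeric(mk$states)
  if (length(unique(s)) < 2) s[sample(length(s), 2)] <- c(0, 1)
  temp <- b_temp * s + as.numeric(simulate_ou_trait(tree, ou_alpha, 1))
  len <- b_len * temp + as.numeric(simulate_ou_trait(tree, ou_alpha, 1))
  data.frame(sds = s, temp = temp, length = len,
             row.names = tree$tip.label)
}
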