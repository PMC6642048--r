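# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# textbook centered-sum Pearson correlation on pairwise-complete entries
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  dx <- x - sum(x) / n
  dy <- y - sum(y) / n
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

# quadratic-time enrichment score oracle: every prefix sum recomputed from
# scratch; extreme-deviation ties resolve toward the positive side
oracle_es <- function(scores, hit, p) {
  n <- length(scores)
  nh <- sum(hit)
  nr <- sum(abs(scores[hit])^p)
  steps <- ifelse(hit, abs(scores)^p / nr, -1 / (n - nh))
  run <- vapply(seq_len(n), function(i) sum(steps[seq_len(i)]), 0)
  pos <- max(run); neg <- min(run)
  if (pos >= -neg) pos else neg
}

# full-enumeration two-sided Mann-Whitney p (tie-free samples)
oracle_mwu_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu))
}

# normal-equations OLS oracle
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       residuals = as.numeric(res))
}

# small deterministic cohort for io/coexpression tests
tiny_cohort <- function(seed = 42, genes = 6, samples = 10,
                        label = "TST") {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples), genes,
              dimnames = list(paste0("G", seq_len(genes)),
                              paste0("S", seq_len(samples))))
  expression_cohort(m, label)
}
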