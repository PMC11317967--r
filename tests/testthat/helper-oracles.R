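# Independent oracles, deliberately coded from first principles and kept
# separate from the package implementation paths they check.

# Binomial-logit GLM by hand-rolled iteratively reweighted least squares.
# X: design matrix; alt/ref: per-observation success/failure counts.
oracle_irls_binom <- function(X, alt, ref, tol = 1e-12, maxit = 200) {
  n <- alt + ref
  y <- alt / n
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- n * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  xlogy <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  dev <- 2 * sum(n * (xlogy(y, mu) + xlogy(1 - y, 1 - mu)))
  list(beta = beta, deviance = dev)
}

# LRT p for the group term via the IRLS oracle
oracle_glm_lrt <- function(alt, ref, group) {
  group <- factor(group)
  X_full <- stats::model.matrix(~group)
  X_null <- X_full[, 1, drop = FALSE]
  d_full <- oracle_irls_binom(X_full, alt, ref)$deviance
  d_null <- oracle_irls_binom(X_null, alt, ref)$deviance
  stat <- d_null - d_full
  list(
    p = stats::pchisq(max(stat, 0), df = nlevels(group) - 1, lower.tail = FALSE),
    deviance_full = d_full, deviance_null = d_null
  )
}

# Two-sided Fisher exact p for a 2 x K table by full enumeration of all
# tables with the observed margins; p = sum of probabilities of tables no
# more probable than the observed one (the standard definition).
oracle_fisher_enum <- function(tab) {
  stopifnot(nrow(tab) == 2, ncol(tab) %in% c(2, 3))
  row1 <- sum(tab[1, ])
  colt <- colSums(tab)
  N <- sum(tab)
  log_prob <- function(cells) {
    # cells: first-row entries; hypergeometric probability of the table
    sum(lchoose(colt, cells)) - lchoose(N, row1)
  }
  obs <- log_prob(tab[1, ])
  total <- 0
  if (ncol(tab) == 2) {
    for (a in max(0, row1 - colt[2]):min(row1, colt[1])) {
      lp <- log_prob(c(a, row1 - a))
      if (lp <= obs + 1e-7) total <- total + exp(lp)
    }
  } else {
    for (a in 0:min(row1, colt[1])) {
      for (b in 0:min(row1 - a, colt[2])) {
        c3 <- row1 - a - b
        if (c3 < 0 || c3 > colt[3]) next
        lp <- log_prob(c(a, b, c3))
        if (lp <= obs + 1e-7) total <- total + exp(lp)
      }
    }
  }
  min(total, 1)
}

# All-pairs interval membership scan: 1-based site position p is inside the
# 0-based half-open [start, end) iff start <= p - 1 < end; first match in
# file order wins.
oracle_repeat_overlap <- function(sites, repeats) {
  vapply(seq_len(nrow(sites)), function(i) {
    hit <- which(repeats$chrom == sites$chrom[i] &
                   repeats$start <= sites$pos[i] - 1 &
                   sites$pos[i] - 1 < repeats$end)
    if (length(hit) == 0) NA_character_ else repeats$family[hit[1]]
  }, character(1))
}

# Step-up BH computed directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
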