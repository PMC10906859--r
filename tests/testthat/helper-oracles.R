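# Independent oracle implementations used to cross-check the package.
# These deliberately take the dumbest correct route (loops, enumeration)
# and share no code with the functions they check.

# Two-sided Fisher p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum the probabilities of all tables with the observed
# margins that are no more probable than the observed one.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-squared statistic by explicit double loop.
oracle_chisq_stat <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# Hosmer-Lemeshow statistic by explicit sorting and g-way splitting.
oracle_hl_stat <- function(p, y, g = 10) {
  ord <- order(p)
  p <- p[ord]; y <- y[ord]
  br <- quantile(p, probs = seq(0, 1, length.out = g + 1), type = 7)
  bin <- cut(p, breaks = unique(br), include.lowest = TRUE)
  stat <- 0
  for (b in levels(bin)) {
    sel <- bin == b
    o1 <- sum(y[sel]); e1 <- sum(p[sel])
    o0 <- sum(!y[sel]); e0 <- sum(1 - p[sel])
    stat <- stat + (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0
  }
  stat
}

# Spearman correlation by explicit mid-ranking then Pearson.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Re-derive the three-stage exclusion filter independently.
oracle_exclusions <- function(records, required_vars) {
  mh <- mean(records$height); sh <- sd(records$height)
  mw <- mean(records$weight); sw <- sd(records$weight)
  out <- records$height < mh - 2 * sh | records$height > mh + 2 * sh |
    records$weight < mw - 2 * sw | records$weight > mw + 2 * sw
  keep <- records[!out, , drop = FALSE]
  keep <- keep[!keep$gender_raw %in% c("other", "unsure"), , drop = FALSE]
  miss <- apply(is.na(keep[, required_vars, drop = FALSE]), 1, any)
  keep[!miss, , drop = FALSE]
}

# Random valid 2x2 table without zero cells, bounded total.
random_2x2 <- function(max_cell = 40) {
  matrix(sample.int(max_cell, 4, replace = TRUE), 2, 2)
}
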