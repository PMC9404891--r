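# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or closed form, never through the package's own
# code paths.

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments of the pooled sample.
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  pl <- mean(us <= u_obs + 1e-9)
  pg <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(pl, pg)))
}

# Spearman rho from the direct midrank formula (Pearson product-moment on
# ranks, written out by hand).
spearman_formula_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# David's Score by hand from a win matrix (rows beat columns), Pij mode.
ds_matrix_oracle <- function(wins) {
  n <- nrow(wins)
  nij <- wins + t(wins)
  p <- matrix(0, n, n)
  p[nij > 0] <- wins[nij > 0] / nij[nij > 0]
  w <- rowSums(p)
  l <- colSums(p)
  w + as.numeric(p %*% w) - l - as.numeric(t(p) %*% l)
}

# tiny roster helper
tiny_roster <- function(ids, sex = NULL, matriline = NULL) {
  n <- length(ids)
  data.frame(id = ids,
             sex = if (is.null(sex)) rep("female", n) else sex,
             matriline = if (is.null(matriline)) rep(NA_character_, n) else matriline,
             stringsAsFactors = FALSE)
}

# proximity record helper
prox_rec <- function(focal, partner, session, dur, overlap) {
  data.frame(focal_id = focal, partner_id = partner, session_id = session,
             session_duration_s = dur, overlap_s = overlap,
             stringsAsFactors = FALSE)
}
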