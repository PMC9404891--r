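#' Dyadic association index (DAI) matrix
#'
#' For each unordered pair of individuals (a, b), `DAI = D_ab / (D_a + D_b -
#' D_ab)`, where `D_ab` is the total duration the two spent within 1 m
#' (summed across all focal sessions of either individual) and `D_a`, `D_b`
#' are each individual's total focal sampling duration. A Jaccard-style index
#' in \[0, 1\]. Pairs with a non-positive denominator get 1 if any proximity
#' was observed and 0 otherwise (the limit of the index); values are clamped
#' to \[0, 1\]. The diagonal is fixed at 0.
#'
#' @param records data.frame of proximity records with columns `focal_id`,
#'   `partner_id`, `session_id`, `session_duration_s`, `overlap_s`.
#' @param roster data.frame with at least an `id` column giving the ordering
#'   of individuals in the output matrix.
#' @return A symmetric numeric matrix (class `dai_matrix`) with dimnames =
#'   roster ids.
#' @export
compute_dai <- function(records, roster) {
  ids <- as.character(roster$id)
  rec_ids <- unique(c(as.character(records$focal_id),
                      as.character(records$partner_id)))
  unknown <- setdiff(rec_ids, ids)
  if (length(unknown) > 0) {
    stop("proximity records mention ids not in roster: ",
         paste(unknown, collapse = ", "))
  }
  if (any(records$overlap_s < 0) || any(records$session_duration_s < 0)) {
    stop("negative durations in proximity records")
  }
  if (any(records$overlap_s > records$session_duration_s + 1e-9)) {
    stop("overlap_s exceeds session_duration_s in proximity records")
  }
  n <- length(ids)
  # D_a: each focal's total sampling time, one contribution per focal session
  ses <- unique(records[, c("focal_id", "session_id", "session_duration_s")])
  d_tot <- tapply(ses$session_duration_s, factor(ses$focal_id, levels = ids), sum)
  d_tot[is.na(d_tot)] <- 0
  # D_ab: overlap summed across all sessions, from either focal's records
  i <- match(as.character(records$focal_id), ids)
  j <- match(as.character(records$partner_id), ids)
  if (any(i == j)) stop("proximity record with focal == partner")
  lo <- pmin(i, j); hi <- pmax(i, j)
  dab <- matrix(0, n, n, dimnames = list(ids, ids))
  agg <- tapply(records$overlap_s, list(factor(lo, 1:n), factor(hi, 1:n)), sum)
  agg[is.na(agg)] <- 0
  dab[upper.tri(dab)] <- agg[upper.tri(agg)]
  dab <- dab + t(dab)
  denom <- outer(as.numeric(d_tot), as.numeric(d_tot), "+") - dab
  dai <- ifelse(denom > 0, dab / denom, ifelse(dab > 0, 1, 0))
  dai <- pmin(pmax(dai, 0), 1)
  diag(dai) <- 0
  dimnames(dai) <- list(ids, ids)
  class(dai) <- c("dai_matrix", class(dai))
  dai
}

#' Eigenvector centrality by power iteration
#'
#' Computes the leading eigenvector of a symmetric nonnegative association
#' matrix by power iteration started from the uniform vector on the largest
#' connected component. Individuals outside that component (including
#' zero-degree individuals) receive score 0. The returned vector has unit
#' Euclidean norm.
#'
#' @param m symmetric nonnegative matrix (e.g. a [compute_dai()] result).
#' @param tol convergence tolerance: max-norm change between successive
#'   normalized iterates.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return Named numeric vector of centrality scores, with attributes
#'   `eigenvalue` (Rayleigh quotient) and `iterations`.
#' @export
eigenvector_centrality <- function(m, tol = 1e-12, max_iter = 10000L) {
  m <- unclass(as.matrix(m))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) stop("matrix must be symmetric")
  if (any(m < 0)) stop("matrix must be nonnegative")
  if (all(m == 0)) stop("all-zero association matrix: centrality undefined")
  n <- nrow(m)
  ids <- rownames(m)
  # largest connected component over nonzero edges
  adj <- m > 0
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L || !any(adj[s, ])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  keep <- which(comp == which.max(sizes))
  a <- m[keep, keep, drop = FALSE]
  # positive diagonal shift: leaves the Perron vector unchanged but breaks the
  # |lambda_min| = lambda_max degeneracy of bipartite graphs, where unshifted
  # power iteration oscillates forever
  shift <- max(rowSums(a)) / 2
  b <- a + diag(shift, nrow(a))
  x <- rep(1 / sqrt(length(keep)), length(keep))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    y <- as.numeric(b %*% x)
    y <- y / sqrt(sum(y^2))
    delta <- max(abs(y - x))
    x <- y
    if (delta < tol) break
    if (iter >= max_iter) {
      stop(sprintf(paste0("power iteration did not converge in %d iterations ",
                          "(last max-norm change %.3e)"),
                   max_iter, delta))
    }
  }
  lambda <- as.numeric(x %*% a %*% x)
  scores <- numeric(n)
  scores[keep] <- x
  names(scores) <- ids
  attr(scores, "eigenvalue") <- lambda
  attr(scores, "iterations") <- iter
  scores
}

#' David's Score dominance ranking
#'
#' From dyadic agonistic outcomes, computes David's Score `DS_i = w_i + w2_i -
#' l_i - l2_i`, where `w_i` is the sum over opponents j of i's win proportion
#' `P_ij`, `w2_i` weights each opponent's `w_j` by `P_ij`, and `l`, `l2` are
#' the mirror-image loss terms. A larger DS means a higher rank. Two win
#' proportion conventions are offered: `"pij"` uses the raw `P_ij = s_ij /
#' n_ij` (0 when the dyad never interacted), `"dij"` the chance-corrected
#' `P_ij - (P_ij - 0.5) / (n_ij + 1)` for interacting dyads.
#'
#' @param bouts data.frame with columns `actor_id`, `receiver_id`; each row is
#'   one decided bout won by the actor (the receiver showed submission).
#' @param roster data.frame with an `id` column.
#' @param correction `"pij"` or `"dij"`.
#' @return data.frame (class `dominance_result`) with columns `id`, `ds`,
#'   `rank` (1 = highest DS; ties broken by id order in the roster).
#' @export
davids_score <- function(bouts, roster, correction = c("pij", "dij")) {
  correction <- match.arg(correction)
  ids <- as.character(roster$id)
  n <- length(ids)
  if (n == 0) stop("empty roster")
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(bouts) > 0) {
    a <- match(as.character(bouts$actor_id), ids)
    r <- match(as.character(bouts$receiver_id), ids)
    if (anyNA(a) || anyNA(r)) {
      bad <- unique(c(as.character(bouts$actor_id)[is.na(a)],
                      as.character(bouts$receiver_id)[is.na(r)]))
      stop("agonistic bouts mention ids not in roster: ",
           paste(bad, collapse = ", "))
    }
    if (any(a == r)) stop("bout with actor == receiver")
    for (kk in seq_along(a)) s[a[kk], r[kk]] <- s[a[kk], r[kk]] + 1
  }
  nij <- s + t(s)
  p <- matrix(0, n, n)
  inter <- nij > 0
  p[inter] <- s[inter] / nij[inter]
  if (correction == "dij") {
    p[inter] <- p[inter] - (p[inter] - 0.5) / (nij[inter] + 1)
  }
  diag(p) <- 0
  w <- rowSums(p)
  l <- colSums(p)
  w2 <- as.numeric(p %*% w)
  l2 <- as.numeric(t(p) %*% l)
  ds <- w + w2 - l - l2
  rank_order <- order(-ds, seq_len(n))
  rk <- integer(n)
  rk[rank_order] <- seq_len(n)
  out <- data.frame(id = ids, ds = ds, rank = rk, stringsAsFactors = FALSE)
  class(out) <- c("dominance_result", class(out))
  out
}

#' Matrilineal relative counts
#'
#' Each individual's number of relatives is the size of its matriline among
#' group members minus one; individuals without a matriline (immigrant males)
#' count 0.
#'
#' @param roster data.frame with columns `id` and `matriline` (`NA` or `""`
#'   for none).
#' @return Named integer vector of relative counts.
#' @export
count_relatives <- function(roster) {
  mat <- as.character(roster$matriline)
  mat[is.na(mat) | mat == ""] <- NA_character_
  sizes <- table(mat)
  out <- ifelse(is.na(mat), 0L, as.integer(sizes[mat]) - 1L)
  names(out) <- as.character(roster$id)
  out
}
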