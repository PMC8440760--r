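# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# Exhaustive pair enumeration for the grey-level co-occurrence matrix.
glcm_oracle <- function(q, levels, angle, offset, normalise = TRUE) {
  d <- switch(as.character(angle),
              "0" = c(0, offset), "45" = c(-offset, offset),
              "90" = c(-offset, 0), "135" = c(-offset, -offset))
  P <- matrix(0L, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, c] + 1, q[r2, c2] + 1] <- P[q[r, c] + 1, q[r2, c2] + 1] + 1L
      }
    }
  }
  if (normalise && sum(P) > 0) P <- P / sum(P)
  P
}

# Nested-loop local range filter with replicated borders.
range_filter_oracle <- function(img, window) {
  k <- (window - 1) / 2
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rs <- pmin(pmax((r - k):(r + k), 1), H)
      cs <- pmin(pmax((c - k):(c + k), 1), W)
      v <- img[rs, cs]
      out[r, c] <- max(v) - min(v)
    }
  }
  out
}

# O(n^2) pairwise-comparison AUC.
auc_oracle <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Exhaustive scan for the FP/FN-balancing cutoff with the package's
# documented tie-breaking, re-derived independently.
cutoff_oracle <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  cand <- c(cand, max(cand) + 1)
  best <- NULL
  for (t in cand) {
    fp <- sum(neg >= t); fn <- sum(pos < t)
    key <- c(abs(fp - fn), fp + fn, t)
    if (is.null(best) || key[1] < best[1] ||
        (key[1] == best[1] && key[2] < best[2]) ||
        (key[1] == best[1] && key[2] == best[2] && key[3] < best[3])) {
      best <- key
    }
  }
  best[3]
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Maximum-cardinality one-to-one matching by exhaustive assignment over
# eligibility (annotation inside candidate mask or within tol of its
# centroid), for small instances only.
match_oracle_tp <- function(cands, ann, tol_px) {
  nc <- nrow(cands); na <- nrow(ann)
  if (nc == 0 || na == 0) return(0L)
  elig <- matrix(FALSE, nc, na)
  for (i in seq_len(nc)) {
    for (j in seq_len(na)) {
      arow <- round(ann$y[j]) + 1; acol <- round(ann$x[j]) + 1
      inside <- arow >= cands$row0[i] && arow <= cands$row1[i] &&
        acol >= cands$col0[i] && acol <= cands$col1[i] &&
        cands$mask[[i]][arow - cands$row0[i] + 1, acol - cands$col0[i] + 1]
      d <- sqrt((cands$centroid_row[i] - arow)^2 +
                (cands$centroid_col[i] - acol)^2)
      elig[i, j] <- inside || d <= tol_px
    }
  }
  best <- 0L
  recurse <- function(j, used) {
    if (j > na) return(0L)
    skip <- recurse(j + 1, used)
    take <- 0L
    for (i in seq_len(nc)) {
      if (!used[i] && elig[i, j]) {
        used2 <- used; used2[i] <- TRUE
        take <- max(take, 1L + recurse(j + 1, used2))
      }
    }
    max(skip, take)
  }
  recurse(1, logical(nc))
}
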