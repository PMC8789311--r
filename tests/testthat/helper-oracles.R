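# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive enumeration (explicit branch
# interval lists, pairwise loops) rather than the package's own code paths.

# explicit branch-interval enumeration: a branch spans [child time, parent
# time); the root lineage persists above the root time
oracleBranchIntervals <- function(tree) {
  kids <- which(tree@parent != 0L)
  data.frame(node = kids,
             lo = tree@times[kids],
             hi = tree@times[tree@parent[kids]])
}

oracleCountLineages <- function(tree, t) {
  root <- which(tree@parent == 0L)
  if (t >= tree@times[root]) return(1L)
  iv <- oracleBranchIntervals(tree)
  sum(iv$lo <= t & t < iv$hi)
}

# leaves under a node by explicit descent
oracleLeafSet <- function(tree, node) {
  n <- length(tree@labels)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v <= n) out <- c(out, v)
    stack <- c(stack, which(tree@parent == v))
  }
  sort(out)
}

oracleClassify <- function(tree, carriers, t) {
  root <- which(tree@parent == 0L)
  if (t >= tree@times[root]) return(c(anc = 1L, der = 0L))
  iv <- oracleBranchIntervals(tree)
  act <- iv$node[iv$lo <= t & t < iv$hi]
  der <- sum(vapply(act, function(v) {
    ls <- oracleLeafSet(tree, v)
    length(ls) <= length(carriers) && all(ls %in% carriers)
  }, logical(1)))
  c(anc = length(act) - der, der = der)
}

# random coalescent genealogy via ape (independent of the package simulator)
randomCoalTree <- function(n, interval = c(0, 1)) {
  localTreeFromPhylo(ape::rcoal(n), interval = interval)
}

# a random clade-compatible carrier set (proper subset of the leaves)
randomCladeCarriers <- function(tree) {
  n <- length(tree@labels)
  nodes <- setdiff(seq_along(tree@parent), which(tree@parent == 0L))
  repeat {
    v <- sample(nodes, 1)
    ls <- oracleLeafSet(tree, v)
    if (length(ls) < n) return(ls)
  }
}

# ---- naive summary-statistic oracles (pairwise loops) ----

oraclePi <- function(m) {
  n <- nrow(m); tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}

oracleThetaW <- function(m) {
  cnt <- colSums(m); n <- nrow(m)
  sum(cnt > 0 & cnt < n) / sum(1 / seq_len(n - 1))
}

oracleThetaH <- function(m) {
  cnt <- colSums(m); n <- nrow(m)
  out <- 0
  for (i in 1:(n - 1)) out <- out + i^2 * sum(cnt == i) * 2 / (n * (n - 1))
  out
}

oracleTajimaD <- function(m) {
  n <- nrow(m)
  cnt <- colSums(m)
  S <- sum(cnt > 0 & cnt < n)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (oraclePi(m) - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

oracleGarud <- function(m) {
  p <- sort(table(apply(m, 1, paste, collapse = "")) / nrow(m), decreasing = TRUE)
  p <- as.numeric(p)
  H1 <- sum(p^2)
  H12 <- (p[1] + ifelse(length(p) > 1, p[2], 0))^2 +
    if (length(p) > 2) sum(p[3:length(p)]^2) else 0
  list(H1 = H1, H12 = H12, H2H1 = (H1 - p[1]^2) / H1)
}

oracleR2 <- function(a, b) {
  pa <- mean(a); pb <- mean(b); pab <- mean(a & b)
  D <- pab - pa * pb
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den == 0) return(NA_real_)
  D^2 / den
}

oracleZns <- function(m) {
  cnt <- colSums(m); n <- nrow(m)
  seg <- which(cnt > 0 & cnt < n)
  if (length(seg) < 2) return(NA_real_)
  vals <- c()
  for (i in seq_along(seg)[-length(seg)])
    for (j in (i + 1):length(seg))
      vals <- c(vals, oracleR2(m[, seg[i]], m[, seg[j]]))
  mean(vals)
}

oracleOmegaMax <- function(m) {
  cnt <- colSums(m); n <- nrow(m)
  seg <- which(cnt > 0 & cnt < n)
  S <- length(seg)
  if (S < 3) return(NA_real_)
  r2 <- matrix(NA_real_, S, S)
  for (i in 1:S) for (j in 1:S) r2[i, j] <- oracleR2(m[, seg[i]], m[, seg[j]])
  best <- -Inf
  for (l in 1:(S - 1)) {
    wsum <- 0
    if (l >= 2) for (i in 1:(l - 1)) for (j in (i + 1):l) wsum <- wsum + r2[i, j]
    if (S - l >= 2) for (i in (l + 1):(S - 1)) for (j in (i + 1):S) wsum <- wsum + r2[i, j]
    xsum <- 0
    for (i in 1:l) for (j in (l + 1):S) xsum <- xsum + r2[i, j]
    nw <- choose(l, 2) + choose(S - l, 2)
    om <- (if (nw > 0) wsum / nw else 0) / (xsum / (l * (S - l)))
    if (!is.nan(om) && om > best) best <- om
  }
  if (best > -Inf) best else NA_real_
}

# explicit pairwise EHH and its bp integral for one allele class
oracleIhh <- function(m, pos, core, rows, trunc = 0.05) {
  g <- length(rows)
  if (g < 2) return(NA_real_)
  ehhAt <- function(jseq) {
    # identity over columns core..j for every pair, walking outward
    vals <- c(); lastx <- pos[core]; laste <- 1; integral <- 0
    cols <- c()
    for (j in jseq) {
      cols <- c(cols, j)
      same <- 0
      for (a in 1:(g - 1)) for (b in (a + 1):g)
        if (all(m[rows[a], cols] == m[rows[b], cols])) same <- same + 1
      e <- same / choose(g, 2)
      integral <- integral + (laste + e) / 2 * abs(pos[j] - lastx)
      laste <- e; lastx <- pos[j]
      if (e < trunc) break
    }
    integral
  }
  r <- if (core < ncol(m)) ehhAt((core + 1):ncol(m)) else 0
  l <- if (core > 1) ehhAt((core - 1):1) else 0
  r + l
}

oracleIhsSite <- function(m, pos, core, trunc = 0.05) {
  d <- which(m[, core] == 1); a <- which(m[, core] == 0)
  ihhD <- oracleIhh(m, pos, core, d, trunc)
  ihhA <- oracleIhh(m, pos, core, a, trunc)
  if (is.na(ihhD) || is.na(ihhA) || ihhD <= 0 || ihhA <= 0) return(NA_real_)
  log(ihhA / ihhD)
}

# exhaustive concordant-pair AUROC (ties count 1/2)
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
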