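# Brute-force reference implementations, kept deliberately naive (explicit
# loops, full sorts, threshold enumeration) and independent of the package's
# vectorised code paths.

oracle_knn <- function(S, k, symmetrize = TRUE) {
  n <- nrow(S)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # full sort of the row, ties by ascending index
    ord <- others[order(-S[i, others], others)]
    A[i, c(i, ord[seq_len(k)])] <- 1
  }
  if (symmetrize) A <- (A + t(A) > 0) * 1
  A
}

oracle_normalize <- function(A) {
  n <- nrow(A)
  out <- matrix(0, n, n)
  d <- rowSums(A)
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i, j] <- A[i, j] / sqrt(d[i] * d[j])
  out
}

# Feature GCN as an explicit per-layer dense product.
oracle_feature_gcn <- function(op, x, weights) {
  z <- x
  for (w in weights) z <- pmax(op %*% z %*% w, 0)
  z
}

# Edge-type message passing by explicit double loops over every pair.
# a1: binary n x m matrix of type-1 edges; tables/rounds as in the package.
oracle_message_passing <- function(a1, table0, table1, rounds_w = NULL,
                                   n_rounds = 1) {
  n <- nrow(a1); m <- ncol(a1)
  h <- ncol(table0)
  type_of <- function(i, j) if (a1[i, j] == 1) 1L else 0L
  deg_r <- function(i, t) sum(vapply(seq_len(m), function(j) type_of(i, j) == t, TRUE))
  deg_d <- function(j, t) sum(vapply(seq_len(n), function(i) type_of(i, j) == t, TRUE))
  drug_feat <- function(i, r, hr) if (r == 1) NULL else hr[i, ]
  hr <- NULL; hd <- NULL
  for (r in seq_len(n_rounds)) {
    new_hr <- matrix(0, n, h)
    for (i in seq_len(n)) {
      acc <- numeric(h)
      for (j in seq_len(m)) {
        t <- type_of(i, j)
        c_ij <- sqrt(deg_r(i, t) * deg_d(j, t))
        if (c_ij == 0) next
        xj <- if (r == 1) {
          if (t == 1) table1[n + j, ] else table0[n + j, ]
        } else {
          w <- if (t == 1) rounds_w[[r - 1]]$w1 else rounds_w[[r - 1]]$w0
          as.numeric(hd[j, ] %*% w)
        }
        acc <- acc + xj / c_ij
      }
      new_hr[i, ] <- tanh(acc)
    }
    new_hd <- matrix(0, m, h)
    for (j in seq_len(m)) {
      acc <- numeric(h)
      for (i in seq_len(n)) {
        t <- type_of(i, j)
        c_ij <- sqrt(deg_r(i, t) * deg_d(j, t))
        if (c_ij == 0) next
        xi <- if (r == 1) {
          if (t == 1) table1[i, ] else table0[i, ]
        } else {
          w <- if (t == 1) rounds_w[[r - 1]]$w1 else rounds_w[[r - 1]]$w0
          as.numeric(hr[i, ] %*% w)
        }
        acc <- acc + xi / c_ij
      }
      new_hd[j, ] <- tanh(acc)
    }
    hr <- new_hr; hd <- new_hd
  }
  list(drug = hr, disease = hd)
}

# Attention score per node by explicit loop.
oracle_attention_scores <- function(z, w, b, q) {
  vapply(seq_len(nrow(z)), function(i) {
    sum(q * tanh(as.numeric(w %*% z[i, ]) + b))
  }, numeric(1))
}

# Three-layer MLP per pair, scalar loops.
oracle_mlp_pair <- function(zr_i, zd_j, mlp) {
  x <- c(zr_i, zd_j)
  a1 <- pmax(as.numeric(x %*% mlp$W1) + mlp$b1, 0)
  a2 <- pmax(as.numeric(a1 %*% mlp$W2) + mlp$b2, 0)
  1 / (1 + exp(-(sum(a2 * mlp$w3) + mlp$b3)))
}

# Pairwise cosine similarity by explicit dot products.
oracle_cosine <- function(z) {
  n <- nrow(z)
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i, j] <- sum(z[i, ] * z[j, ]) /
        (sqrt(sum(z[i, ]^2)) * sqrt(sum(z[j, ]^2)))
  out
}

# AUROC by enumerating every positive-negative pair.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos)
    for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# AUPRC by enumerating all distinct thresholds.
oracle_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (th in ths) {
    sel <- scores >= th
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / sum(labels)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Strip container classes/attributes down to a bare unnamed matrix.
bare <- function(x) {
  x <- unclass(x)
  attr(x, "entity_kind") <- NULL
  unname(x)
}

# Small random dataset helper for property-style loops.
random_dataset <- function(n, m, seed, density = 0.25) {
  set.seed(seed)
  repeat {
    Y <- matrix(rbinom(n * m, 1, density), n, m)
    if (sum(Y) > 0 && sum(Y) < n * m) break
  }
  mk_sim <- function(k) {
    B <- matrix(runif(k * k), k, k)
    S <- (B + t(B)) / 2
    diag(S) <- 1
    S
  }
  list(drug_sim = similarity_matrix(mk_sim(n), entity_kind = "drug"),
       disease_sim = similarity_matrix(mk_sim(m), entity_kind = "disease"),
       assoc = association_matrix(Y))
}
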