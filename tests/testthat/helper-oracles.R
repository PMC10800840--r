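# Independent brute-force reference implementations. These deliberately share
# no code with the package: plain loops and direct formula transcriptions.

# betaMNTD by direct double loop over taxa.
oracle_bmntd <- function(counts, D, weighted = TRUE) {
  ns <- nrow(counts)
  out <- matrix(0, ns, ns)
  for (k in seq_len(ns - 1)) {
    for (l in (k + 1):ns) {
      xk <- counts[k, ]; xl <- counts[l, ]
      pk <- which(xk > 0); pl <- which(xl > 0)
      fk <- if (weighted) xk[pk] / sum(xk[pk]) else rep(1 / length(pk), length(pk))
      fl <- if (weighted) xl[pl] / sum(xl[pl]) else rep(1 / length(pl), length(pl))
      s1 <- 0
      for (a in seq_along(pk)) {
        s1 <- s1 + fk[a] * min(D[pk[a], pl])
      }
      s2 <- 0
      for (b in seq_along(pl)) {
        s2 <- s2 + fl[b] * min(D[pl[b], pk])
      }
      out[k, l] <- out[l, k] <- 0.5 * (s1 + s2)
    }
  }
  out
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- min(running_min, 1)
  }
  adj
}

# LMG by enumerating every ordering of the predictors.
oracle_lmg <- function(y, X) {
  k <- ncol(X)
  perms <- gtools_permutations(k)
  r2_of <- function(idx) {
    if (length(idx) == 0) return(0)
    summary(lm(y ~ X[, idx, drop = FALSE]))$r.squared
  }
  shares <- numeric(k)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    for (pos in seq_len(k)) {
      before <- if (pos == 1) integer(0) else ord[seq_len(pos - 1)]
      shares[ord[pos]] <- shares[ord[pos]] +
        r2_of(c(before, ord[pos])) - r2_of(before)
    }
  }
  shares / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Beta partitioning from explicit a/b/c set algebra for one pair.
oracle_partition_pair <- function(x, y, family) {
  sx <- which(x > 0); sy <- which(y > 0)
  a <- length(intersect(sx, sy))
  b <- length(setdiff(sx, sy))
  cc <- length(setdiff(sy, sx))
  if (family == "baselga_sorensen") {
    total <- if (2 * a + b + cc == 0) 0 else (b + cc) / (2 * a + b + cc)
    repl <- if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
    rich <- total - repl
  } else {
    s <- a + b + cc
    total <- if (s == 0) 0 else (b + cc) / s
    repl <- if (s == 0) 0 else 2 * min(b, cc) / s
    rich <- if (s == 0) 0 else abs(b - cc) / s
  }
  c(total = total, replacement = repl, richness_difference = rich)
}

# Zi/Pi from the adjacency matrix, one node at a time.
oracle_zipi <- function(adj, modules) {
  n <- nrow(adj)
  k <- rowSums(adj)
  zi <- pi <- numeric(n)
  for (i in seq_len(n)) {
    own <- modules == modules[i]
    ki_own <- sum(adj[i, own])
    peers_own <- vapply(which(own), function(j) sum(adj[j, own]), numeric(1))
    sdev <- sd(peers_own)
    zi[i] <- if (is.na(sdev) || sdev == 0) 0 else (ki_own - mean(peers_own)) / sdev
    if (k[i] == 0) {
      pi[i] <- 0
    } else {
      pi[i] <- 1 - sum(vapply(unique(modules), function(s) {
        (sum(adj[i, modules == s]) / k[i])^2
      }, numeric(1)))
    }
  }
  list(zi = zi, pi = pi)
}

# Normalized stochasticity ratio from betaMNTD with its own taxa-shuffle
# draws; returns the mean over within-group pairs per group.
oracle_pnst <- function(counts, D, groups, n_null, seed) {
  ns <- nrow(counts)
  obs <- oracle_bmntd(counts, D)
  nt <- ncol(counts)
  set.seed(seed)
  null_sum <- matrix(0, ns, ns)
  null_max <- -Inf
  for (r in seq_len(n_null)) {
    perm <- sample.int(nt)
    b <- oracle_bmntd(counts, D[perm, perm])
    null_sum <- null_sum + b
    null_max <- max(null_max, max(b))
  }
  e_null <- null_sum / n_null
  dmax <- max(null_max, max(obs))
  vals <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- c()
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        dd <- obs[idx[a], idx[b]] / dmax
        ee <- e_null[idx[a], idx[b]] / dmax
        nst <- if (dd >= ee) (1 - dd) / (1 - ee) else dd / ee
        v <- c(v, min(max(nst, 0), 1))
      }
    }
    vals[[g]] <- mean(v)
  }
  vals
}

# Data generated by the RCbray null-assembly procedure itself: the
# exchangeable fixture for which RC should be centred near 0.
make_null_process_communities <- function(n_samples, pool, richness, total,
                                          occupancy_weight, seed) {
  set.seed(seed)
  nt <- length(pool)
  m <- matrix(0L, n_samples, nt)
  for (s in seq_len(n_samples)) {
    drawn <- sample.int(nt, richness, prob = occupancy_weight)
    cnt <- rep(1L, richness)
    cnt <- cnt + rmultinom(1, total - richness, pool[drawn])[, 1]
    m[s, drawn] <- cnt
  }
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                      paste0("t", seq_len(nt)))
  m
}

# Small deterministic community fixture used across tests.
make_small_comm <- function() {
  m <- rbind(S1 = c(5, 3, 1, 1, 2, 0),
             S2 = c(0, 2, 4, 1, 0, 3),
             S3 = c(2, 0, 0, 5, 1, 1))
  colnames(m) <- paste0("t", 1:6)
  as_community(m)
}

random_comm <- function(n_samples, n_taxa, seed, max_count = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, 3), n_samples, n_taxa)
  # ensure no empty samples
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                      paste0("t", seq_len(n_taxa)))
  as_community(m)
}

# wrap a hand-built igraph as a co_network for topology / zi_pi tests
as_co_network <- function(g, rho = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (is.null(rho)) rho <- rep(1, nrow(el))
  edges <- tibble::tibble(taxon1 = el$from, taxon2 = el$to, rho = rho,
                          p_value = 0, p_adjusted = 0,
                          sign = ifelse(rho > 0, "positive", "negative"))
  igraph::E(g)$rho <- rho
  structure(list(graph = g, edges = edges,
                 nodes = tibble::tibble(taxon_id = igraph::V(g)$name),
                 method = "spearman", r_min = 0.7, alpha = 0.05,
                 min_prevalence = 0),
            class = "co_network")
}
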