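# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths (and igraph / survival) so that agreement is evidence, not
# tautology.

# NSR by direct definition: for each miRNA, count targets regulated by no
# other miRNA.
bf_nsr <- function(edges) {
  vapply(unique(edges$mirna), function(m) {
    targets <- edges$mrna[edges$mirna == m]
    sum(vapply(targets, function(g) sum(edges$mrna == g) == 1L, logical(1)))
  }, integer(1))
}

# Betweenness by explicit all-pairs shortest-path counting (BFS from every
# source, then the pair-dependency sum), normalized by (n-1)(n-2)/2.
bf_betweenness <- function(edges) {
  nodes <- unique(c(edges$mirna, edges$mrna))
  n <- length(nodes)
  adj <- lapply(setNames(nodes, nodes), function(u) {
    unique(c(edges$mrna[edges$mirna == u], edges$mirna[edges$mrna == u]))
  })
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sig <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    d <- setNames(rep(Inf, n), nodes)
    sg <- setNames(rep(0, n), nodes)
    d[s] <- 0
    sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(d[[v]])) {
            d[[v]] <- d[[u]] + 1
            nxt <- union(nxt, v)
          }
          if (d[[v]] == d[[u]] + 1) sg[[v]] <- sg[[v]] + sg[[u]]
        }
      }
      frontier <- nxt
    }
    dist[s, ] <- d
    sig[s, ] <- sg
  }
  btw <- setNames(rep(0, n), nodes)
  for (v in nodes) {
    for (s in nodes) {
      for (t in nodes) {
        if (s == t || s == v || t == v) next
        if (is.finite(dist[s, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  btw <- btw / 2 # each unordered pair visited twice
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw * 0
}

# Two-group log-rank chi-square from the hypergeometric event table,
# written out term by term.
bf_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Hypergeometric upper tail as an explicit combinatorial sum.
bf_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# All permutations of a small vector (recursive; for exact-null checks).
bf_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in bf_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Exact NSR null by enumerating gene-stub assignments that form simple
# graphs; p = fraction of simple assignments with NSR >= observed.
bf_exact_nsr_p <- function(edges) {
  obs <- bf_nsr(edges)
  mirnas <- names(obs)
  perms <- bf_permutations(edges$mrna)
  total <- 0
  ge <- setNames(rep(0, length(mirnas)), mirnas)
  seen_keys <- character(0)
  for (g in perms) {
    key <- paste(g, collapse = "|")
    # next_permutation-style dedup of identical multiset orderings
    if (key %in% seen_keys) next
    seen_keys <- c(seen_keys, key)
    e2 <- data.frame(mirna = edges$mirna, mrna = g)
    if (anyDuplicated(paste(e2$mirna, e2$mrna))) next
    total <- total + 1
    nsr2 <- bf_nsr(e2)
    for (m in mirnas) if (nsr2[[m]] >= obs[[m]]) ge[[m]] <- ge[[m]] + 1
  }
  ge / total
}

# Small random bipartite toy network (no duplicate edges).
random_toy_network <- function(n_mirna = 4, n_mrna = 8, n_edges = 10) {
  pairs <- expand.grid(
    mirna = sprintf("m%02d", seq_len(n_mirna)),
    mrna = sprintf("g%02d", seq_len(n_mrna)),
    stringsAsFactors = FALSE
  )
  pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ] |>
    tibble::as_tibble()
}

# Small expression fixture: n_feat features, two groups, optional shifts.
toy_expression <- function(n_feat = 10, n1 = 5, n2 = 6, sigma = 1,
                           shifts = NULL) {
  samples <- c(sprintf("S%d", 1:n1), sprintf("R%d", 1:n2))
  vals <- matrix(rnorm(n_feat * (n1 + n2), mean = 8, sd = sigma), nrow = n_feat)
  if (!is.null(shifts)) {
    vals[, (n1 + 1):(n1 + n2)] <- vals[, (n1 + 1):(n1 + n2)] + shifts
  }
  expr <- tibble::as_tibble(as.data.frame(vals), .name_repair = "minimal")
  names(expr) <- samples
  expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("f%03d", seq_len(n_feat))), expr
  )
  groups <- tibble::tibble(
    sample_id = samples,
    group = rep(c("sensitive", "resistant"), c(n1, n2))
  )
  list(expr = expr, groups = groups)
}
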