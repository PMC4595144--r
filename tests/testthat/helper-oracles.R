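# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately naive and share no code with R/.

# Benjamini-Hochberg step-up, written literally from the definition.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  adj[o[n]] <- p[o[n]]
  for (i in (n - 1):1) {
    if (n == 1) break
    adj[o[i]] <- min(adj[o[i + 1]], p[o[i]] * n / i)
  }
  if (n == 1) adj <- p
  pmin(adj, 1)
}

# O(n^3) average-linkage agglomeration: returns merge heights and the
# partition obtained by cutting at height h (clusters = groups merged at
# or below h).
avg_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    merges <- c(merges, list(merged))
  }
  cut <- function(h) {
    cl <- as.list(seq_len(n))
    for (k in seq_along(heights)) {
      if (heights[k] > h) break
      members <- merges[[k]]
      hit <- which(vapply(cl, function(s) any(s %in% members), logical(1)))
      cl <- c(cl[-hit], list(sort(unique(unlist(cl[hit])))))
    }
    lab <- integer(n)
    for (k in seq_along(cl)) lab[cl[[k]]] <- k
    lab
  }
  list(heights = heights, cut = cut)
}

# Betweenness by exhaustive simple-path enumeration (tiny graphs only):
# for each ordered pair, enumerate all simple paths, keep the shortest,
# and credit interior nodes with the fraction of shortest paths they lie on.
betweenness_brute <- function(adj_mat) {
  n <- nrow(adj_mat)
  btw <- numeric(n)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nb in which(adj_mat[from, ] == 1)) {
      if (!(nb %in% visited))
        out <- c(out, all_paths(nb, to, c(visited, nb)))
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t, s)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(shortest)
      }
    }
  }
  btw
}

# signed-powered Spearman difference D_s for one module, written directly
# from the formulas (independent of the package internals)
ds_brute <- function(x_cases, x_controls, beta) {
  c1 <- sign(cor(t(x_cases), method = "spearman")) *
    abs(cor(t(x_cases), method = "spearman"))^beta
  c2 <- sign(cor(t(x_controls), method = "spearman")) *
    abs(cor(t(x_controls), method = "spearman"))^beta
  d <- sqrt(0.5 * abs(c1 - c2))
  diag(d) <- 0
  sqrt(mean(d[upper.tri(d)]^2))
}

# plain (unshrunken) nearest-centroid prediction with class priors,
# matching the delta = 0 limit of the shrunken classifier
nearest_centroid_predict <- function(x_train, y_train, x_new, s0_plus_sd, priors) {
  cen <- cbind(control = rowMeans(x_train[, !y_train, drop = FALSE]),
               case = rowMeans(x_train[, y_train, drop = FALSE]))
  disc <- sapply(c("control", "case"), function(k)
    colSums((x_new - cen[, k])^2 / s0_plus_sd^2) - 2 * log(priors[[k]]))
  ifelse(disc[, "case"] < disc[, "control"], "case", "control")
}

# small planted-signal expression fixture for classifier tests
make_signal_data <- function(n_genes, n_signal, effect, n_case, n_ctrl, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (n_case + n_ctrl)), n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_case + n_ctrl))))
  y <- c(rep(TRUE, n_case), rep(FALSE, n_ctrl))
  if (n_signal > 0) x[seq_len(n_signal), y] <- x[seq_len(n_signal), y] + effect
  list(x = x, y = y)
}
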