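# Independent oracles used to cross-check the production implementations.
# They are deliberately written in the most literal textbook style.

# Textbook Dijkstra with a goal set: linear scans, no priority queue.
# Edge cost = cost of the destination pixel; start pixels cost nothing.
dijkstra_oracle <- function(cost, region, start, goal, diag_scale = FALSE) {
  nr <- nrow(cost); nc <- ncol(cost)
  lin <- function(px) px[, 1] + nr * (px[, 2] - 1)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[lin(start)] <- 0
  goal_lin <- lin(goal)
  repeat {
    d <- dist; d[done | !region] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) return(Inf)
    done[u] <- TRUE
    if (u %in% goal_lin) return(dist[u])
    r <- (u - 1) %% nr + 1; c <- (u - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!region[rr, cc] || done[rr, cc]) next
      w <- cost[rr, cc]
      if (diag_scale && dr != 0 && dc != 0) w <- w * sqrt(2)
      if (dist[u] + w < dist[rr, cc]) dist[rr, cc] <- dist[u] + w
    }
  }
}

# Exhaustive minimal path cost by depth-first enumeration of simple paths
# with cost-based pruning (exact for non-negative costs).
enumerate_path_cost <- function(cost, region, start, goal) {
  nr <- nrow(cost); nc <- ncol(cost)
  lin <- function(px) px[, 1] + nr * (px[, 2] - 1)
  goal_lin <- lin(goal)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(r, c, acc) {
    if (acc >= best) return()
    u <- r + nr * (c - 1)
    if (u %in% goal_lin) { best <<- acc; return() }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!region[rr, cc] || visited[rr, cc]) next
      visited[rr, cc] <<- TRUE
      dfs(rr, cc, acc + cost[rr, cc])
      visited[rr, cc] <<- FALSE
    }
  }
  for (i in seq_len(nrow(start))) {
    visited[] <- FALSE
    visited[start[i, 1], start[i, 2]] <- TRUE
    dfs(start[i, 1], start[i, 2], 0)
  }
  best
}

# Per-pixel Frangi response via explicit finite differences and base
# eigen(), sharing only the Gaussian smoothing with the implementation.
frangi_oracle <- function(slice, spacing = c(1, 1),
                          scales_mm = c(0.7, 1, 1.4, 2), beta = 0.5) {
  nr <- nrow(slice); nc <- ncol(slice)
  E <- matrix(0, nr, nc)
  clamp <- function(i, n) min(max(i, 1), n)
  for (s in scales_mm) {
    g <- lobeseg:::.smoothSep(slice, s / spacing[1], s / spacing[2])
    H11 <- H22 <- H12 <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ip <- clamp(i + 1, nr); im <- clamp(i - 1, nr)
      jp <- clamp(j + 1, nc); jm <- clamp(j - 1, nc)
      H11[i, j] <- s^2 * (g[ip, j] - 2 * g[i, j] + g[im, j]) / spacing[1]^2
      H22[i, j] <- s^2 * (g[i, jp] - 2 * g[i, j] + g[i, jm]) / spacing[2]^2
      H12[i, j] <- s^2 * (g[ip, jp] - g[ip, jm] - g[im, jp] + g[im, jm]) /
        (4 * spacing[1] * spacing[2])
    }
    cnorm <- sqrt(max(H11^2 + 2 * H12^2 + H22^2)) / 2
    if (cnorm <= 1e-8) next
    Es <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ev <- eigen(matrix(c(H11[i, j], H12[i, j], H12[i, j], H22[i, j]),
                         2, 2), symmetric = TRUE)$values
      ev <- ev[order(abs(ev))]
      if (ev[2] >= 0) next
      rb2 <- (ev[1] / ev[2])^2
      s2 <- ev[1]^2 + ev[2]^2
      Es[i, j] <- exp(-rb2 / (2 * beta^2)) *
        (1 - exp(-s2 / (2 * cnorm^2)))
    }
    E <- pmax(E, Es)
  }
  E
}

# O(n*m) double-loop shortest distances, reference for surface stats.
min_dist_bruteforce <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    best
  }, numeric(1))
}

# Naive Gaussian elimination with partial pivoting (RBF solver oracle).
gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n - 1)) {
    p <- which.max(abs(M[k:n, k])) + k - 1
    if (p != k) M[c(k, p), ] <- M[c(p, k), ]
    for (i in (k + 1):n)
      M[i, ] <- M[i, ] - (M[i, k] / M[k, k]) * M[k, ]
  }
  x <- numeric(n)
  for (i in n:1)
    x[i] <- (M[i, n + 1] - sum(M[i, seq_len(n)[-seq_len(i)]] *
                               x[-seq_len(i)])) / M[i, i]
  x
}
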