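# Independent oracles: straightforward R re-implementations used only to
# check the package's compiled/optimized routes.

# plain-loop BLN energy (independent of the compiled kernel)
oracle_bln_energy <- function(conf, seq, params = bln_parameters()) {
  n <- nrow(conf)
  lab <- seq$labels
  dih <- seq$dihedral_classes
  p <- params
  e <- 0
  for (i in 1:(n - 1)) {
    r <- sqrt(sum((conf[i + 1, ] - conf[i, ])^2))
    e <- e + p$k_b * (r - p$sigma)^2
  }
  if (n >= 3) for (i in 1:(n - 2)) {
    u <- conf[i, ] - conf[i + 1, ]; v <- conf[i + 2, ] - conf[i + 1, ]
    th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    e <- e + 0.5 * p$k_theta * (th - p$theta0)^2
  }
  cross <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                            a[1]*b[2]-a[2]*b[1])
  cls_idx <- c(H = 1, E = 2, T = 3)
  if (n >= 4) for (i in 1:(n - 3)) {
    b1 <- conf[i+1, ] - conf[i, ]; b2 <- conf[i+2, ] - conf[i+1, ]
    b3 <- conf[i+3, ] - conf[i+2, ]
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    phi <- atan2(sum(cross(n1, b2) * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
    abc <- params$dihedral_table[cls_idx[[dih[i]]], ]
    e <- e + abc[1]*(1+cos(phi)) + abc[2]*(1+cos(3*phi)) + abc[3]*(1+sin(phi))
  }
  bd_idx <- c(B = 1, L = 2, N = 3)
  for (i in 1:n) for (j in seq_len(n)[-seq_len(min(i + 2, n))]) {
    r <- sqrt(sum((conf[j, ] - conf[i, ])^2))
    s1 <- p$S1[bd_idx[[lab[i]]], bd_idx[[lab[j]]]]
    s2 <- p$S2[bd_idx[[lab[i]]], bd_idx[[lab[j]]]]
    e <- e + 4 * p$epsilon * s1 * ((p$sigma / r)^12 - s2 * (p$sigma / r)^6)
  }
  e
}

# BFS hop matrix in plain R
oracle_hops <- function(G) {
  n <- nrow(G)
  S <- matrix(n, n, n)
  for (s in 1:n) {
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(G[u, ] == 1L & dist < 0)
      dist[nb] <- dist[u] + 1L
      queue <- c(queue, nb)
    }
    S[s, dist >= 0] <- dist[dist >= 0]
  }
  S
}

oracle_sch <- function(A, B) {
  SA <- oracle_hops(A); SB <- oracle_hops(B)
  n <- nrow(A); s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (SA[i, j] != SB[i, j])
      s <- s + abs(SA[i, j] - SB[i, j]) / max(SA[i, j], SB[i, j])
  }
  2 * s / (n * (n - 1))
}

# exhaustive discrete Frechet by enumerating monotone couplings (tiny tracks)
oracle_frechet <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A); m <- nrow(B)
  dmat <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  walk <- function(i, j, cur) {
    cur <- max(cur, dmat[i, j])
    if (cur >= best) return(invisible())
    if (i == n && j == m) { best <<- cur; return(invisible()) }
    if (i < n) walk(i + 1, j, cur)
    if (j < m) walk(i, j + 1, cur)
    if (i < n && j < m) walk(i + 1, j + 1, cur)
  }
  walk(1, 1, 0)
  best
}

random_contact_map <- function(n, p = 0.25) {
  G <- matrix(0L, n, n)
  ut <- which(upper.tri(G))
  on <- ut[runif(length(ut)) < p]
  G[on] <- 1L
  G[lower.tri(G)] <- t(G)[lower.tri(G)]
  G
}
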