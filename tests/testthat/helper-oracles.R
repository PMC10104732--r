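# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (two-pass sums, BFS flood fill, graph
# shortest path via igraph, closed forms) kept separate from the package's
# own algorithms.

# two-pass within-class scatter: mean first, then squared deviations
oracle_G <- function(v, t) {
  v <- as.vector(v)
  fg <- v[v >= t]
  bg <- v[v < t]
  g <- 0
  if (length(fg)) g <- g + sum((fg - sum(fg) / length(fg))^2)
  if (length(bg)) g <- g + sum((bg - sum(bg) / length(bg))^2)
  g
}

# exhaustive scan argmin with smallest-t tie-break
oracle_threshold <- function(v, ts) {
  gs <- vapply(ts, function(t) oracle_G(v, t), numeric(1))
  list(t_star = ts[which.min(gs)], G = gs)
}

# queue-based BFS flood fill labelling (independent of min-label propagation)
oracle_components <- function(m, connectivity = 26) {
  d <- dim(m)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & switch(as.character(connectivity),
    "6" = nz == 1, "18" = nz <= 2, "26" = nz <= 3
  ), , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(m)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      pc <- arrayInd(p, d)
      for (r in seq_len(nrow(offs))) {
        q <- pc + offs[r, ]
        if (any(q < 1L) || any(q > d)) next
        ql <- q[1] + (q[2] - 1L) * d[1] + (q[3] - 1L) * d[1] * d[2]
        if (m[ql] && lab[ql] == 0L) {
          lab[ql] <- cur
          queue <- c(queue, ql)
        }
      }
    }
  }
  lab
}

# shortest path cost over the 8-connected pixel graph via igraph, with edge
# weight = step length x local cost of the entered pixel
oracle_livewire_cost <- function(cost_map, seed, target) {
  nr <- nrow(cost_map)
  nc <- ncol(cost_map)
  id <- function(r, c) r + (c - 1L) * nr
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      from <- c(from, id(r, c))
      to <- c(to, id(r2, c2))
      w <- c(w, sqrt(dr^2 + dc^2) * cost_map[r2, c2])
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nr * nc))
  )
  igraph::E(g)$weight <- w
  d <- igraph::distances(g,
    v = as.character(id(seed[1], seed[2])),
    to = as.character(id(target[1], target[2])), mode = "out"
  )
  as.numeric(d)
}

# implicit fields -------------------------------------------------------------

sphere_field <- function(radius = 10, spacing = 1, pad = 2) {
  half <- radius + pad
  ax <- seq(-half, half, by = spacing)
  n <- length(ax)
  g <- expand.grid(x = ax, y = ax, z = ax)
  f <- array(radius - sqrt(g$x^2 + g$y^2 + g$z^2), dim = c(n, n, n))
  ct_volume(f, spacing = rep(spacing, 3), origin = rep(-half, 3))
}

torus_field <- function(R = 8, r = 3, spacing = 1, pad = 2) {
  half <- R + r + pad
  ax <- seq(-half, half, by = spacing)
  axz <- seq(-(r + pad), r + pad, by = spacing)
  f <- array(0, dim = c(length(ax), length(ax), length(axz)))
  for (k in seq_along(axz)) {
    rho <- sqrt(outer(ax^2, ax^2, `+`))
    f[, , k] <- r - sqrt((rho - R)^2 + axz[k]^2)
  }
  ct_volume(f, spacing = rep(spacing, 3), origin = c(-half, -half, -(r + pad)))
}

# independent trapezoid quadrature (weight-vector formulation)
oracle_trapz_mean <- function(t, p) {
  n <- length(t)
  w <- numeric(n)
  w[1] <- (t[2] - t[1]) / 2
  w[n] <- (t[n] - t[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  sum(w * p) / (t[n] - t[1])
}

# seeded random volume for threshold-oracle checks: integer-valued mixture
random_ct_fixture <- function(seed) {
  set.seed(seed)
  d <- sample(4:16, 3, replace = TRUE)
  n <- prod(d)
  mix <- runif(1, 0.2, 0.8)
  vals <- ifelse(
    runif(n) < mix,
    round(rnorm(n, mean = 60, sd = 18)),
    round(rnorm(n, mean = 180, sd = 25))
  )
  array(pmax(vals, 0), dim = d)
}

# a capped (closed) stenosed-lumen mask: truth mask padded with empty slices
capped_lumen_mask <- function(d = 0.3, spacing = 0.5, R0 = 2, L = 20) {
  geom <- vessel_geometry(L = L, R0 = R0, d = d)
  m <- lumen_truth_mask(geom, spacing = spacing)
  dm <- dim(m$data)
  padded <- array(FALSE, dm + c(0, 0, 2))
  padded[, , 2:(dm[3] + 1)] <- m$data
  ct_mask(padded, m$spacing, m$origin - c(0, 0, m$spacing[3]))
}
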