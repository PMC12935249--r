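# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementation.

# strict barycentric point-in-triangle test
inside_triangle_strict <- function(p, a, b, c) {
  s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
  s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
  (s1 > 0 && s2 > 0 && s3 > 0) || (s1 < 0 && s2 < 0 && s3 < 0)
}

# brute-force convex hull area: a point is interior iff some triangle of
# three other points strictly contains it; surviving vertices are ordered by
# angle around their centroid and fed to the shoelace formula. Exponential in
# n -- only for n <= 8 point clouds in general position.
brute_hull_area <- function(x, y) {
  n <- length(x)
  pts <- cbind(x, y)
  interior <- logical(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (length(others) < 3) next
    for (tri in utils::combn(others, 3, simplify = FALSE)) {
      if (inside_triangle_strict(pts[i, ], pts[tri[1], ], pts[tri[2], ],
                                 pts[tri[3], ])) {
        interior[i] <- TRUE
        break
      }
    }
  }
  v <- pts[!interior, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  xs <- v[, 1]; ys <- v[, 2]
  0.5 * abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys))
}

# quadratic-scan nearest-neighbour distances
brute_nnd <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# hand-rolled Huber IRLS (tuning k * MAD scale, weighted least squares)
hand_huber <- function(x, y, k = 1.345, maxit = 50, tol = 1e-8) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    s <- stats::median(abs(r)) / 0.6745
    if (s == 0) break
    w <- pmin(1, k * s / abs(r))
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * y))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# exact two-sided rank-sum p-value by enumerating all assignments of ranks
enum_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  all_w <- utils::combn(length(pooled), length(a),
                        FUN = function(idx) sum(idx))
  mean_w <- mean(all_w)
  mean(abs(all_w - mean_w) >= abs(w_obs - mean_w) - 1e-12)
}

# Benjamini-Hochberg step-up by hand
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# deterministic 2-D grid oracle for ellipse intersection area
grid_overlap_area <- function(muA, SA, cA, muB, SB, cB, m = 1500L) {
  SAi <- solve(SA); SBi <- solve(SB)
  box_lo <- pmax(muA - sqrt(cA * diag(SA)), muB - sqrt(cB * diag(SB)))
  box_hi <- pmin(muA + sqrt(cA * diag(SA)), muB + sqrt(cB * diag(SB)))
  if (any(box_lo >= box_hi)) return(0)
  xs <- seq(box_lo[1], box_hi[1], length.out = m)
  ys <- seq(box_lo[2], box_hi[2], length.out = m)
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]
  count <- 0
  for (x in xs) {
    dx <- x - muA[1]; dyv <- ys - muA[2]
    qa <- SAi[1, 1] * dx^2 + 2 * SAi[1, 2] * dx * dyv + SAi[2, 2] * dyv^2
    dx2 <- x - muB[1]; dyv2 <- ys - muB[2]
    qb <- SBi[1, 1] * dx2^2 + 2 * SBi[1, 2] * dx2 * dyv2 + SBi[2, 2] * dyv2^2
    count <- count + sum(qa <= cA & qb <= cB)
  }
  count * hx * hy
}

# minimal valid raw sample data.frame
make_raw_df <- function(n = 3, taxon = "wildcat") {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    taxon = taxon,
    region = "Hainich",
    case_study = 2,
    year = 2000 + seq_len(n) %% 20,
    month = (seq_len(n) %% 12) + 1,
    sex = rep(c("m", "f"), length.out = n),
    d13C_measured = -20 - seq_len(n) * 0.1,
    d15N = 3 + seq_len(n) * 0.1,
    d34S = 4 + seq_len(n) * 0.1,
    pctC = 45, pctN = 14.8, pctS = 0.2,
    stringsAsFactors = FALSE
  )
}
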