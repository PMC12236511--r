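# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# numerical steady-state oracle, independent of the package's closed forms.
# With substrate clamped, the steady state of (ES, EP) solves a 2x2 linear
# system (exact for any E0, since every term is proportional to enzyme):
#   k1 S (E0 - ES - EP) + k_minus2 EP - (k_minus1 + k2) ES = 0
#   k2 ES - (k_minus2 + k3) EP = 0
# v0(S) = k3 EP / E0. The saturating rate, half-saturation point (located by
# bisection) and a Hanes-Woolf regression over 50 substrate concentrations
# then give kcat and KM numerically.
oracle_v0 <- function(k, S, E0 = 1e-9) {
  a <- k[["k1"]] * S
  A <- rbind(c(-(a + k[["k_minus1"]] + k[["k2"]]), k[["k_minus2"]] - a),
             c(k[["k2"]], -(k[["k_minus2"]] + k[["k3"]])))
  b <- c(-a * E0, 0)
  # row equilibration keeps the solve well conditioned at extreme magnitudes
  s <- apply(abs(A), 1, max)
  sol <- solve(A / s, b / s)
  k[["k3"]] * sol[2] / E0
}

oracle_steady_state <- function(k, E0 = 1e-9) {
  vmax <- oracle_v0(k, 1e12, E0)
  f <- function(logS) oracle_v0(k, 10^logS, E0) - vmax / 2
  lo <- -15; hi <- 12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  S_half <- 10^((lo + hi) / 2)
  S <- S_half * 10^seq(-1.5, 1.5, length.out = 50)
  v0 <- vapply(S, function(s) oracle_v0(k, s, E0), numeric(1))
  hw <- lm(I(S / v0) ~ S)           # Hanes-Woolf: slope 1/kcat, icpt KM/kcat
  kcat <- 1 / coef(hw)[["S"]]
  KM <- coef(hw)[["(Intercept)"]] * kcat
  c(kcat = kcat, KM = KM)
}

# brute-force superposition: grid over rotation axes (Fibonacci sphere) with
# the per-axis optimal angle obtained in closed form from the Rodrigues
# expansion (residual is linear in cos/sin of the angle)
oracle_best_rotation <- function(P, Q, n_axes = 4000) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_axes) - 0.5
  zs <- 1 - 2 * i / n_axes
  rs <- sqrt(1 - zs^2)
  axes <- cbind(rs * cos(golden * i), rs * sin(golden * i), zs)
  eval_axis <- function(u) {
    ux <- cbind(u[2] * Pc[, 3] - u[3] * Pc[, 2],
                u[3] * Pc[, 1] - u[1] * Pc[, 3],
                u[1] * Pc[, 2] - u[2] * Pc[, 1])
    uuP <- outer(drop(Pc %*% u), u)
    # x(theta) = Pc cos + (u x Pc) sin + u(u.Pc)(1-cos); maximizing the
    # overlap sum(Qc . x(theta)) = b cos + cc sin + d over theta
    b <- sum(Qc * (Pc - uuP))   # coefficient of cos(theta)
    cc <- sum(Qc * ux)          # coefficient of sin(theta)
    d <- sum(Qc * uuP)          # theta-independent, axis-dependent
    theta <- atan2(cc, b)
    list(obj = -(sqrt(b^2 + cc^2) + d), theta = theta)
  }
  objs <- vapply(seq_len(n_axes), function(j) eval_axis(axes[j, ])$obj,
                 numeric(1))
  # polish the axis locally from the best grid nodes (unconstrained 3-vector
  # renormalized inside the objective); still a direct search on the same
  # objective, independent of the SVD path
  polish <- function(u0) {
    opt <- stats::optim(u0, function(v) {
      eval_axis(v / sqrt(sum(v^2)))$obj
    }, method = "Nelder-Mead", control = list(reltol = 1e-15, maxit = 5000))
    list(obj = opt$value, u = opt$par / sqrt(sum(opt$par^2)))
  }
  cand <- purrr::map(order(objs)[1:5], ~ polish(axes[.x, ]))
  bestc <- cand[[which.min(purrr::map_dbl(cand, "obj"))]]
  u <- bestc$u
  e <- eval_axis(u)
  ang <- e$theta * 180 / pi
  if (ang < 0) {
    ang <- -ang
    u <- -u
  }
  list(angle_deg = ang, axis = u)
}

# O(n^2) brute-force minimum interatomic distance between two atom sets
oracle_min_distance <- function(A, B) {
  dmin <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dmin <- min(dmin, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
  }
  dmin
}

# per-sample bin assignment for an equal-width histogram, right-closed bins
# with the lowest edge included in bin 1
oracle_histogram <- function(x, edges) {
  counts <- integer(length(edges) - 1)
  for (v in x) {
    if (v == edges[1]) {
      counts[1] <- counts[1] + 1
      next
    }
    b <- findInterval(v, edges, left.open = TRUE)
    counts[b] <- counts[b] + 1
  }
  counts
}

# reduce an angle modulo 360/n into [0, 180/n] by exhaustive enumeration
oracle_reduce_angle <- function(a, n) {
  period <- 360 / n
  cand <- abs(a - (-n:n) * period)
  cand <- pmin(cand %% 360, 360 - cand %% 360)
  min(cand)
}

# simple particle table used by several time-resolved tests
make_count_table <- function(fractions, times, n_total = 1000,
                             n_unassigned = 0) {
  tibble::tibble(
    dataset_id = sprintf("d%02d", seq_along(times)),
    time_s = times,
    n_decamer = round(n_total * (1 - fractions)),
    n_filament = round(n_total * fractions),
    n_unassigned = n_unassigned)
}
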