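# Independent oracles used across the suite.  These deliberately avoid
# the package's propagator implementation: matrix exponentials come from
# eigen-decomposition, pulse trains are stepped segment by segment, and
# geometry checks use their own arithmetic.

# exp(t*L) for the two-site evolution matrix, via eigen()
oracle_expm2 <- function(k1, km1, off, t) {
  L <- matrix(c(-k1 + 0i, k1 + 0i, km1 + 0i,
                complex(real = -km1, imaginary = off)), 2, 2)
  e <- eigen(L)
  e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)
}

# single-quantum CPMG: explicit delay-pulse-delay loop with complex
# conjugation at every ideal 180 pulse
oracle_sq_rex <- function(p_b, k_ex, dw_rad, n, t_relax) {
  p_a <- 1 - p_b
  k1 <- k_ex * p_b
  km1 <- k_ex * p_a
  d <- t_relax / (2 * n)
  Ed <- oracle_expm2(k1, km1, dw_rad, d)
  E2 <- oracle_expm2(k1, km1, dw_rad, 2 * d)
  M <- c(p_a + 0i, p_b + 0i)
  M <- Ed %*% M
  for (p in seq_len(n - 1)) M <- E2 %*% Conj(M)
  M <- Ed %*% Conj(M)
  -log(Mod(M[1]) / p_a) / t_relax
}

# multiple-quantum CPMG: step the full echo train segment by segment
# through the alternating DQ/ZQ frames, averaging both coherence
# pathways
oracle_mq_rex <- function(p_b, k_ex, dwx_rad, dwh_rad, n, t_relax) {
  p_a <- 1 - p_b
  k1 <- k_ex * p_b
  km1 <- k_ex * p_a
  d <- t_relax / (2 * n)
  one_path <- function(offs) {
    M <- c(p_a + 0i, p_b + 0i)
    M <- oracle_expm2(k1, km1, offs[1], d) %*% M
    for (k in 2:n) M <- oracle_expm2(k1, km1, offs[k], 2 * d) %*% M
    M <- oracle_expm2(k1, km1, offs[n + 1], d) %*% M
    -log(Mod(M[1]) / p_a) / t_relax
  }
  sg <- (-1)^(0:n)
  (one_path(dwh_rad + sg * dwx_rad) + one_path(dwh_rad - sg * dwx_rad)) / 2
}

# Luz-Meiboom fast-exchange closed form for the exchange contribution
oracle_luz_meiboom <- function(p_b, k_ex, dw_rad, nu) {
  p_b * (1 - p_b) * dw_rad^2 / k_ex *
    (1 - (4 * nu / k_ex) * tanh(k_ex / (4 * nu)))
}

# minimum RMSD over rigid transforms by a nested Euler-angle grid search
# (translation solved by centroid alignment at each rotation)
oracle_grid_superpose <- function(mobile, reference, levels = 4) {
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    Rz2 %*% Ry %*% Rz1
  }
  pc <- sweep(mobile, 2, colMeans(mobile))
  qc <- sweep(reference, 2, colMeans(reference))
  eval_rmsd <- function(a, b, c)
    sqrt(mean(rowSums((pc %*% t(rot(a, b, c)) - qc)^2)))
  ctr <- c(0, 0, 0)
  span <- pi
  best <- Inf
  for (lv in seq_len(levels)) {
    gr <- seq(-span, span, length.out = 9)
    for (a in ctr[1] + gr) for (b in ctr[2] + gr) for (c in ctr[3] + gr) {
      v <- eval_rmsd(a, b, c)
      if (v < best) { best <- v; ctr <- c(a, b, c) }
    }
    span <- span / 6
  }
  best
}

# brute-force violation statistic: plain double loop with its own
# barycenter arithmetic
oracle_violation <- function(trajectory, spec) {
  pairs <- spec$pairs
  at <- trajectory$atoms
  pos <- function(m, resid, names) {
    nm <- strsplit(names, ";", fixed = TRUE)[[1]]
    idx <- sapply(nm, function(a) which(at$resno == resid & at$name == a)[1])
    if (length(idx) == 1) m[idx, ] else
      c(mean(m[idx, 1]), mean(m[idx, 2]), mean(m[idx, 3]))
  }
  sapply(trajectory$models, function(m) {
    tot <- 0
    for (r in seq_len(nrow(pairs))) {
      pi_ <- pos(m, pairs$resid_i[r], pairs$atoms_i[r])
      pj <- pos(m, pairs$resid_j[r], pairs$atoms_j[r])
      d <- sqrt(sum((pi_ - pj)^2))
      tot <- tot + max(0, d - pairs$d_viol[r])
    }
    tot / nrow(pairs)
  })
}

# small dispersion dataset helper: n_probes MQ probes at one or two
# fields with a reduced frequency grid, for fast fitting tests
small_truth <- function(n_probes = 4, fields = 850, noise = 0.02,
                        seed = 1, p_excited = 0.032, k_ex = 2490) {
  pr <- wt_methyl_probes(n_probes, fields_MHz = fields)
  synthetic_truth(exchange_params(p_excited, k_ex, 293), probes = pr,
                  fields_MHz = fields, noise_fraction = noise, seed = seed)
}

small_schedule <- function() {
  cpmg_schedule("CH3_MQ", nu_list = c(4, 8, 14, 24, 38, 60, 88, 120) / 0.06)
}

# random rigid transform applied to a coordinate matrix
random_rigid <- function(xyz, seed = 1) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1]), 0,
                 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[2]), sin(ang[2]),
                 0, -sin(ang[2]), cos(ang[2])), 3, 3)
  sweep(xyz %*% t(Rx %*% Rz), 2, runif(3, -20, 20), `+`)
}
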