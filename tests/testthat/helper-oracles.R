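# Independent brute-force oracles used to cross-check the fast
# implementations. These deliberately share no code with the package
# internals beyond base R.

# Kirchhoff matrix by explicit double loop
oracle_kirchhoff <- function(m, cutoff) {
  n <- nrow(m)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((m[i, ] - m[j, ])^2))
      if (d <= cutoff) {
        K[i, j] <- -1
        K[i, i] <- K[i, i] + 1
      }
    }
  }
  K
}

# ANM Hessian by explicit per-pair block assembly
oracle_hessian <- function(m, cutoff) {
  n <- nrow(m)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- m[j, ] - m[i, ]
      d2 <- sum(r^2)
      if (sqrt(d2) > cutoff) next
      blk <- outer(r, r) / d2
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- -blk
      H[ii, ii] <- H[ii, ii] + blk
    }
  }
  H
}

# residual MSD of a TLS line fit computed from scratch via SVD of the
# centred coordinates (no scatter-matrix shortcut)
oracle_line_msd <- function(pts) {
  pc <- sweep(pts, 2, colMeans(pts))
  s <- svd(pc)
  dir <- s$v[, 1]
  proj <- pc %*% dir
  mean(rowSums((pc - proj %*% t(dir))^2))
}

# bisection MSD profile by refitting both arms from scratch at every
# split (chain-centroid trace, split residue in both arms)
oracle_profile <- function(resid, m, min_segment) {
  r <- sort(unique(resid))
  cen <- t(vapply(r, function(rr) colMeans(m[resid == rr, , drop = FALSE]),
                  numeric(3)))
  cand <- seq(min_segment, length(r) - min_segment + 1)
  msd <- vapply(cand, function(k) {
    low <- cen[1:k, , drop = FALSE]
    high <- cen[k:length(r), , drop = FALSE]
    (nrow(low) * oracle_line_msd(low) + nrow(high) * oracle_line_msd(high)) /
      (nrow(low) + nrow(high))
  }, numeric(1))
  list(resid = r[cand], msd = msd)
}

# minimum RMSD by brute-force search over an axis-angle rotation grid.
# With M = t(Pc) %*% Qc, rmsd^2(R) = (|Pc|^2 + |Qc|^2 - 2 tr(R'M)) / n and
# tr(R'M) = tr(M) + sin(t) tr(K'M) + (1 - cos(t)) tr((KK)'M) for the
# Rodrigues form, so each axis needs two traces and the angle sweep is
# closed-form.
oracle_rmsd_grid <- function(P, Q, n_axes = 10000, angle_step_deg = 2) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  k <- seq_len(n_axes) - 1
  z <- 1 - (2 * k + 1) / n_axes
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  axes <- cbind(rho * cos(phi), rho * sin(phi), z)
  theta <- seq(0, 2 * pi, by = angle_step_deg * pi / 180)
  base <- sum(diag(M))
  best <- -Inf
  for (a in seq_len(n_axes)) {
    u <- axes[a, ]
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    tA <- sum(t(K) * M)
    tB <- sum(t(K %*% K) * M)
    val <- max(base + sin(theta) * tA + (1 - cos(theta)) * tB)
    if (val > best) best <- val
  }
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * best) / nrow(P)))
}

# GROMOS clustering by literal neighbour counting over index sets
oracle_gromos <- function(D, cutoff) {
  n <- nrow(D)
  left <- seq_len(n)
  clusters <- list()
  while (length(left) > 0) {
    counts <- vapply(left, function(i) sum(D[i, left] <= cutoff), numeric(1))
    centre <- left[which.max(counts)]
    members <- left[D[centre, left] <= cutoff]
    clusters[[length(clusters) + 1]] <- list(centroid = centre,
                                             members = sort(members))
    left <- setdiff(left, members)
  }
  clusters
}

# small noisy bent-dimer ensemble used across tests
make_bent_ensemble <- function(n_res = 500, hinge = 268, angle = 30,
                               noise = 0.05, n_frames = 10, seed = 1) {
  base <- build_rod(rod_spec(n_residues_per_chain = n_res,
                             hinge_residue = hinge, noise_sd = 0))
  set.seed(seed)
  coords <- lapply(seq_len(n_frames), function(i) {
    bent <- bend_at_hinge(base, hinge, angle)
    m <- as.matrix(bent[, c("x", "y", "z")])
    if (noise > 0) m <- m + matrix(rnorm(length(m), 0, noise), nrow(m), 3)
    m
  })
  new_ensemble(base[, c("chain", "resid", "domain")], coords)
}

# averaged bisection profile over an ensemble's frames
mean_profile_hinge <- function(ens, min_segment = 10) {
  profs <- sapply(seq_along(ens$coords), function(i) {
    bisection_msd_profile(ensemble_frame(ens, i), min_segment = min_segment)$msd
  })
  p1 <- bisection_msd_profile(ensemble_frame(ens, 1), min_segment = min_segment)
  p1$resid[which.min(rowMeans(profs))]
}
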