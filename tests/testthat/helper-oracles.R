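## Independent oracles used to freeze expected values: these reimplement
## the checked quantities by a different route than the package code.

cross_o <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## projection-based dihedral: project the outer bonds onto the plane
## perpendicular to the central bond and take the signed angle there
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  ang <- atan2(sum(cross_o(u, v) * b), sum(u * v)) * 180 / pi
  ## the conventional sign is positive for a clockwise turn viewed
  ## from p2 towards p3, which is the negative of the plane angle above
  -ang
}

## brute-force in-place RMSD over an explicit per-atom sum
oracle_rmsd <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  tot <- 0
  for (k in seq_len(nrow(a))) tot <- tot + sum((a[k, ] - b[k, ])^2)
  sqrt(tot / nrow(a))
}

## exhaustive symmetry-corrected RMSD: minimum over the cartesian
## product of all within-group permutations
oracle_rmsd_sym <- function(a, b, groups) {
  perm_list <- lapply(groups, function(g) {
    pm <- perms_o(length(g))
    lapply(seq_len(nrow(pm)), function(r) g[pm[r, ]])
  })
  combos <- expand.grid(lapply(perm_list, seq_along))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    b2 <- b
    for (gi in seq_along(groups))
      b2[groups[[gi]], ] <- b[perm_list[[gi]][[combos[r, gi]]], ]
    best <- min(best, oracle_rmsd(a, b2))
  }
  best
}

perms_o <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms_o(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow = nrow(sub)))))
}

## circular mean via complex arithmetic (independent formulation)
oracle_circ_mean <- function(x) {
  z <- mean(exp(1i * x * pi / 180))
  Arg(z) * 180 / pi
}

## exact power by repeated multiplication in doubles (valid below 2^53)
oracle_pow <- function(base, expo) {
  out <- 1
  for (k in seq_len(expo)) out <- out * base
  out
}

## random rigid motion applied to a coordinate matrix
random_rigid <- function(xyz) {
  ax <- stats::rnorm(3)
  R <- glycodock::rotation_matrix(ax, stats::runif(1, 0, 360))
  t <- stats::rnorm(3, 0, 10)
  sweep(xyz %*% t(R), 2, t, "+")
}

## small standard fixtures
tiny_chain <- function(n = 4, ...) make_chain(fixture_spec(chain_length = n, ...))

standard_complex <- function(n = 6, tightness = 1, seed = 1) {
  ch <- make_chain(fixture_spec(chain_length = n,
                                sulfation = "heterogeneous"))
  c(make_complex(ch, tightness = tightness, seed = seed), list())
}
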