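# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: everything is explicit double loops over residues
# and pairs, so they can serve as a second route for the loss, gradient and
# superposition checks.

oracle_restraint <- function(coords, spec) {
  total <- 0
  for (i in seq_along(spec$indices)) {
    key <- as.character(spec$indices[i])
    d <- coords[key, ] - spec$reference[key, ]
    total <- total + d[1]^2 + d[2]^2 + d[3]^2
  }
  total / length(spec$indices)
}

oracle_pair_distances <- function(coords, term) {
  a <- term$group_a$indices
  b <- term$group_b$indices
  d <- c()
  if (term$pairing == "positional") {
    for (i in seq_along(a)) {
      v <- coords[as.character(a[i]), ] - coords[as.character(b[i]), ]
      d <- c(d, sqrt(sum(v^2)))
    }
  } else {
    for (i in seq_along(a)) for (j in seq_along(b)) {
      v <- coords[as.character(a[i]), ] - coords[as.character(b[j]), ]
      d <- c(d, sqrt(sum(v^2)))
    }
  }
  d
}

oracle_attractive <- function(coords, term) {
  d <- oracle_pair_distances(coords, term)
  max(mean(d - term$cutoff), 0)
}

oracle_repulsive <- function(coords, term) {
  d <- oracle_pair_distances(coords, term)
  max(mean(term$cutoff - d), 0)
}

oracle_regularization <- function(plddt, ptm, iptm) {
  (1 - sum(plddt) / length(plddt)) + (1 - ptm) + (1 - iptm)
}

# central finite differences of the weighted coordinate loss
fd_gradient <- function(coords, restraint, cv_terms, w_c, h = 1e-4) {
  f <- function(cc) afex_loss(cc, restraint, cv_terms, NULL,
                              w_c = w_c, w_r = 0)$l_afex
  g <- coords * 0
  for (i in seq_len(nrow(coords))) for (k in 1:3) {
    up <- coords; up[i, k] <- up[i, k] + h
    dn <- coords; dn[i, k] <- dn[i, k] - h
    g[i, k] <- (f(up) - f(dn)) / (2 * h)
  }
  g
}

# derivative-free best-fit oracle: minimize RMSD over Euler angles +
# translation with optim, independent of the SVD route
oracle_fit_rmsd <- function(P, Q) {
  rot <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(a) sqrt(mean(rowSums((Pc %*% rot(a) - Qc)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                     c(0, 0, pi / 2), c(pi, 0, 0), c(1, 1, 1))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    if (o$value < best) best <- o$value
  }
  best
}

# random CA-only structure as a bare coordinate matrix
random_coords <- function(n, seed, spread = 10) {
  set.seed(seed)
  matrix(stats::rnorm(n * 3, sd = spread), n, 3,
         dimnames = list(seq_len(n), NULL))
}

# random CV terms valid for an n-residue coordinate set
random_terms <- function(n, seed) {
  set.seed(seed + 10000)
  k <- sample(1:3, 1)
  lapply(seq_len(k), function(t) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    pairing <- if (na == nb && stats::runif(1) < 0.3) "positional" else
      "all_pairs"
    idx <- sample(n, na + nb)
    cv_term(sample(c("attractive", "repulsive"), 1),
            residue_group("a", idx[seq_len(na)]),
            residue_group("b", idx[na + seq_len(nb)]),
            cutoff = stats::runif(1, 4, 15), pairing = pairing)
  })
}

# two-residue toy complex with the pair a fixed distance apart
two_residue_structure <- function(distance = 20) {
  build_structure(data.frame(
    chain = c("A", "B"), resno = c(1, 1), resname = "GLY", atom = "CA",
    x = c(0, distance), y = 0, z = 0))
}

rotation_about_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# rigidly move every atom of a structure
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(s$atom[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2, t, "+")
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s
}
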