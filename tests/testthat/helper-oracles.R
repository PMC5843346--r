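# Independent oracles used by the tests; these deliberately avoid the code
# paths they check.

# Horn quaternion-method superposition: optimal RMSD from the largest
# eigenvalue of the 4x4 key matrix (independent of the SVD/Kabsch route).
quat_superpose_rmsd_A <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  K <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]),
    nrow = 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  G <- sum(Xc^2) + sum(Yc^2)
  sqrt(max(0, G - 2 * lmax) / nrow(X))
}

# orientational Boltzmann average of cos(theta) for a dipole in a uniform
# field (Langevin function)
langevin_fun <- function(x) 1 / tanh(x) - 1 / x

# random rotation matrix from a seeded quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# interpolated full width at half maximum of a sampled peak
measure_fwhm <- function(x, y) {
  h <- max(y) / 2
  i0 <- which.max(y)
  f <- stats::approxfun(x, y - h)
  left <- stats::uniroot(f, c(x[1], x[i0]))$root
  right <- stats::uniroot(f, c(x[i0], x[length(x)]))$root
  right - left
}

# a Lorentzian test band with the straight baseline through its window ends
# removed (so the periodic FFT extension is continuous)
lorentzian_band <- function(nu, center, fwhm) {
  y <- 1 / (1 + ((nu - center) / (fwhm / 2))^2)
  n <- length(nu)
  y - (y[1] + (nu - nu[1]) * (y[n] - y[1]) / (nu[n] - nu[1]))
}

# minimal fixed-column PDB content for parser tests
handcrafted_pdb_lines <- function() {
  c("HEADER    TEST",
    "ATOM      1  N   ALA A   1      11.104  13.207   2.100  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.560  13.300   2.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      13.000  14.700   1.500  1.00  0.00           C",
    "TER",
    "END")
}
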