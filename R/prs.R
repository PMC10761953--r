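#' @include elastic-network.R
NULL

#' Fibonacci-sphere unit force set
#'
#' Places M quasi-uniform unit vectors on the sphere with the golden-angle
#' lattice: z_k = 1 - 2(k + 0.5)/M and phi_k = k * pi * (3 - sqrt(5)) for
#' k = 0..M-1. Used to make per-residue perturbations isotropic; M = 100
#' is the default for scanning.
#'
#' @param M number of directions (>= 1).
#' @return a \linkS4class{ForceSet} with scheme "fibonacci"
#' @export
fibonacciForceSet <- function(M = 100L) {
  if (M < 1) stop("M must be >= 1")
  k <- seq_len(M) - 1
  z <- 1 - 2 * (k + 0.5) / M
  phi <- k * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(s * cos(phi), s * sin(phi), z)
  d <- d / sqrt(rowSums(d^2))  # guard rounding so norms are exactly 1
  new("ForceSet", directions = d, scheme = "fibonacci")
}

#' Analytic isotropic force scheme
#'
#' Stands for the exact M -> infinity limit of isotropic force averaging;
#' carries no sampled directions and makes \code{prsScan} use the
#' closed-form spherical average <|A u|^2> = tr(A^T A) / 3.
#'
#' @return a \linkS4class{ForceSet} with scheme "analytic"
#' @export
analyticForceSet <- function() {
  new("ForceSet", directions = diag(3), scheme = "analytic")
}

#' Linear response displacement field for one perturbation
#'
#' First-order response of the fluctuating network to an external force:
#' Delta R = (1/kT) C F, with F zero everywhere except the three entries
#' of the perturbed residue.
#'
#' @param cov \linkS4class{CovarianceModel}.
#' @param residue perturbed residue index (1..N).
#' @param force 3-vector (force units; kT scales out of normalized PRS).
#' @return N x 3 matrix of displacements
#' @export
lrtResponse <- function(cov, residue, force) {
  C <- cov@matrix
  n <- nrow(C) / 3
  if (residue < 1 || residue > n)
    stop(sprintf("residue %d out of range 1..%d", residue, n))
  force <- as.numeric(force)
  if (length(force) != 3 || any(!is.finite(force)))
    stop("force must be a finite 3-vector")
  ii <- (3 * residue - 2):(3 * residue)
  dr <- (C[, ii, drop = FALSE] %*% force) / cov@kT
  matrix(dr, ncol = 3, byrow = TRUE)
}

#' Perturbation response scan
#'
#' Applies every force direction at every residue and propagates each
#' through linear response theory. Element (i, j) of the response is the
#' mean squared displacement magnitude at residue j under perturbation of
#' residue i: (1/M) sum_m |C_block(j,i) u_m|^2 / kT^2. With the
#' "analytic" scheme the exact isotropic limit tr(A^T A)/3 replaces the
#' sampled average. Rows are then normalized by the self-response so the
#' diagonal is exactly 1; effector/sensor profiles are the off-diagonal
#' row/column means of the normalized matrix.
#'
#' @param cov \linkS4class{CovarianceModel}.
#' @param forces \linkS4class{ForceSet} (default 100 Fibonacci directions).
#' @return a \linkS4class{PRSResult}
#' @export
prsScan <- function(cov, forces = fibonacciForceSet(100L)) {
  C <- cov@matrix
  n <- nrow(C) / 3
  kT <- cov@kT
  ## second-moment matrix of the directions: the sampled mean of |A u|^2
  ## equals tr(A S A^T); the analytic limit has S = I/3
  if (forces@scheme == "analytic") {
    S <- diag(3) / 3
    M <- nrow(forces@directions)
  } else {
    U <- forces@directions
    M <- nrow(U)
    S <- crossprod(U) / M
  }
  Rchol <- chol(S + diag(3) * 1e-15)
  resp <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    Ci <- C[, ii, drop = FALSE] %*% t(Rchol)   # 3N x 3
    sq <- rowSums(Ci^2)
    resp[i, ] <- colSums(matrix(sq, nrow = 3)) / kT^2
  }
  d <- diag(resp)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1]
    stop(sprintf("degenerate covariance: zero self-response at residue %d", bad))
  }
  Z <- resp / d       # row-wise division (column recycling over rows)
  diag(Z) <- 1        # exact unit diagonal
  eff <- (rowSums(Z) - 1) / (n - 1)
  sen <- (colSums(Z) - 1) / (n - 1)
  new("PRSResult", response = resp, normalized = Z,
      effectorProfile = eff, sensorProfile = sen,
      nForces = as.integer(M), scheme = forces@scheme)
}

#' Key effector residues by z-score
#'
#' Scores each residue's effector profile against the profile mean and
#' standard deviation; residues above \code{zThreshold} are returned in
#' descending score order (ties by ascending residue index). A constant
#' profile has no outliers and returns an empty table with a warning.
#'
#' @param result \linkS4class{PRSResult}.
#' @param zThreshold z-score cutoff (default 1.0; exposed, not hard-coded).
#' @return data.frame(residue, zscore), possibly empty
#' @export
keyResidues <- function(result, zThreshold = 1.0) {
  p <- result@effectorProfile
  s <- stats::sd(p)
  if (!is.finite(s) || s == 0) {
    warning("constant effector profile: no key residues")
    return(data.frame(residue = integer(0), zscore = numeric(0)))
  }
  z <- (p - mean(p)) / s
  sel <- which(z > zThreshold)
  ord <- sel[order(-z[sel], sel)]
  data.frame(residue = ord, zscore = z[ord])
}
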