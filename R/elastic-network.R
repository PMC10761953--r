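#' @include structure-io.R
NULL

## contact pairs (i < j) within cutoff, by full pairwise distance scan
.contact_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], d = d[idx])
}

.is_connected <- function(n, pairs) {
  if (n == 1) return(TRUE)
  if (nrow(pairs) == 0) return(FALSE)
  g <- igraph::graph_from_edgelist(as.matrix(pairs[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$no == 1
}

#' Build the anisotropic network model Hessian
#'
#' Represents the CA trace as beads joined by identical Hookean springs for
#' every pair within \code{cutoff}. The 3x3 super-element for a contacting
#' pair (i, j) is -gamma * (d d^T) / |d|^2 with d = r_j - r_i; diagonal
#' super-elements enforce zero row sums (translational invariance).
#'
#' @param caModel CA-only \linkS4class{StructureModel} (or an N x 3 matrix).
#' @param cutoff contact cutoff r_c in Angstrom (default 13).
#' @param gamma uniform spring constant (default 1; PRS output is
#'   normalized so the absolute scale cancels).
#' @return an \linkS4class{ElasticNetwork}
#' @export
buildANMHessian <- function(caModel, cutoff = 13, gamma = 1) {
  pos <- if (is(caModel, "StructureModel")) coords(caModel) else as.matrix(caModel)
  n <- nrow(pos)
  if (n < 3) stop("need at least 3 CA positions")
  if (cutoff <= 0) stop("cutoff must be positive")
  ## collinearity: rank of centered coordinates must be >= 2
  if (qr(scale(pos, scale = FALSE))$rank < 2)
    stop("collinear CA positions give a degenerate network (> 6 zero modes)")
  pairs <- .contact_pairs(pos, cutoff)
  if (!.is_connected(n, pairs))
    stop(sprintf("contact graph disconnected at cutoff %.2f A", cutoff))
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    d <- pos[j, ] - pos[i, ]
    blk <- -gamma * tcrossprod(d) / sum(d^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  new("ElasticNetwork", positions = pos, cutoff = cutoff, gamma = gamma,
      hessian = H)
}

#' Pseudo-inverse covariance of an elastic network
#'
#' Eigendecomposes the ANM Hessian, removes exactly the six smallest-
#' magnitude (rigid-body) modes, and assembles
#' C = kT * sum_k lambda_k^-1 v_k v_k^T over the remaining modes. Errors
#' loudly if the count of near-zero eigenvalues differs from six, which
#' signals a disconnected or degenerate geometry rather than silently
#' inverting noise.
#'
#' @param network \linkS4class{ElasticNetwork}.
#' @param kT thermal-energy scale (default 1).
#' @param zeroModeTol eigenvalues below zeroModeTol * max(lambda) count as
#'   zero modes (default 1e-8).
#' @return a \linkS4class{CovarianceModel} with source "anm"
#' @export
anmCovariance <- function(network, kT = 1, zeroModeTol = 1e-8) {
  H <- network@hessian
  eig <- eigen(H, symmetric = TRUE)
  lam <- eig$values  # descending
  lmax <- max(abs(lam))
  nzero <- sum(abs(lam) < zeroModeTol * lmax)
  if (nzero != 6)
    stop(sprintf("expected 6 zero modes, found %d (disconnected or degenerate geometry)",
                 nzero))
  keep <- seq_len(length(lam) - 6)
  V <- eig$vectors[, keep, drop = FALSE]
  C <- kT * V %*% (t(V) / lam[keep])
  C <- (C + t(C)) / 2
  new("CovarianceModel", matrix = C, kT = kT, source = "anm",
      nZeroModesRemoved = 6L)
}

## internal: Kabsch rotation/translation (defined with the trajectory
## metrics, used here for superposition)

.iterated_mean_superpose <- function(frameList, passes = 2L) {
  ## superpose all frames onto an iteratively refined mean structure;
  ## two passes remove the dependence on frame order
  ref <- frameList[[1]]
  aligned <- frameList
  for (p in seq_len(passes)) {
    mean_xyz <- Reduce(`+`, aligned) / length(aligned)
    ref <- mean_xyz
    aligned <- lapply(frameList, function(f) .kabsch_apply(f, ref))
  }
  aligned
}

#' Positional covariance from a conformational ensemble
#'
#' Superposes every frame onto the mean structure (mean refined over two
#' superposition passes), then computes the population covariance of the
#' flattened 3N coordinates: C = (1/F) * sum_f (x_f - xbar)(x_f - xbar)^T.
#'
#' @param ensemble \linkS4class{CoordinateEnsemble} with a CA-only topology
#'   and at least two frames.
#' @return a \linkS4class{CovarianceModel} with source "ensemble"
#' @export
ensembleCovariance <- function(ensemble) {
  F_ <- nFrames(ensemble)
  if (F_ < 2) stop("need at least 2 frames for an ensemble covariance")
  aligned <- .iterated_mean_superpose(frames(ensemble))
  X <- do.call(rbind, lapply(aligned, function(f) as.vector(t(f))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / F_
  C <- (C + t(C)) / 2
  new("CovarianceModel", matrix = C, kT = 1, source = "ensemble",
      nZeroModesRemoved = 0L)
}

#' Export a Hessian or covariance as TSV
#'
#' Row-major numeric TSV preceded by a comment header recording N, the
#' source and kT where applicable.
#'
#' @param x ElasticNetwork or CovarianceModel.
#' @param path output file.
#' @export
exportMatrixTSV <- function(x, path) {
  if (is(x, "ElasticNetwork")) {
    M <- x@hessian
    hdr <- sprintf("# ANM hessian N=%d cutoff=%g gamma=%g",
                   nrow(x@positions), x@cutoff, x@gamma)
  } else if (is(x, "CovarianceModel")) {
    M <- x@matrix
    hdr <- sprintf("# covariance N=%d source=%s kT=%g",
                   nrow(M) / 3, x@source, x@kT)
  } else stop("unsupported object for TSV export")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(M, digits = 6, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
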