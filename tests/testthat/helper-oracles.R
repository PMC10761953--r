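## Independent oracles and small builders shared across the suite.

## quaternion (Horn) method for optimal superposition RMSD — independent
## of the SVD-based implementation under test
quaternion_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(X, Y)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  mu <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * mu) / nrow(X)
  sqrt(max(0, msd))
}

## exhaustive simple-path search with the same tie rules as the package
## contract: min total weight, then fewest nodes, then lexicographically
## smallest node sequence. Returns NULL if no path exists.
enumerate_best_path <- function(n, edgeDf, source, sink) {
  adj <- vector("list", n)
  wmap <- new.env()
  for (k in seq_len(nrow(edgeDf))) {
    i <- edgeDf$i[k]; j <- edgeDf$j[k]; w <- edgeDf$weight[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
    assign(paste(min(i, j), max(i, j)), w, envir = wmap)
  }
  best <- NULL
  rec <- function(node, visited, path, weight) {
    if (node == sink) {
      cand <- list(nodes = path, weight = weight)
      if (is.null(best)) best <<- cand
      else {
        if (cand$weight < best$weight - 1e-12) best <<- cand
        else if (abs(cand$weight - best$weight) <= 1e-12) {
          if (length(cand$nodes) < length(best$nodes)) best <<- cand
          else if (length(cand$nodes) == length(best$nodes)) {
            for (q in seq_along(cand$nodes)) {
              if (cand$nodes[q] < best$nodes[q]) { best <<- cand; break }
              if (cand$nodes[q] > best$nodes[q]) break
            }
          }
        }
      }
      return()
    }
    for (nb in adj[[node]]) {
      if (visited[nb]) next
      visited[nb] <- TRUE
      rec(nb, visited, c(path, nb),
          weight + get(paste(min(node, nb), max(node, nb)), envir = wmap))
      visited[nb] <- FALSE
    }
  }
  visited <- rep(FALSE, n)
  visited[source] <- TRUE
  rec(source, visited, source, 0)
  best
}

## random connected-ish undirected weighted graph as a ResidueGraph
random_graph <- function(n, p = 0.45, wmin = 0.1, wmax = 2) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  e <- data.frame(i = as.integer(pairs[keep, 1]),
                  j = as.integer(pairs[keep, 2]),
                  weight = stats::runif(sum(keep), wmin, wmax))
  new("ResidueGraph", nNodes = as.integer(n), edges = e,
      contactCutoff = 0, weighting = "unit")
}

## write a minimal fixed-column PDB ATOM record
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          element = "") {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, paste0(" ", name), resname, chain, resid, x, y, z, element)
}

## all-atom water-like toy topology for H-bond tests: donor O, its H, and
## an acceptor O placed per-frame by the caller
hbond_toy_ensemble <- function(acceptor_positions) {
  atoms <- data.frame(
    serial = 1:3, name = c("O", "H1", "OXT"), element = c("O", "H", "O"),
    resname = c("HOH", "HOH", "HOH"), resid = c(1L, 1L, 2L),
    chain = "A", stringsAsFactors = FALSE)
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  topo <- StructureModel(atoms, base)
  frames <- lapply(acceptor_positions, function(a) {
    f <- base; f[3, ] <- a; f
  })
  CoordinateEnsemble(topo, frames)
}

## analytic exposed area of two overlapping equal spheres (radius R,
## centre separation d < 2R): per sphere 4 pi R^2 minus the buried cap
two_sphere_area <- function(R, d) {
  h <- R - d / 2
  cap <- 2 * pi * R * h
  2 * (4 * pi * R^2 - cap)
}
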