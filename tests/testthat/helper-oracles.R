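# Independent oracles and fixture builders shared across tests.

# Build wwPDB-format ATOM/HETATM lines (fixed columns) for handmade fixtures.
pdb_line <- function(eleno, elety, resid, chain, resno, x, y, z,
                     b = 0, occ = 1, alt = "", icode = "", type = "ATOM",
                     element = substr(trimws(elety), 1, 1)) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, elety, alt, resid, chain, resno, icode,
          x, y, z, occ, b, element)
}

# Minimal CA-only PDB text for a trace-like data frame.
pdb_from_coords <- function(resno, x, y, z, b = 0, resid = "ALA",
                            chain = "A") {
  n <- length(resno)
  paste(pdb_line(seq_len(n), "CA", rep_len(resid, n), chain, resno,
                 x, y, z, rep_len(b, n)),
        collapse = "\n")
}

# O(n^2) brute-force contact matrix.
brute_contacts <- function(xyz, cutoff) {
  n <- nrow(xyz)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) C[i, j] <- 1
  }
  C
}

# Literal double-loop energy response from a correlation matrix and contacts.
brute_energy_response <- function(M, C) {
  n <- nrow(M)
  du <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (C[i, j] == 1)
        du[i] <- du[i] + (M[i, i] - 2 * M[i, j] + M[j, j])
    }
  }
  du
}

# Breadth-first-search hop distances from a source over a 0/1 adjacency.
bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(A[v, ] == 1 & d == Inf)
    d[nb] <- d[v] + 1
    queue <- c(queue, nb)
  }
  d
}

# Connected-component count over a 0/1 adjacency, via repeated BFS.
n_components <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  k <- 0
  while (any(!seen)) {
    k <- k + 1
    seen[is.finite(bfs_dist(A, which(!seen)[1]))] <- TRUE
  }
  k
}

# 3-bead linear chain at canonical spacing: contacts 1-2 and 2-3 only.
three_bead_trace <- function() {
  generate_synthetic_trace(3, "linear", spacing = 3.8, noise_sd = 0)
}

random_trace <- function(n, seed) {
  generate_synthetic_trace(n, "perturbed-lattice", spacing = 4.5,
                           noise_sd = 0.8, seed = seed)
}
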