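# Circular (Morgan-style) fingerprints hashed onto a fixed-length bit vector,
# and Tanimoto similarity.  The hashing scheme follows the ECFP recipe: atom
# invariants are iteratively combined with sorted neighbour (bond order,
# invariant) pairs for `radius` rounds, and every environment identifier seen
# along the way sets one bit modulo the vector length.

# Deterministic 31-bit integer hash of an integer vector (djb2 variant).
# All arithmetic stays below 2^53 so it is exact in doubles.
.hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483648
  h
}

#' Circular fingerprint of a molecule
#'
#' Computes an ECFP-like circular fingerprint of the heavy-atom graph.  The
#' initial invariant of an atom encodes its atomic number, degree, formal
#' charge, implicit hydrogen count and ring membership; each iteration up to
#' `radius` rehashes the invariant together with the sorted (bond order,
#' neighbour invariant) pairs, so a radius-3 fingerprint encodes atom
#' environments up to 3 bonds away.
#'
#' @param mol A `mol_graph` as returned by [standardize_structure()], or a
#'   SMILES string (standardized internally).
#' @param n_bits Length of the bit vector (default 1024).
#' @param radius Neighbourhood radius (default 3).
#' @return Integer vector of 0/1 of length `n_bits`.
#' @examples
#' \donttest{
#' fp <- compute_fingerprint("c1ccccc1")
#' length(fp)   # 1024
#' sum(fp)      # number of set bits
#' }
#' @export
compute_fingerprint <- function(mol, n_bits = 1024L, radius = 3L) {
  if (is.character(mol)) {
    std <- standardize_structure(mol)
    if (!std$ok) stop("cannot standardize SMILES: ", std$reason)
    mol <- std$mol
  }
  stopifnot(inherits(mol, "mol_graph"), n_bits >= 1, radius >= 0)

  n <- mol$n_atoms
  z <- .ATOMIC_NUMBER[mol$symbol]
  z[is.na(z)] <- 0
  inv <- vapply(seq_len(n), function(i) {
    .hash_ints(c(z[i], mol$degree[i], mol$charge[i], mol$h_count[i],
                 as.integer(mol$in_ring[i])))
  }, numeric(1))

  # adjacency with bond orders
  nbrs <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]; o <- mol$bonds$order[b]
    nbrs[[a1]] <- rbind(nbrs[[a1]], c(a2, o))
    nbrs[[a2]] <- rbind(nbrs[[a2]], c(a1, o))
  }

  all_ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_inv <- inv
      for (i in seq_len(n)) {
        nb <- nbrs[[i]]
        if (is.null(nb)) next
        pairs <- cbind(nb[, 2], inv[nb[, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        new_inv[i] <- .hash_ints(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
      }
      inv <- new_inv
      all_ids <- c(all_ids, inv)
    }
  }

  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1] <- 1L
  bits
}

#' Tanimoto similarity of two bit vectors
#'
#' \eqn{|a \wedge b| / |a \vee b|}; defined as 1 when both vectors are empty
#' (two structures with no set bits are indistinguishable).
#'
#' @param a,b Integer/logical 0-1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 1), c(0, 1, 1, 1))  # 2 shared / 4 in union = 0.5
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Fingerprint matrix for a set of molecules
#'
#' @param mols List of `mol_graph` objects.
#' @param n_bits,radius Passed to [compute_fingerprint()].
#' @return Integer matrix (molecules x bits) with columns `fp0001`, ...
#' @export
fingerprint_matrix <- function(mols, n_bits = 1024L, radius = 3L) {
  m <- t(vapply(mols, compute_fingerprint, integer(n_bits),
                n_bits = n_bits, radius = radius))
  colnames(m) <- sprintf("fp%04d", seq_len(n_bits))
  m
}

#' Maximum Tanimoto similarity against a reference fingerprint matrix
#'
#' @param fp A single fingerprint (0/1 vector).
#' @param ref_fps Matrix of reference fingerprints (rows = molecules).
#' @return List with `tc` (max similarity) and `idx` (row index of the most
#'   similar reference; first one on ties).
#' @keywords internal
nearest_tanimoto <- function(fp, ref_fps) {
  fp <- as.numeric(fp)
  inter <- as.numeric(ref_fps %*% fp)
  un <- rowSums(ref_fps) + sum(fp) - inter
  tc <- ifelse(un == 0, 1, inter / un)
  idx <- which.max(tc)
  list(tc = tc[idx], idx = idx)
}
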