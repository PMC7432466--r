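# Molecular descriptors and the feature-matrix plumbing.  Physicochemical
# properties (MW, logP, TPSA, MR, hydrogen-bond counts) come from OpenBabel;
# topological descriptors are computed on the heavy-atom graph.  The final
# feature representation of a compound is the variance-filtered descriptor
# block concatenated with the 1024-bit circular fingerprint.

# Topological descriptors from the internal graph.
.graph_descriptors <- function(mol) {
  sym <- mol$symbol
  deg <- mol$degree
  bonds <- mol$bonds
  n <- mol$n_atoms

  n_hal <- sum(sym %in% c("F", "Cl", "Br", "I"))
  n_rings <- cycle_rank(mol)
  rot <- 0L
  if (nrow(bonds) > 0) {
    rot <- sum(bonds$order == 1 & !mol$ring_bond &
                 deg[bonds$a1] > 1 & deg[bonds$a2] > 1)
  }

  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  chi1 <- if (nrow(bonds)) sum(1 / sqrt(deg[bonds$a1] * deg[bonds$a2])) else 0

  wiener <- 0; diam <- 0
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    d <- igraph::distances(g)
    fin <- d[upper.tri(d)]
    fin <- fin[is.finite(fin)]
    wiener <- sum(fin)
    diam <- if (length(fin)) max(fin) else 0
  }

  c(
    n_heavy      = n,
    n_carbon     = sum(sym == "C"),
    n_nitrogen   = sum(sym == "N"),
    n_oxygen     = sum(sym == "O"),
    n_sulfur     = sum(sym == "S"),
    n_halogen    = n_hal,
    n_hetero     = sum(!sym %in% c("C", "H")),
    frac_hetero  = if (n) sum(!sym %in% c("C", "H")) / n else 0,
    n_h_total    = sum(mol$h_count),
    n_bonds      = nrow(bonds),
    n_double     = sum(bonds$order == 2),
    n_triple     = sum(bonds$order == 3),
    n_rings      = n_rings,
    n_ring_atoms = sum(mol$in_ring),
    n_rot_bonds  = rot,
    max_degree   = if (n) max(deg) else 0,
    mean_degree  = if (n) mean(deg) else 0,
    n_branch     = sum(deg >= 3),
    zagreb       = sum(deg^2),
    chi0         = chi0,
    chi1         = chi1,
    wiener       = wiener,
    graph_diameter = diam,
    mw_graph     = mol_weight(mol)
  )
}

#' Compute molecular descriptors for one structure
#'
#' Returns a named vector combining OpenBabel bulk properties (molecular
#' weight, logP, topological polar surface area, molar refractivity,
#' hydrogen-bond acceptor/donor counts, fluorine count) with topological
#' descriptors of the heavy-atom graph (atom/bond/ring counts, connectivity
#' chi indices, Zagreb and Wiener indices, rotatable bonds).  All descriptors
#' are deterministic functions of the standardized structure.
#'
#' @param mol A `mol_graph`, or a SMILES string (standardized internally).
#' @return Named numeric vector; entries may be non-finite if an individual
#'   descriptor fails (filtered later at matrix level).
#' @examples
#' \donttest{
#' d <- compute_descriptors("CCO")
#' d[["MW"]]   # 46.07
#' }
#' @export
compute_descriptors <- function(mol) {
  if (is.character(mol)) {
    std <- standardize_structure(mol)
    if (!std$ok) stop("cannot standardize SMILES: ", std$reason)
    mol <- std$mol
  }
  stopifnot(inherits(mol, "mol_graph"))
  ob <- tryCatch(
    ChemmineR::propOB(suppressWarnings(ChemmineR::smiles2sdf(mol$smiles))),
    error = function(e) NULL
  )
  if (is.null(ob)) {
    obd <- c(MW = NA_real_, logP = NA_real_, TPSA = NA_real_, MR = NA_real_,
             HBA = NA_real_, HBD = NA_real_, nF = NA_real_)
  } else {
    obd <- c(MW = ob$MW[1], logP = ob$logP[1], TPSA = ob$TPSA[1],
             MR = ob$MR[1], HBA = ob$HBA2[1], HBD = ob$HBD[1], nF = ob$nF[1])
  }
  c(obd, .graph_descriptors(mol))
}

#' Descriptor matrix for a set of molecules
#'
#' @param mols List of `mol_graph` objects.
#' @return Numeric matrix (molecules x descriptors).
#' @export
descriptor_matrix <- function(mols) {
  t(vapply(mols, compute_descriptors,
           compute_descriptors(mols[[1]]) * NA_real_))
}

#' Variance-filter a descriptor matrix
#'
#' Removes descriptor columns whose population variance (dividing by n) falls
#' below `min_variance` or that contain any non-finite value.  The surviving
#' column names form a mask that must be re-applied to any compounds
#' featurized later, so screening-time compounds live in exactly the feature
#' space the model was trained in.
#'
#' @param m Numeric matrix (compounds x descriptors) with column names.
#' @param min_variance Minimum population variance to retain a column
#'   (default 0.05).
#' @return List with `matrix` (filtered), `keep` (retained column names) and
#'   `variance` (named vector of population variances, NA where non-finite
#'   values occurred).
#' @export
filter_descriptor_matrix <- function(m, min_variance = 0.05) {
  stopifnot(is.matrix(m), nrow(m) >= 1, !is.null(colnames(m)))
  finite_ok <- apply(m, 2, function(x) all(is.finite(x)))
  pvar <- rep(NA_real_, ncol(m))
  names(pvar) <- colnames(m)
  pvar[finite_ok] <- apply(m[, finite_ok, drop = FALSE], 2, function(x) {
    mean((x - mean(x))^2)
  })
  keep <- finite_ok & !is.na(pvar) & pvar >= min_variance
  if (!any(keep)) stop("variance filter removed every descriptor column")
  list(matrix = m[, keep, drop = FALSE], keep = colnames(m)[keep],
       variance = pvar)
}

#' Featurize standardized compounds
#'
#' Computes the descriptor matrix and circular fingerprint matrix for a set
#' of standardized structures.  No variance filtering is applied here; the
#' filter mask is learned on a training set (see
#' [filter_descriptor_matrix()]) and applied at model-assembly time.
#'
#' @param mols List of `mol_graph` objects (from [standardize_structures()]).
#' @param ids Optional character vector of compound identifiers used as
#'   rownames.
#' @param n_bits,radius Fingerprint parameters.
#' @return List of class `feature_set` with `descriptors`, `fingerprints`
#'   matrices and `ids`.
#' @export
featurize_compounds <- function(mols, ids = NULL, n_bits = 1024L,
                                radius = 3L) {
  stopifnot(length(mols) >= 1)
  desc <- descriptor_matrix(mols)
  fps <- fingerprint_matrix(mols, n_bits = n_bits, radius = radius)
  if (!is.null(ids)) {
    rownames(desc) <- ids
    rownames(fps) <- ids
  }
  structure(list(descriptors = desc, fingerprints = fps,
                 ids = ids %||% rownames(desc)),
            class = "feature_set")
}

#' Assemble the model feature matrix
#'
#' Applies a frozen descriptor mask and concatenates the fingerprint block.
#'
#' @param features A `feature_set`.
#' @param keep Character vector of descriptor columns to retain (the variance
#'   mask learned on training data).
#' @return Numeric matrix `[descriptors[, keep], fingerprints]`.
#' @export
assemble_features <- function(features, keep) {
  stopifnot(inherits(features, "feature_set"))
  missing_cols <- setdiff(keep, colnames(features$descriptors))
  if (length(missing_cols))
    stop("feature space mismatch; missing descriptors: ",
         paste(missing_cols, collapse = ", "))
  cbind(features$descriptors[, keep, drop = FALSE], features$fingerprints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
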