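# Structure handling: SMILES parsing, standardization, InChIKeys and the
# internal molecular-graph representation used by the fingerprint and
# descriptor code.  Format conversion and canonicalization are delegated to
# OpenBabel through ChemmineOB; graphs are read from ChemmineR SDF objects.

# Elements treated as metals for the purpose of rejecting metal complexes
# during curation (alkali/alkaline earth, transition metals, post-transition
# metals and metalloids heavier than B/Si are all included).
.METALS <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc",
  "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Cs", "Ba", "La", "Ce",
  "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po"
)

.ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904
)

# Typical valences used to infer implicit hydrogen counts from a kekulized
# connection table; for S and P the smallest typical valence that covers the
# explicit bond order sum is used.
.VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5), S = c(2, 4, 6),
  Cl = 1, Br = 1, I = 1, H = 1
)

#' Canonical SMILES via OpenBabel
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string, or `NA_character_` if the input could
#'   not be parsed.
#' @keywords internal
ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

#' InChIKey via OpenBabel
#' @inheritParams ob_canonical
#' @return InChIKey string or `NA_character_`.
#' @keywords internal
ob_inchikey <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "INCHIKEY", paste0(smiles, "\n")),
    error = function(e) ""
  )
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

# Old-style MDL charge codes in the SDF atom block.
.CHARGE_CODE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                  `6` = -2, `7` = -3)

#' Parse a SMILES string into the internal molecular graph
#'
#' The graph stores heavy atoms only; implicit hydrogen counts are inferred
#' from typical valences on the kekulized connection table.  Ring membership
#' is derived from the bridge structure of the bond graph.
#'
#' @param smiles A single SMILES string (ideally already canonical).
#' @return A list of class `mol_graph` with elements `symbol`, `charge`,
#'   `h_count`, `degree`, `in_ring`, `bonds` (data.frame `a1`, `a2`, `order`),
#'   `n_atoms` and `smiles`, or `NULL` when the SMILES cannot be parsed.
#' @keywords internal
parse_mol <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf)) return(NULL)
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  symbol <- sub("_.*$", "", rownames(ab))
  n <- length(symbol)
  charge_code <- if (ncol(ab) >= 5) as.integer(ab[, 5]) else integer(n)
  charge <- unname(.CHARGE_CODE[as.character(charge_code)])
  charge[is.na(charge)] <- 0L

  if (is.null(dim(bb)) && length(bb) >= 3) bb <- matrix(bb, nrow = 1)
  if (is.null(bb) || length(bb) == 0 || NROW(bb) == 0 || NCOL(bb) < 3) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }

  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  bond_sum <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    o <- bonds$order[i]
    bond_sum[bonds$a1[i]] <- bond_sum[bonds$a1[i]] + o
    bond_sum[bonds$a2[i]] <- bond_sum[bonds$a2[i]] + o
  }

  h_count <- integer(n)
  for (i in seq_len(n)) {
    vals <- .VALENCES[[symbol[i]]]
    if (is.null(vals)) { h_count[i] <- 0L; next }
    eff <- vals + charge[i]
    eff <- eff[eff >= bond_sum[i]]
    h_count[i] <- if (length(eff)) as.integer(min(eff) - bond_sum[i]) else 0L
  }

  in_ring <- rep(FALSE, n)
  ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    if (any(ring_bond)) {
      ring_atoms <- unique(c(bonds$a1[ring_bond], bonds$a2[ring_bond]))
      in_ring[ring_atoms] <- TRUE
    }
  }

  structure(
    list(symbol = symbol, charge = charge, h_count = h_count,
         degree = degree, in_ring = in_ring, bonds = bonds,
         ring_bond = ring_bond, n_atoms = n, smiles = smiles),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n  atoms: ", x$n_atoms,
      "  bonds: ", nrow(x$bonds),
      "  rings (cycle rank): ", cycle_rank(x), "\n", sep = "")
  invisible(x)
}

# Number of independent cycles (SSSR count) of the heavy-atom graph.
cycle_rank <- function(mol) {
  n_comp <- n_components(mol)
  nrow(mol$bonds) - mol$n_atoms + n_comp
}

n_components <- function(mol) {
  if (nrow(mol$bonds) == 0) return(mol$n_atoms)
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2),
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$n_atoms)
    g <- igraph::add_vertices(g, mol$n_atoms - igraph::vcount(g))
  igraph::components(g)$no
}

#' Molecular weight of a parsed structure
#'
#' Average atomic masses over heavy atoms plus implicit hydrogens.
#'
#' @param mol A `mol_graph`.
#' @return Molecular weight in daltons.
#' @keywords internal
mol_weight <- function(mol) {
  m <- .ATOMIC_MASS[mol$symbol]
  m[is.na(m)] <- 0
  sum(m) + sum(mol$h_count) * .ATOMIC_MASS[["H"]]
}

#' Standardize a molecular structure
#'
#' Canonicalizes a SMILES string with OpenBabel, strips salts and solvents by
#' keeping the largest organic fragment, and derives the InChIKey used as the
#' structure identity key throughout curation.  Two different encodings of the
#' same molecule yield the same InChIKey.  Metal complexes, polymeric
#' structures (attachment points), fragment-free inputs and unparseable text
#' are rejected with a reason code, matching the structure-removal step of the
#' curation funnel.
#'
#' @param smiles A single SMILES string (may be `NA` or empty).
#' @return A list with elements `ok` (logical), and on success `smiles`
#'   (canonical SMILES of the parent fragment), `inchikey`, and `mol` (the
#'   parsed `mol_graph`); on failure `reason`, one of `"no_structure"`,
#'   `"polymer"`, `"unparseable"`, `"metal_complex"`, `"inorganic"`.
#' @examples
#' \donttest{
#' standardize_structure("CCO")$inchikey
#' standardize_structure("OCC")$inchikey     # same key, different encoding
#' standardize_structure("")$reason          # "no_structure"
#' }
#' @export
standardize_structure <- function(smiles) {
  fail <- function(reason) list(ok = FALSE, reason = reason,
                                smiles = NA_character_,
                                inchikey = NA_character_, mol = NULL)
  if (length(smiles) != 1) stop("standardize_structure() takes one SMILES")
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(fail("no_structure"))
  smiles <- trimws(smiles)
  if (grepl("*", smiles, fixed = TRUE)) return(fail("polymer"))

  can <- ob_canonical(smiles)
  if (is.na(can)) return(fail("unparseable"))

  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) return(fail("unparseable"))
  if (length(frags) > 1) {
    mols <- lapply(frags, parse_mol)
    if (any(vapply(mols, is.null, logical(1)))) return(fail("unparseable"))
    sizes <- vapply(mols, function(m) m$n_atoms, numeric(1))
    parent <- frags[[which.max(sizes)]]
    mol <- mols[[which.max(sizes)]]
  } else {
    parent <- frags[[1]]
    mol <- parse_mol(parent)
    if (is.null(mol)) return(fail("unparseable"))
  }

  if (any(mol$symbol %in% .METALS)) return(fail("metal_complex"))
  if (!any(mol$symbol == "C")) return(fail("inorganic"))

  parent_can <- ob_canonical(parent)
  if (is.na(parent_can)) return(fail("unparseable"))
  key <- ob_inchikey(parent_can)
  if (is.na(key)) return(fail("unparseable"))
  if (!identical(parent_can, parent)) {
    mol <- parse_mol(parent_can)
    if (is.null(mol)) return(fail("unparseable"))
  }
  mol$smiles <- parent_can

  list(ok = TRUE, smiles = parent_can, inchikey = key, mol = mol,
       reason = NA_character_)
}

#' Standardize a vector of SMILES strings
#'
#' Vectorized wrapper around [standardize_structure()].
#'
#' @param smiles Character vector of SMILES (NA/empty allowed).
#' @return A [tibble::tibble] with columns `input`, `ok`, `smiles`,
#'   `inchikey`, `reason`, and a list-column `mol` of parsed graphs.
#' @export
standardize_structures <- function(smiles) {
  smiles <- as.character(smiles)
  uniq <- unique(smiles)
  res_u <- lapply(uniq, standardize_structure)
  res <- res_u[match(smiles, uniq)]
  tibble::tibble(
    input = smiles,
    ok = vapply(res, `[[`, logical(1), "ok"),
    smiles = vapply(res, `[[`, character(1), "smiles"),
    inchikey = vapply(res, `[[`, character(1), "inchikey"),
    reason = vapply(res, `[[`, character(1), "reason"),
    mol = lapply(res, `[[`, "mol")
  )
}
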