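# Activity-data curation: from a raw bioactivity export (one row per assay
# measurement) to a deduplicated per-target pKi dataset.  The funnel applies,
# in order: (1) load, (2) remove records without a standardizable structure,
# (3) keep confidence score >= 8, (4) keep records from large assays
# (documents with >= 10 records), (5) keep exact Ki-family measurements and
# convert to pKi, (6) merge replicate measurements per InChIKey when they are
# consistent, (7) remove compounds whose feature vectors are
# indistinguishable.  Every step's record count is kept in a curation report.

.DEFAULT_COLS <- c(
  smiles = "canonical_smiles",
  standard_type = "standard_type",
  standard_value = "standard_value",
  standard_units = "standard_units",
  standard_relation = "standard_relation",
  document_id = "document_chembl_id",
  confidence_score = "confidence_score",
  target = "target"
)

.DEFAULT_KI_TYPES <- c("Ki", "pKi", "logKi", "log Ki")

#' Load an activity-record table from CSV
#'
#' Reads a bioactivity export in the usual database schema (structure SMILES,
#' standard type/value/units/relation, source document identifier, assay
#' confidence score, target label).  Column names are configurable through
#' `col_map`.  Rows with unparseable numeric values are kept with `NA` values
#' and reported in the `row_errors` attribute; missing structures are
#' preserved as `NA` (they are removed later by the curation funnel, not
#' here).
#'
#' @param path Path to a CSV file.
#' @param col_map Named character vector mapping the internal field names
#'   (`smiles`, `standard_type`, `standard_value`, `standard_units`,
#'   `standard_relation`, `document_id`, `confidence_score`, `target`) to the
#'   file's column names.  Defaults to ChEMBL-style export names.
#' @return A [tibble::tibble] of activity records with the internal column
#'   names; attribute `row_errors` holds a tibble of rows whose numeric
#'   fields failed to parse.
#' @export
load_activity_table <- function(path, col_map = .DEFAULT_COLS) {
  if (!file.exists(path)) stop("file not found: ", path)
  col_map <- utils::modifyList(as.list(.DEFAULT_COLS), as.list(col_map))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(unlist(col_map), names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  df <- tibble::tibble(
    smiles = raw[[col_map$smiles]],
    standard_type = raw[[col_map$standard_type]],
    standard_value = suppressWarnings(as.numeric(raw[[col_map$standard_value]])),
    standard_units = raw[[col_map$standard_units]],
    standard_relation = raw[[col_map$standard_relation]],
    document_id = raw[[col_map$document_id]],
    confidence_score = suppressWarnings(as.integer(raw[[col_map$confidence_score]])),
    target = raw[[col_map$target]]
  )
  df$smiles[!is.na(df$smiles) & !nzchar(trimws(df$smiles))] <- NA_character_

  bad_value <- which(!is.na(raw[[col_map$standard_value]]) &
                       nzchar(raw[[col_map$standard_value]]) &
                       is.na(df$standard_value))
  bad_conf <- which(!is.na(raw[[col_map$confidence_score]]) &
                      nzchar(raw[[col_map$confidence_score]]) &
                      is.na(df$confidence_score))
  errs <- tibble::tibble(
    row = c(bad_value, bad_conf),
    field = c(rep("standard_value", length(bad_value)),
              rep("confidence_score", length(bad_conf)))
  )
  attr(df, "row_errors") <- errs
  df
}

#' Convert a Ki-family measurement to pKi
#'
#' Ki concentrations are normalized to molar units and transformed as
#' \eqn{-\log_{10}(K_i [\mathrm{M}])}, so 1 nM corresponds to pKi 9.  Values
#' already on the pKi scale pass through unchanged; `logKi` (log10 of molar
#' Ki) is negated.
#'
#' @param value Numeric measurement value.
#' @param unit Unit label for Ki-type values (`"nM"`, `"uM"`/`"µM"`,
#'   `"mM"`, `"pM"`, `"M"`); ignored for pKi/logKi types.
#' @param standard_type Measurement type: `"Ki"`, `"pKi"`, `"logKi"` or
#'   `"log Ki"` (case-insensitive).
#' @return The pKi value.
#' @examples
#' to_pki(1, "nM", "Ki")    # 9
#' to_pki(50, "nM", "Ki")   # 7.301
#' to_pki(7.2, NA, "pKi")   # 7.2
#' @export
to_pki <- function(value, unit, standard_type = "Ki") {
  type <- tolower(gsub(" ", "", standard_type))
  if (type == "pki") return(value)
  if (type == "logki") return(-value)
  if (type != "ki") stop("not a Ki-family standard type: ", standard_type)
  if (is.na(value) || value <= 0)
    stop("Ki value must be positive, got ", value)
  scale <- c(pm = 1e-12, nm = 1e-9, um = 1e-6, mm = 1e-3, m = 1)
  u <- tolower(trimws(unit))
  u[u == "µm"] <- "um"
  if (is.na(u) || !u %in% names(scale)) stop("unrecognized unit: ", unit)
  -log10(value * scale[[u]])
}

# Vectorized, non-throwing version used inside the pipeline: returns NA where
# conversion is impossible.
.to_pki_safe <- function(value, unit, standard_type) {
  vapply(seq_along(value), function(i) {
    tryCatch(to_pki(value[i], unit[i], standard_type[i]),
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Filter activity records (curation funnel steps 2-5)
#'
#' Applies, in order: removal of records without a standardizable structure
#' (step 2); the assay confidence-score cut (step 3); the large-assay rule
#' keeping only documents that still group `min_assay_size` or more records
#' (step 4); and the Ki-family standard-type cut, which also drops censored
#' measurements (relation other than `"="`) and records whose value cannot be
#' converted to pKi (step 5).  The step order matters: assay sizes are counted
#' after the structure and confidence removals.
#'
#' @param records Activity-record tibble (see [load_activity_table()]).
#' @param min_confidence Minimum confidence score (default 8).
#' @param min_assay_size Minimum number of records per document (default 10).
#' @param ki_types Accepted standard types, case-insensitive (default
#'   `c("Ki", "pKi", "logKi", "log Ki")`).
#' @param std Optional precomputed [standardize_structures()] result for
#'   `records$smiles` (avoids recomputation in the pipeline wrapper).
#' @return Tibble of retained records with added columns `inchikey`,
#'   `smiles_std`, `pki` and list-column `mol`; attribute `steps` holds the
#'   named record counts after each step.
#' @export
filter_records <- function(records, min_confidence = 8, min_assay_size = 10,
                           ki_types = .DEFAULT_KI_TYPES, std = NULL) {
  stopifnot(min_confidence >= 0, min_confidence <= 9, min_assay_size >= 1)
  steps <- c(loaded = nrow(records))

  if (is.null(std)) std <- standardize_structures(records$smiles)
  records$inchikey <- std$inchikey
  records$smiles_std <- std$smiles
  records$mol <- std$mol
  records <- records[std$ok, , drop = FALSE]
  steps <- c(steps, structures = nrow(records))

  records <- records[!is.na(records$confidence_score) &
                       records$confidence_score >= min_confidence, ,
                     drop = FALSE]
  steps <- c(steps, confidence = nrow(records))

  doc_sizes <- table(records$document_id)
  big <- names(doc_sizes)[doc_sizes >= min_assay_size]
  records <- records[records$document_id %in% big, , drop = FALSE]
  steps <- c(steps, assay_size = nrow(records))

  type_ok <- tolower(gsub(" ", "", records$standard_type)) %in%
    tolower(gsub(" ", "", ki_types))
  rel_ok <- !is.na(records$standard_relation) &
    records$standard_relation == "="
  records <- records[type_ok & rel_ok, , drop = FALSE]
  records$pki <- .to_pki_safe(records$standard_value, records$standard_units,
                              records$standard_type)
  records <- records[is.finite(records$pki), , drop = FALSE]
  steps <- c(steps, ki_type = nrow(records))

  attr(records, "steps") <- steps
  records
}

#' Merge replicate measurements per compound
#'
#' Records sharing an InChIKey are replicate measurements of one compound.
#' A replicate group is collapsed to its arithmetic-mean pKi when the
#' population standard deviation of the group is below `sd_fraction` of the
#' full pKi range of the dataset; groups with larger spread are considered
#' inconsistent and dropped entirely.  Singletons pass through unchanged.
#'
#' @param df Tibble with columns `inchikey` and `pki` (extra columns are
#'   carried through from each group's first record).
#' @param sd_fraction Consistency bound as a fraction of the dataset's pKi
#'   range (default 0.10).
#' @return Tibble with unique `inchikey`, mean `pki` and `n_merged`;
#'   attribute `dropped` lists the InChIKeys of inconsistent groups.
#' @export
merge_duplicates <- function(df, sd_fraction = 0.10) {
  stopifnot(nrow(df) >= 1, all(is.finite(df$pki)))
  rng <- diff(range(df$pki))
  groups <- split(seq_len(nrow(df)), df$inchikey)
  keep_rows <- integer(0)
  pki_mean <- numeric(0)
  n_merged <- integer(0)
  dropped <- character(0)
  for (key in names(groups)) {
    idx <- groups[[key]]
    x <- df$pki[idx]
    if (length(x) > 1) {
      pop_sd <- sqrt(mean((x - mean(x))^2))
      if (pop_sd >= sd_fraction * rng) {
        dropped <- c(dropped, key)
        next
      }
    }
    keep_rows <- c(keep_rows, idx[1])
    pki_mean <- c(pki_mean, mean(x))
    n_merged <- c(n_merged, length(x))
  }
  out <- df[keep_rows, , drop = FALSE]
  out$pki <- pki_mean
  out$n_merged <- n_merged
  attr(out, "dropped") <- dropped
  out
}

#' Remove compounds with indistinguishable feature vectors
#'
#' Compounds whose full feature vector (descriptors + fingerprint) is
#' bitwise identical cannot be told apart by the model but may carry
#' different activities (e.g. stereoisomers differing only at a chiral
#' hydrogen under a 2D representation), so every member of such a group is
#' removed.
#'
#' @param compounds Tibble with an `inchikey` column.
#' @param features A `feature_set` (or numeric matrix) whose rownames are the
#'   compounds' InChIKeys.
#' @return The subset of `compounds` with unique feature vectors; attribute
#'   `removed` lists removed InChIKeys.
#' @export
drop_feature_duplicates <- function(compounds, features) {
  m <- if (inherits(features, "feature_set"))
    cbind(features$descriptors, features$fingerprints) else features
  missing_keys <- setdiff(compounds$inchikey, rownames(m))
  if (length(missing_keys))
    stop("no feature vector for compound(s): ",
         paste(missing_keys, collapse = ", "))
  m <- m[compounds$inchikey, , drop = FALSE]
  sig <- apply(m, 1, paste, collapse = "\r")
  dup_sigs <- unique(sig[duplicated(sig)])
  removed <- compounds$inchikey[sig %in% dup_sigs]
  out <- compounds[!sig %in% dup_sigs, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Curate an activity table into a per-target pKi dataset
#'
#' Runs the full curation funnel (structure standardization, confidence and
#' assay-size cuts, Ki-family selection and pKi conversion, replicate
#' merging, feature-duplicate removal) and returns the curated dataset
#' together with a per-step [curation report][print.curation_report].
#'
#' @param records Activity-record tibble from [load_activity_table()] or the
#'   synthetic generator.
#' @param target Optional target label (`"CB1"`/`"CB2"`); when given, only
#'   records for that target are used.
#' @param min_confidence,min_assay_size,ki_types Passed to
#'   [filter_records()].
#' @param sd_fraction Passed to [merge_duplicates()].
#' @param n_bits,radius Fingerprint parameters for the feature-duplicate
#'   step.
#' @return List of class `curated_dataset`: `data` (tibble with `inchikey`,
#'   `smiles`, `pki`, `n_merged`, `target`), `report` (a `curation_report`),
#'   `features` (a `feature_set` for the curated compounds) and `mols`
#'   (parsed structures keyed by InChIKey).
#' @export
curate_activity_data <- function(records, target = NULL, min_confidence = 8,
                                 min_assay_size = 10,
                                 ki_types = .DEFAULT_KI_TYPES,
                                 sd_fraction = 0.10,
                                 n_bits = 1024L, radius = 3L) {
  if (!is.null(target)) records <- records[records$target == target, ,
                                           drop = FALSE]
  target_label <- if (!is.null(target)) target
    else if (nrow(records)) records$target[1] else NA_character_

  filt <- filter_records(records, min_confidence = min_confidence,
                         min_assay_size = min_assay_size,
                         ki_types = ki_types)
  steps <- attr(filt, "steps")

  if (nrow(filt) == 0) {
    steps <- c(steps, duplicates_merged = 0, feature_duplicates = 0)
    report <- new_curation_report(steps, target_label)
    return(structure(list(
      data = tibble::tibble(inchikey = character(0), smiles = character(0),
                            pki = numeric(0), n_merged = integer(0),
                            target = character(0)),
      report = report, features = NULL, mols = list()),
      class = "curated_dataset"))
  }

  merged <- merge_duplicates(
    tibble::tibble(inchikey = filt$inchikey, pki = filt$pki,
                   smiles = filt$smiles_std, mol = filt$mol),
    sd_fraction = sd_fraction)
  steps <- c(steps, duplicates_merged = nrow(merged))

  feats <- featurize_compounds(merged$mol, ids = merged$inchikey,
                               n_bits = n_bits, radius = radius)
  deduped <- drop_feature_duplicates(merged, feats)
  steps <- c(steps, feature_duplicates = nrow(deduped))

  keep <- deduped$inchikey
  features <- structure(list(
    descriptors = feats$descriptors[keep, , drop = FALSE],
    fingerprints = feats$fingerprints[keep, , drop = FALSE],
    ids = keep), class = "feature_set")
  mols <- deduped$mol
  names(mols) <- keep

  data <- tibble::tibble(inchikey = deduped$inchikey,
                         smiles = deduped$smiles,
                         pki = deduped$pki,
                         n_merged = deduped$n_merged,
                         target = target_label)
  structure(list(data = data, report = new_curation_report(steps, target_label),
                 features = features, mols = mols),
            class = "curated_dataset")
}

new_curation_report <- function(steps, target = NA_character_) {
  structure(list(steps = steps, target = target), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report", if (!is.na(x$target)) paste0(" [", x$target, "]"),
      "\n", sep = "")
  labels <- c(loaded = "1. records loaded",
              structures = "2. standardizable structure",
              confidence = "3. confidence score cut",
              assay_size = "4. large assays only",
              ki_type = "5. Ki-family, exact, convertible",
              duplicates_merged = "6. replicates merged (consistent)",
              feature_duplicates = "7. unique feature vectors")
  for (nm in names(x$steps))
    cat(sprintf("  %-36s %6d\n", labels[[nm]], x$steps[[nm]]))
  invisible(x)
}

#' @export
print.curated_dataset <- function(x, ...) {
  print(x$report)
  cat("Curated compounds:", nrow(x$data), "\n")
  invisible(x)
}

#' Write a curated dataset to CSV and its report to JSON
#'
#' @param x A `curated_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_curated_dataset <- function(x, dir) {
  stopifnot(inherits(x, "curated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data_path <- file.path(dir, "curated.csv")
  report_path <- file.path(dir, "curation_report.json")
  utils::write.csv(x$data, data_path, row.names = FALSE)
  jsonlite::write_json(as.list(x$report$steps), report_path,
                       auto_unbox = TRUE)
  invisible(c(data = data_path, report = report_path))
}
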