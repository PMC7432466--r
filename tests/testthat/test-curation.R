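test_that("activity tables load with schema checks and value parsing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "canonical_smiles,standard_type,standard_value,standard_units,standard_relation,document_chembl_id,confidence_score,target",
    "CCO,Ki,12.5,nM,=,DOC1,9,CB2",
    ",Ki,3,nM,=,DOC1,9,CB2",
    "c1ccccc1,Ki,oops,nM,=,DOC2,8,CB2"), path)
  tab <- load_activity_table(path)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$standard_value[1], 12.5)
  expect_equal(tab$standard_units[1], "nM")
  expect_true(is.na(tab$smiles[2]))          # absence preserved, not dropped
  expect_true(is.na(tab$standard_value[3]))  # collected as row error
  expect_equal(attr(tab, "row_errors")$row, 3)

  writeLines(c("canonical_smiles,standard_type", "CCO,Ki"), path)
  expect_error(load_activity_table(path), "standard_value")
})

test_that("Ki measurements convert to pKi on the molar log scale", {
  expect_equal(to_pki(1, "nM", "Ki"), 9)
  expect_equal(to_pki(7.2, NA, "pKi"), 7.2)
  expect_equal(to_pki(50, "nM", "Ki"), 9 - log10(50))
  expect_equal(to_pki(1, "uM", "Ki"), 6)
  expect_equal(to_pki(1, "M", "Ki"), 0)
  expect_error(to_pki(-5, "nM", "Ki"), "positive")
  expect_error(to_pki(0, "nM", "Ki"), "positive")
  expect_error(to_pki(10, "parsec", "Ki"), "unit")
  expect_error(to_pki(10, "nM", "IC50"), "Ki-family")
})

test_that("pKi conversion is strictly decreasing and log-linear in Ki", {
  v <- c(0.3, 1, 7, 50, 1200)
  p <- vapply(v, to_pki, numeric(1), unit = "nM")
  expect_true(all(diff(p) < 0))
  for (ki in v)
    expect_equal(to_pki(10 * ki, "nM", "Ki"), to_pki(ki, "nM", "Ki") - 1)
})

test_that("the assay-size filter counts documents after earlier removals", {
  smi <- generate_structures(21, seed = 3)
  tab <- rbind(
    activity_row(smi[1:12], pki = seq(5, 7.2, length.out = 12), doc = "BIG"),
    activity_row(smi[13:21], pki = seq(5, 7, length.out = 9), doc = "SMALL"))
  out <- filter_records(tab, min_assay_size = 10)
  expect_equal(nrow(out), 12)
  expect_true(all(out$document_id == "BIG"))
  steps <- attr(out, "steps")
  expect_equal(unname(steps[c("loaded", "assay_size")]), c(21, 12))
})

test_that("low-confidence records are removed at the confidence step", {
  smi <- generate_structures(12, seed = 4)
  tab <- activity_row(smi, pki = seq(5, 8, length.out = 12))
  tab$confidence_score[3] <- 7L
  out <- filter_records(tab)
  expect_equal(attr(out, "steps")[["confidence"]], 11)
  # with nothing to remove, every filter passes everything through
  tab2 <- activity_row(smi[1:10], pki = seq(5, 8, length.out = 10))
  out2 <- filter_records(tab2)
  expect_equal(nrow(out2), 10)
})

test_that("censored and non-Ki records fall at the standard-type step", {
  smi <- generate_structures(12, seed = 6)
  tab <- activity_row(smi, pki = seq(5, 8, length.out = 12))
  tab$standard_relation[1] <- ">"
  tab$standard_type[2] <- "IC50"
  out <- filter_records(tab)
  expect_equal(attr(out, "steps")[["ki_type"]], 10)
  # pKi-typed records need no unit
  tab3 <- activity_row(smi[1:10], value = seq(5, 8, length.out = 10),
                       type = "pKi", unit = "")
  out3 <- filter_records(tab3)
  expect_equal(out3$pki, seq(5, 8, length.out = 10))
})

test_that("replicate merging follows the population-SD consistency rule", {
  df <- tibble::tibble(
    inchikey = c("A", "A", "B", "B", "C", "D", "E"),
    pki = c(7.0, 7.1, 5.0, 9.0, 6.2, 4.0, 10.0))
  # dataset range is [4, 10]; bound = 0.6
  out <- merge_duplicates(df, sd_fraction = 0.10)
  expect_setequal(out$inchikey, c("A", "C", "D", "E"))
  expect_equal(out$pki[out$inchikey == "A"], 7.05)   # pop SD 0.05 < 0.6
  expect_equal(attr(out, "dropped"), "B")            # pop SD 2.0 >= 0.6
  expect_equal(out$n_merged[out$inchikey == "A"], 2)
  expect_equal(out$n_merged[out$inchikey == "C"], 1)
})

test_that("merged groups reproduce brute-force per-group means", {
  set.seed(8)
  keys <- sample(LETTERS[1:8], 40, replace = TRUE)
  df <- tibble::tibble(inchikey = keys, pki = runif(40, 6.9, 7.1))
  df <- rbind(df, tibble::tibble(inchikey = "Z1", pki = 4),
              tibble::tibble(inchikey = "Z2", pki = 10))
  out <- merge_duplicates(df)
  expect_false(any(duplicated(out$inchikey)))
  oracle <- tapply(df$pki, df$inchikey, mean)
  for (k in out$inchikey)
    expect_equal(out$pki[out$inchikey == k], unname(oracle[[k]]))
})

test_that("feature-duplicate groups are removed entirely", {
  m <- rbind(A = c(1, 0, 1), B = c(1, 0, 1), C = c(0, 1, 1))
  comp <- tibble::tibble(inchikey = c("A", "B", "C"))
  out <- drop_feature_duplicates(comp, m)
  expect_equal(out$inchikey, "C")
  expect_setequal(attr(out, "removed"), c("A", "B"))
  # all-distinct input passes through untouched
  m2 <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1))
  expect_equal(drop_feature_duplicates(comp, m2)$inchikey, comp$inchikey)
  expect_error(drop_feature_duplicates(tibble::tibble(inchikey = "Q"), m),
               "Q")
})

test_that("stereoisomers invisible to 2D features are both removed", {
  smi <- generate_structures(10, seed = 9)
  # E/Z isomers: distinct structure keys, identical 2D feature vectors
  ez <- c("C/C=C/CCc1ccc(O)cc1", "C/C=C\\CCc1ccc(O)cc1")
  tab <- rbind(
    activity_row(smi, pki = seq(4.5, 9.5, length.out = 10)),
    activity_row(ez, pki = c(6, 7)))
  cur <- curate_activity_data(tab, target = "CB2")
  steps <- cur$report$steps
  expect_equal(steps[["duplicates_merged"]], 12)  # twins have distinct keys
  expect_equal(steps[["feature_duplicates"]], 10) # both twins removed
  ez_keys <- standardize_structures(ez)$inchikey
  expect_false(any(ez_keys %in% cur$data$inchikey))
})

test_that("curation counts are monotone and curation is idempotent", {
  smi <- generate_structures(40, seed = 13, fraction_invalid = 0.1)
  cfg <- synth_config(n_compounds = 40, seed = 13)
  truth <- assign_true_pki(smi, cfg)
  tab <- generate_activity_table(truth, cfg, "CB1")
  cur <- curate_activity_data(tab, target = "CB1")
  expect_true(all(diff(unname(cur$report$steps)) <= 0))
  expect_equal(cur$report$steps[["loaded"]], nrow(tab))

  # feed the curated output back through as a clean pKi table
  tab2 <- activity_row(cur$data$smiles, value = cur$data$pki, type = "pKi",
                       unit = "", target = "CB1")
  cur2 <- curate_activity_data(tab2, target = "CB1",
                               min_assay_size = min(10, nrow(cur$data)))
  expect_equal(sort(cur2$data$inchikey), sort(cur$data$inchikey))
  expect_equal(cur2$data$pki[order(cur2$data$inchikey)],
               cur$data$pki[order(cur$data$inchikey)])
})
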