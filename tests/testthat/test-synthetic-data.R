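# Synthetic panel generator: determinism, class structure, ground truth.

test_that("species metadata draws OGT inside the class range", {
  cfg <- panel_config(n_species_per_class = c(meso = 3), seed = 7)
  meta <- make_species_metadata(cfg)
  expect_equal(nrow(meta), 3L)
  expect_true(all(meta$thermal_class == "mesophile"))
  expect_true(all(meta$ogt_true >= 20 & meta$ogt_true <= 42))
  expect_true(all(!duplicated(meta$species_id)))
})

test_that("an all-zero species panel is rejected", {
  cfg <- panel_config(n_species_per_class = c(meso = 0))
  expect_error(make_species_metadata(cfg), "empty panel")
})

test_that("invalid configs are rejected at construction", {
  expect_error(panel_config(mean_protein_length = 0), "mean_protein_length")
  expect_error(panel_config(tf_fraction = 1.5), "tf_fraction")
  expect_error(panel_config(disorder_target_by_class = 1.2), "disorder target")
  expect_error(panel_config(n_species_per_class = -1), "species counts")
})

test_that("identical config and seed reproduce identical panels and byte streams", {
  p1 <- simulate_panel(small_config(seed = 1))
  p2 <- simulate_panel(small_config(seed = 1))
  expect_identical(p1$records, p2$records)
  expect_identical(p1$metadata, p2$metadata)
  expect_identical(p1$go, p2$go)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_panel(p1, d1); write_panel(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("adding species to one class does not perturb existing species", {
  small <- simulate_panel(small_config(seed = 5))
  bigger_cfg <- small_config(seed = 5)
  bigger_cfg$n_species_per_class["hyperthermophile"] <- 5
  bigger <- simulate_panel(bigger_cfg)
  shared <- small$metadata$species_id
  sub <- bigger$records[bigger$records$species_id %in% shared, , drop = FALSE]
  rownames(sub) <- NULL
  expect_identical(small$records, sub)
})

test_that("extreme disorder targets yield all-false / all-true ground truth", {
  cfg0 <- panel_config(n_species_per_class = c(meso = 1),
                       proteome_size_by_class = 30,
                       disorder_target_by_class = 0, seed = 2)
  p0 <- simulate_panel(cfg0)
  expect_equal(nrow(p0$truth), 0L)
  cfg1 <- panel_config(n_species_per_class = c(meso = 1),
                       proteome_size_by_class = 30,
                       disorder_target_by_class = 1, seed = 2)
  p1 <- simulate_panel(cfg1)
  frac <- truth_disordered_fraction(p1)
  expect_true(all(frac == 1))
})

test_that("realized disordered fraction approximates the configured target", {
  cfg <- panel_config(n_species_per_class = c(meso = 1),
                      proteome_size_by_class = 200,
                      disorder_target_by_class = 0.25,
                      mean_protein_length = 300,
                      tf_fraction = 0, seed = 3)
  p <- simulate_panel(cfg)
  len <- nchar(p$records$sequence)
  realized <- sum(truth_disordered_fraction(p) * len) / sum(len)
  expect_lt(abs(realized - 0.25), 0.05)
})

test_that("mean realized disorder is ordered across classes as configured", {
  p <- simulate_panel(small_config(seed = 9))
  frac <- truth_disordered_fraction(p)
  cls <- p$metadata$thermal_class[match(p$records$species_id,
                                        p$metadata$species_id)]
  by_class <- tapply(frac, cls, mean)
  expect_lt(by_class[["hyperthermophile"]], by_class[["mesophile"]])
  expect_lt(by_class[["psychrophile"]], by_class[["thermophile"]])
})

test_that("GO annotation respects the TF fraction", {
  base <- simulate_panel(small_config(seed = 4))
  go0 <- make_go_annotations(base$records, character(),
                             panel_config(tf_fraction = 0), seed = 4)
  expect_equal(sum(go0$go_id == "GO:0003700"), 0L)
  go1 <- make_go_annotations(base$records, base$records$protein_id,
                             panel_config(tf_fraction = 1), seed = 4)
  expect_true(all(go1$go_id == "GO:0003700"))

  cfg <- panel_config(n_species_per_class = c(meso = 1),
                      proteome_size_by_class = 100,
                      tf_fraction = 0.1, seed = 5)
  p <- simulate_panel(cfg)
  n_tf_rows <- sum(p$go$go_id == "GO:0003700")
  expect_equal(n_tf_rows, length(p$tf_ids))
  expect_lt(abs(n_tf_rows - 0.1 * nrow(p$records)), 5)
  expect_true(all(p$go$go_name[p$go$go_id != "GO:0003700"] %in%
                    c("translation", "transport",
                      "regulation of transcription, DNA-dependent",
                      "signal transduction", "proteolysis", "chemotaxis",
                      "metabolic process", "translational elongation",
                      "oxidation reduction", "ribosome biogenesis",
                      "two-component signal transduction system",
                      "peptidyl-histidine phosphorylation", "cell adhesion",
                      "pathogenesis", "protein secretion", "transcription")))
})

test_that("bundled scorer separates ground-truth disordered from ordered residues", {
  p <- simulate_panel(panel_config(n_species_per_class = c(meso = 1),
                                   proteome_size_by_class = 150,
                                   disorder_target_by_class = 0.3,
                                   seed = 6))
  tracks <- get_tracks(p$records)
  frac <- truth_disordered_fraction(p)
  dis_scores <- numeric(); ord_scores <- numeric()
  truth_by_id <- split(p$truth, p$truth$protein_id)
  for (i in seq_len(nrow(p$records))) {
    id <- p$records$protein_id[i]
    sc <- tracks[[id]]
    mask <- rep(FALSE, length(sc))
    tr <- truth_by_id[[id]]
    if (!is.null(tr)) for (j in seq_len(nrow(tr))) {
      mask[tr$start[j]:tr$end[j]] <- TRUE
    }
    dis_scores <- c(dis_scores, sc[mask])
    ord_scores <- c(ord_scores, sc[!mask])
  }
  expect_gte(mean(dis_scores) - mean(ord_scores), 0.2)
})
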