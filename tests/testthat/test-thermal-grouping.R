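# OGT resolution, class assignment, group statistics, genus bins and the
# proteome-size/disorder correlation.

test_that("OGT resolution passes exact values and averages ranges", {
  meta <- data.frame(species_id = c("a", "b", "c"),
                     ogt_value = c(98, NA, NA),
                     ogt_range_low = c(NA, 20, NA),
                     ogt_range_high = c(NA, 30, NA),
                     thermal_class = c(NA, NA, "hyperthermophile"),
                     stringsAsFactors = FALSE)
  ogt <- resolve_ogt(meta)
  expect_equal(ogt, c(98, 25, NA))
  meta2 <- assign_thermal_classes(meta)
  expect_equal(meta2$thermal_class,
               c("hyperthermophile", "mesophile", "hyperthermophile"))
})

test_that("OGT classification covers ranges, the 75C overlap and the gaps", {
  expect_equal(classify_ogt(98)$thermal_class, "hyperthermophile")
  expect_equal(classify_ogt(75)$thermal_class, "hyperthermophile")
  expect_equal(classify_ogt(74.9)$thermal_class, "thermophile")
  expect_equal(classify_ogt(10)$thermal_class, "psychrophile")
  expect_equal(classify_ogt(30)$thermal_class, "mesophile")
  # gap values go to the nearest boundary, flagged
  g43 <- classify_ogt(43)
  expect_equal(g43$thermal_class, "mesophile")
  expect_true(g43$flagged)
  expect_equal(classify_ogt(44.5)$thermal_class, "thermophile")
  expect_equal(classify_ogt(18)$thermal_class, "psychrophile")
  expect_equal(classify_ogt(19.5)$thermal_class, "mesophile")
  expect_equal(classify_ogt(2)$thermal_class, "psychrophile")
  expect_equal(classify_ogt(120)$thermal_class, "hyperthermophile")
})

test_that("classification is total: every finite OGT maps to exactly one class", {
  grid <- seq(-10, 120, by = 0.5)
  cl <- classify_ogt(grid)
  expect_false(anyNA(cl$thermal_class))
  expect_true(all(cl$thermal_class %in% c("psychrophile", "mesophile",
                                          "thermophile", "hyperthermophile")))
})

test_that("group statistics match hand computation and conserve counts", {
  meta <- data.frame(species_id = paste0("s", 1:5),
                     thermal_class = c(rep("mesophile", 3), "thermophile",
                                       "hyperthermophile"),
                     stringsAsFactors = FALSE)
  summaries <- data.frame(species_id = paste0("s", 1:5),
                          avg_protein_mean_score = c(2, 4, 6, 10, 3),
                          stringsAsFactors = FALSE)
  g <- group_stats(summaries, meta)
  meso <- g[g$thermal_class == "mesophile", ]
  expect_equal(meso$mean, 4)
  expect_equal(meso$median, 4)
  expect_equal(meso$sem, stats::sd(c(2, 4, 6)) / sqrt(3))
  # singleton classes: SEM 0, min = median = max
  single <- g[g$thermal_class == "thermophile", ]
  expect_equal(single$sem, 0)
  expect_equal(single$min, single$max)
  expect_equal(sum(g$n), 5L)
  expect_error(group_stats(summaries, meta, "no_such_measure"), "measure")
})

test_that("genus binning uses the published colour bin edges", {
  meta <- data.frame(species_id = paste0("s", 1:6),
                     genus = c("g1", "g1", "g2", "g3", "g4", "g5"),
                     thermal_class = "mesophile", stringsAsFactors = FALSE)
  summaries <- data.frame(species_id = paste0("s", 1:6),
                          avg_protein_mean_score = c(17, 19, 0, 30, 22, 26),
                          stringsAsFactors = FALSE)
  bins <- taxonomic_bins(summaries, meta)
  expect_equal(bins$bin[bins$genus == "g1"], "yellow")  # mean 18
  expect_equal(bins$bin[bins$genus == "g2"], "white")
  expect_equal(bins$bin[bins$genus == "g3"], "red")
  expect_equal(bins$bin[bins$genus == "g4"], "ochre")
  expect_equal(bins$bin[bins$genus == "g5"], "orange")
  # partition: every nonnegative value falls in exactly one bin
  vals <- c(0, 15.99, 16, 19.99, 20, 23.99, 24, 27.99, 28, 100)
  cuts <- cut(vals, c(0, 16, 20, 24, 28, Inf), right = FALSE,
              include.lowest = FALSE,
              labels = c("white", "yellow", "ochre", "orange", "red"))
  expect_false(anyNA(cuts[-1][vals[-1] > 0]))
})

test_that("size-disorder correlation is Spearman and behaves at the extremes", {
  mono <- data.frame(species_id = paste0("s", 1:10),
                     n_proteins = (1:10) * 100,
                     avg_protein_mean_score = (1:10) + 0.5)
  expect_equal(size_disorder_correlation(mono)$rho, 1)

  set.seed(13)
  null <- data.frame(species_id = paste0("s", 1:200),
                     n_proteins = sample(500:5000, 200),
                     avg_protein_mean_score = stats::runif(200, 2, 25))
  expect_lt(abs(size_disorder_correlation(null)$rho), 0.2)

  expect_error(size_disorder_correlation(mono[1:2, ]), "3 species")
})
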