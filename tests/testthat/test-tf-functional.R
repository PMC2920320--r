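# Transcription-factor profiling and GO profiling of long-IDR proteins.

test_that("TF selection takes exactly the directly annotated proteins", {
  go <- data.frame(protein_id = c("p1", "p2", "p3", "p3", "p4"),
                   go_id = c("GO:0003700", "GO:0006412", "GO:0003700",
                             "GO:0006810", "GO:0006412"),
                   stringsAsFactors = FALSE)
  expect_setequal(select_tfs(go), c("p1", "p3"))
  expect_equal(select_tfs(go, protein_set = c("p3", "p4")), "p3")
  expect_length(select_tfs(go[0, ]), 0)
})

test_that("TF selection recovers the generator's TF set exactly", {
  p <- simulate_panel(small_config(seed = 3))
  expect_setequal(select_tfs(p$go), p$tf_ids)
})

test_that("matched mesophile subsets follow the deterministic greedy rule", {
  meta <- data.frame(species_id = c("m1", "m2", "m3", "t1"),
                     thermal_class = c(rep("mesophile", 3), "thermophile"),
                     stringsAsFactors = FALSE)
  mk <- function(target_size) {
    data.frame(species_id = c("m1", "m2", "m3", "t1"),
               n_proteins = c(1000, 3000, 5000, target_size),
               stringsAsFactors = FALSE)
  }
  expect_equal(matched_mesophile_subset(meta, mk(1000), "thermophile"), "m1")
  expect_equal(matched_mesophile_subset(meta, mk(3000), "thermophile"), "m2")
  no_meso <- meta[meta$thermal_class != "mesophile", ]
  expect_error(
    matched_mesophile_subset(no_meso, mk(1000)[4, ], "thermophile"),
    "no mesophile")
})

test_that("matched subset mean lands near the target on a synthetic panel", {
  cfg <- panel_config(
    n_species_per_class = c(meso = 8, thermo = 3),
    proteome_size_by_class = c(meso = 100, thermo = 90),
    seed = 12)
  p <- simulate_panel(cfg)
  sizes <- as.data.frame(table(p$records$species_id), stringsAsFactors = FALSE)
  names(sizes) <- c("species_id", "n_proteins")
  sub <- matched_mesophile_subset(p$metadata, sizes, "thermophile")
  target <- mean(sizes$n_proteins[grepl("^THE", sizes$species_id)])
  achieved <- mean(sizes$n_proteins[sizes$species_id %in% sub])
  expect_lt(abs(achieved - target) / target, 0.1)
})

test_that("TF comparison recovers configured length and disorder effects", {
  starred_right_direction <- 0L
  for (seed in 1:5) {
    cfg <- panel_config(
      n_species_per_class = c(meso = 3, hyper = 3),
      proteome_size_by_class = c(meso = 250, hyper = 160),
      disorder_target_by_class = c(meso = 0.15, hyper = 0.15),
      tf_fraction = 0.3,
      tf_length_factor_by_class = c(meso = 1, hyper = 0.7),
      tf_disorder_factor_by_class = c(meso = 1, hyper = 0.5),
      seed = seed)
    p <- simulate_panel(cfg)
    tracks <- get_tracks(p$records)
    tf <- suppressWarnings(tf_comparison(p$records, tracks, p$go, p$metadata))
    hy <- tf$rows[tf$rows$group == "hyperthermophile", ]
    me <- tf$rows[tf$rows$group == "mesophile", ]
    tl <- tf$tests[tf$tests$label_a == "hyperthermophile" &
                     tf$tests$measure == "length", ]
    td <- tf$tests[tf$tests$label_a == "hyperthermophile" &
                     tf$tests$measure == "disorder", ]
    if (hy$mean_length < me$mean_length && hy$mean_disorder < me$mean_disorder &&
        nzchar(tl$stars) && nzchar(td$stars)) {
      starred_right_direction <- starred_right_direction + 1L
    }
  }
  expect_equal(starred_right_direction, 5L)
})

test_that("identical groups show no significant TF difference", {
  cfg <- panel_config(
    n_species_per_class = c(meso = 2, thermo = 2),
    proteome_size_by_class = 80,
    disorder_target_by_class = 0.1,
    tf_fraction = 0.2,
    tf_length_factor_by_class = 1,
    tf_disorder_factor_by_class = 1,
    seed = 30)
  p <- simulate_panel(cfg)
  tf <- suppressWarnings(tf_comparison(p$records, get_tracks(p$records),
                                       p$go, p$metadata))
  td <- tf$tests[tf$tests$label_a == "thermophile", ]
  expect_true(all(td$p_value > 0.05))
  expect_true(all(td$stars == ""))
})

test_that("tf_ratio is n_tfs per annotated protein and order-invariant", {
  p <- simulate_panel(small_config(seed = 14))
  tracks <- get_tracks(p$records)
  tf1 <- suppressWarnings(tf_comparison(p$records, tracks, p$go, p$metadata))
  perm <- sample(nrow(p$records))
  tf2 <- suppressWarnings(tf_comparison(p$records[perm, ], tracks, p$go,
                                        p$metadata))
  r1 <- tf1$rows[order(tf1$rows$group), ]
  r2 <- tf2$rows[order(tf2$rows$group), ]
  expect_equal(r1$tf_ratio, r2$tf_ratio)
  expect_equal(r1$n_tfs, r2$n_tfs)
  meso <- r1[r1$group == "mesophile", ]
  n_meso_annot <- sum(p$records$species_id %in%
                        p$metadata$species_id[p$metadata$thermal_class == "mesophile"])
  expect_equal(meso$tf_ratio, 100 * meso$n_tfs / n_meso_annot)
})

test_that("disorder bands label mesophiles inside closed bands only", {
  meta <- data.frame(species_id = paste0("s", 1:5),
                     thermal_class = c(rep("mesophile", 4), "hyperthermophile"),
                     stringsAsFactors = FALSE)
  summaries <- data.frame(species_id = paste0("s", 1:5),
                          avg_protein_mean_score = c(2.5, 9, 6, 4, 2),
                          stringsAsFactors = FALSE)
  bands <- disorder_band_groups(summaries, meta)
  expect_equal(bands$band, c("MLD", "MMD", NA, "MLD", NA))
  expect_error(
    disorder_band_groups(summaries, meta,
                         bands = list(A = c(1, 5), B = c(4, 8))),
    "overlap")
})

test_that("GO profile counts multi-term proteins once per process", {
  protein_table <- data.frame(protein_id = c("p1", "p2", "p3"),
                              n_long_idrs = c(1L, 2L, 0L),
                              stringsAsFactors = FALSE)
  records <- data.frame(protein_id = c("p1", "p2", "p3"),
                        species_id = "spA", sequence = "M",
                        stringsAsFactors = FALSE)
  go <- data.frame(protein_id = c("p1", "p1", "p2", "p3"),
                   go_id = "GO:x",
                   go_name = c("translation", "transport", "translation",
                               "proteolysis"),
                   aspect = "P", stringsAsFactors = FALSE)
  prof <- go_profile_long_idr(protein_table, records, go,
                              groups = list(G = "spA"))
  # denominator: p1 and p2 have long IDRs; p3 does not
  expect_equal(attr(prof, "denominators")[["G"]], 2L)
  expect_equal(prof$pct_G[prof$go_process == "translation"], 100)
  expect_equal(prof$pct_G[prof$go_process == "transport"], 50)
  expect_equal(prof$pct_G[prof$go_process == "proteolysis"], 0)
  # multi-term proteins let columns sum above 100
  expect_gt(sum(prof$pct_G), 100)
})

test_that("GO profile applies the below-1% display floor", {
  n <- 200
  protein_table <- data.frame(protein_id = paste0("p", 1:n),
                              n_long_idrs = 1L, stringsAsFactors = FALSE)
  records <- data.frame(protein_id = paste0("p", 1:n), species_id = "spA",
                        sequence = "M", stringsAsFactors = FALSE)
  go <- data.frame(protein_id = paste0("p", 1:n), go_id = "GO:x",
                   go_name = c("chemotaxis", rep("translation", n - 1)),
                   aspect = "P", stringsAsFactors = FALSE)
  prof <- go_profile_long_idr(protein_table, records, go, list(G = "spA"))
  chem <- prof[prof$go_process == "chemotaxis", ]
  expect_equal(chem$pct_G, 0.5)
  expect_equal(chem$disp_G, "<1%")
  expect_warning(
    go_profile_long_idr(protein_table[0, ], records, go, list(G = "spA")),
    "no long-IDR")
})

test_that("GO profile denominators agree with the disorder-metrics module", {
  p <- simulate_panel(small_config(seed = 16))
  tracks <- get_tracks(p$records)
  pt <- protein_disorder_table(tracks)
  groups <- list(H = p$metadata$species_id[p$metadata$thermal_class ==
                                             "hyperthermophile"])
  prof <- suppressWarnings(go_profile_long_idr(pt, p$records, p$go, groups))
  hyper_prot <- p$records$protein_id[p$records$species_id %in% groups$H]
  n_lidr <- sum(pt$n_long_idrs > 0 & pt$protein_id %in% hyper_prot)
  expect_equal(attr(prof, "denominators")[["H"]], n_lidr)
})
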