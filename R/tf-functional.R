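# Transcription-factor profiling across thermal classes and GO
# biological-process profiling of proteins carrying long disordered
# regions, including matched mesophile control groups.

#' Select transcription factors from a GO table
#'
#' A protein is a transcription factor iff it carries a direct GO:0003700
#' annotation (no ontology-graph propagation).
#'
#' @param go_table annotation data.frame (`protein_id`, `go_id`).
#' @param protein_set optional character vector restricting the result.
#' @return character vector of unique TF protein ids.
#' @export
select_tfs <- function(go_table, protein_set = NULL) {
  tfs <- unique(go_table$protein_id[go_table$go_id == GO_TF[["go_id"]]])
  if (!is.null(protein_set)) tfs <- intersect(tfs, protein_set)
  tfs
}

#' Mesophile subset matched on mean proteome size
#'
#' Builds a deterministic mesophile control group whose mean proteome size
#' approximates the mean of a target class. Mesophile species are sorted
#' by absolute distance of their proteome size from the target mean (ties
#' by species id) and added greedily while each addition moves the subset
#' mean no farther from the target than omitting it. A warning is emitted
#' when the achieved mean deviates from the target by more than 10%.
#'
#' @param meta species metadata with `thermal_class`.
#' @param summaries per-species summary table with `species_id`,
#'   `n_proteins`.
#' @param target_class the class whose mean proteome size is matched
#'   (`"thermophile"` or `"hyperthermophile"`).
#' @return character vector of selected mesophile species ids.
#' @export
matched_mesophile_subset <- function(meta, summaries, target_class) {
  target_class <- normalize_class(target_class)
  cls <- meta$thermal_class[match(summaries$species_id, meta$species_id)]
  sizes <- summaries$n_proteins
  tgt <- sizes[cls == target_class]
  if (length(tgt) == 0L) stop("target class '", target_class, "' is empty")
  meso_idx <- which(cls == "mesophile")
  if (length(meso_idx) == 0L) stop("no mesophile species to select from")
  target_mean <- mean(tgt)
  ord <- meso_idx[order(abs(sizes[meso_idx] - target_mean),
                        summaries$species_id[meso_idx])]
  chosen <- ord[1L]
  for (i in ord[-1L]) {
    cur_err <- abs(mean(sizes[chosen]) - target_mean)
    new_err <- abs(mean(sizes[c(chosen, i)]) - target_mean)
    if (new_err <= cur_err) chosen <- c(chosen, i) else break
  }
  achieved <- mean(sizes[chosen])
  if (abs(achieved - target_mean) > 0.1 * target_mean) {
    warning(sprintf(
      "matched subset mean proteome size %.0f deviates >10%% from target %.0f",
      achieved, target_mean))
  }
  summaries$species_id[chosen]
}

#' Transcription-factor comparison across thermal groups
#'
#' For the four thermal classes and the two size-matched mesophile control
#' groups (meso-thermo, meso-hyper), reports the number of TFs, their mean
#' length and mean predicted disorder (per-protein mean score, %) with
#' SEMs, and the TF ratio among annotated proteins. Each non-mesophile
#' group is compared to the mesophiles with the Mann-Whitney test on TF
#' length and TF disorder, annotated with significance stars.
#'
#' @param records protein-record table for the whole panel.
#' @param tracks named list of score tracks covering all proteins.
#' @param go_table GO annotation table.
#' @param meta species metadata with `thermal_class`.
#' @param threshold disorder threshold for per-protein mean-score
#'   percentages (unused by the mean itself; kept for provenance).
#' @return list with `rows` (one `TFComparisonRow` per group) and `tests`
#'   (GroupComparison rows for length and disorder vs mesophiles).
#' @export
tf_comparison <- function(records, tracks, go_table, meta, threshold = 0.5) {
  tf_ids <- select_tfs(go_table, records$protein_id)
  cls <- meta$thermal_class[match(records$species_id, meta$species_id)]
  len <- nchar(records$sequence)
  dis <- 100 * vapply(tracks[records$protein_id], mean, numeric(1))
  annotated <- records$protein_id %in% go_table$protein_id
  is_tf <- records$protein_id %in% tf_ids

  # per-species proteome sizes for matched-control construction
  sizes <- stats::aggregate(list(n_proteins = records$protein_id),
                            by = list(species_id = records$species_id),
                            FUN = length)
  groups <- list()
  for (k in THERMAL_CLASSES) groups[[k]] <- meta$species_id[meta$thermal_class == k]
  for (tc in c("thermophile", "hyperthermophile")) {
    lbl <- if (tc == "thermophile") "meso-thermo" else "meso-hyper"
    groups[[lbl]] <- tryCatch(matched_mesophile_subset(meta, sizes, tc),
                              error = function(e) character())
  }

  meso_species <- groups[["mesophile"]]
  meso_tf <- is_tf & records$species_id %in% meso_species
  rows <- list(); tests <- list()
  for (g in names(groups)) {
    in_g <- records$species_id %in% groups[[g]]
    g_tf <- is_tf & in_g
    n_tfs <- sum(g_tf)
    n_annot <- sum(annotated & in_g)
    rows[[g]] <- data.frame(
      group = g, n_tfs = n_tfs,
      mean_length = if (n_tfs) mean(len[g_tf]) else NA_real_,
      sem_length = if (n_tfs) sem(len[g_tf]) else NA_real_,
      mean_disorder = if (n_tfs) mean(dis[g_tf]) else NA_real_,
      sem_disorder = if (n_tfs) sem(dis[g_tf]) else NA_real_,
      tf_ratio = if (n_annot) 100 * n_tfs / n_annot else NA_real_,
      stringsAsFactors = FALSE
    )
    if (g != "mesophile" && n_tfs > 0 && sum(meso_tf) > 0) {
      tests[[paste0(g, ":length")]] <-
        cbind(measure = "length",
              mann_whitney(len[g_tf], len[meso_tf], g, "mesophile"))
      tests[[paste0(g, ":disorder")]] <-
        cbind(measure = "disorder",
              mann_whitney(dis[g_tf], dis[meso_tf], g, "mesophile"))
    }
  }
  list(rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tests = if (length(tests)) {
         do.call(rbind, c(tests, list(make.row.names = FALSE)))
       } else NULL)
}

#' Assign mesophiles to average-disorder bands
#'
#' Labels mesophile species whose headline disorder falls inside a closed
#' band; the default bands are MLD (low disorder, 1-4%) and MMD (medium
#' disorder, 8-11%). Species outside every band stay unlabeled (NA).
#'
#' @param summaries per-species summary table.
#' @param meta species metadata.
#' @param bands named list of `c(low, high)` percent bands (inclusive).
#' @param measure headline disorder measure used for banding.
#' @return data.frame `species_id`, `band` (NA where unlabeled); only
#'   mesophiles are eligible.
#' @export
disorder_band_groups <- function(summaries, meta,
                                 bands = list(MLD = c(1, 4), MMD = c(8, 11)),
                                 measure = "avg_protein_mean_score") {
  bmat <- do.call(rbind, bands)
  if (any(bmat[, 1] > bmat[, 2])) stop("band low > high")
  if (length(bands) > 1L) {
    o <- order(bmat[, 1])
    if (any(bmat[o, 1][-1] <= bmat[o, 2][-nrow(bmat)])) {
      stop("overlapping disorder bands")
    }
  }
  cls <- meta$thermal_class[match(summaries$species_id, meta$species_id)]
  x <- summaries[[measure]]
  band <- rep(NA_character_, nrow(summaries))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    band[cls == "mesophile" & x >= b[1] & x <= b[2]] <- nm
  }
  data.frame(species_id = summaries$species_id, band = band,
             stringsAsFactors = FALSE)
}

#' GO biological-process profile of long-IDR proteins
#'
#' For each species group, takes the proteins with at least one long
#' disordered region (>= `min_idr_len` consecutive residues above the
#' threshold) as the denominator and reports, per GO process, the
#' percentage of those proteins annotated to the process. A protein with
#' several process terms counts once in each row, so columns may sum above
#' 100%. Percentages below 1 carry the display marker `"<1%"` alongside
#' the stored numeric value.
#'
#' @param protein_table per-protein disorder table (columns `protein_id`,
#'   `n_long_idrs`) as built by [protein_disorder_table()] /
#'   the pipeline.
#' @param records protein-record table (supplies species membership).
#' @param go_table GO annotation table.
#' @param groups named list: group label -> character vector of species
#'   ids (e.g. H = hyperthermophiles, MLD, MMD).
#' @return data.frame with columns `go_process`, one numeric `pct_<group>`
#'   per group and one `disp_<group>` display column using the `"<1%"`
#'   floor marker.
#' @export
go_profile_long_idr <- function(protein_table, records, go_table, groups) {
  species_of <- stats::setNames(records$species_id, records$protein_id)
  has_lidr <- protein_table$protein_id[protein_table$n_long_idrs > 0]
  bp <- go_table[!is.na(go_table$go_name) & go_table$aspect %in% c("P", NA), , drop = FALSE]
  processes <- sort(unique(bp$go_name))
  out <- data.frame(go_process = processes, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    members <- has_lidr[species_of[has_lidr] %in% groups[[g]]]
    denom <- length(members)
    if (denom == 0L) {
      warning("group '", g, "' has no long-IDR proteins; empty profile")
      pct <- rep(NA_real_, length(processes))
    } else {
      sub <- bp[bp$protein_id %in% members, , drop = FALSE]
      counts <- vapply(processes, function(p) {
        length(unique(sub$protein_id[sub$go_name == p]))
      }, integer(1))
      pct <- 100 * counts / denom
    }
    out[[paste0("pct_", g)]] <- pct
    out[[paste0("disp_", g)]] <- format_pct_floor(pct)
  }
  attr(out, "denominators") <- vapply(names(groups), function(g) {
    sum(species_of[has_lidr] %in% groups[[g]])
  }, integer(1))
  out
}

# Display convention: percentages below 1 print as the literal "<1%".
format_pct_floor <- function(pct) {
  ifelse(is.na(pct), ".",
         ifelse(pct < 1, "<1%", formatC(pct, digits = 2, format = "f")))
}
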