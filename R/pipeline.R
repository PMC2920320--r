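# Orchestration: one call runs simulate (optional) -> score -> metrics ->
# CH -> thermal groups -> TF -> GO profile, writes every intermediate
# table plus a JSON report, and returns a classed result object.

#' Configuration of a full analysis run
#'
#' Exactly one of `synthetic` (a [panel_config()]) or `inputs` (a named
#' list with `fasta` — one or more FASTA paths —, `metadata`, `go`, and
#' optionally `tracks` for external score tracks) must be given.
#'
#' @param synthetic a [panel_config()] describing a synthetic panel.
#' @param inputs named list of input paths (see above).
#' @param scorer `"bundled"` or a path to an external IUPred-style
#'   score-track file.
#' @param window bundled-scorer smoothing window (odd).
#' @param threshold disorder threshold in (0, 1).
#' @param min_idr_len minimal long-IDR length (residues).
#' @param headline_measure proteome measure used for grouping, binning and
#'   the size correlation.
#' @param ch_sample_size maximum proteins per CH panel.
#' @param bands mesophile average-disorder bands for the GO profile.
#' @param seed master seed for every stochastic step.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL,
                       scorer = "bundled", window = 21L,
                       threshold = 0.5, min_idr_len = 30L,
                       headline_measure = "avg_protein_mean_score",
                       ch_sample_size = 2000L,
                       bands = list(MLD = c(1, 4), MMD = c(8, 11)),
                       seed = 1L) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("exactly one of 'synthetic' and 'inputs' must be given")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!headline_measure %in% DISORDER_MEASURES) {
    stop("unknown headline measure '", headline_measure, "'")
  }
  cfg <- list(synthetic = synthetic, inputs = inputs, scorer = scorer,
              window = as.integer(window), threshold = threshold,
              min_idr_len = as.integer(min_idr_len),
              headline_measure = headline_measure,
              ch_sample_size = as.integer(ch_sample_size),
              bands = bands, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full thermal-disorder analysis
#'
#' Executes every stage of the analysis on a synthetic or file-based
#' panel, optionally writing all intermediate tables, a JSON report and a
#' plain-text summary into `out_dir`. Reruns with the same config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when NULL nothing is written.
#' @return object of class `thermal_disorder_run`.
#' @export
run_thermal_disorder_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$synthetic)) {
    panel <- run_stage("simulate", simulate_panel(config$synthetic))
    records <- panel$records
    meta <- panel$metadata
    go <- panel$go
  } else {
    panel <- NULL
    records <- run_stage("read", {
      do.call(rbind, lapply(config$inputs$fasta, read_fasta))
    })
    meta <- run_stage("read", read_species_metadata(config$inputs$metadata))
    go <- run_stage("read", read_go_table(config$inputs$go))
    if (!is.null(config$inputs$tracks)) config$scorer <- config$inputs$tracks
  }
  meta <- run_stage("classify", assign_thermal_classes(meta))

  tracks <- run_stage("score", get_tracks(records, config$scorer, config$window))

  per_protein <- run_stage("metrics",
                           protein_disorder_table(tracks, config$threshold,
                                                  config$min_idr_len))
  per_protein$species_id <- records$species_id[match(per_protein$protein_id,
                                                     records$protein_id)]
  summaries <- run_stage("metrics", {
    do.call(rbind, lapply(split(per_protein, per_protein$species_id),
                          function(d) summarize_proteome(d, d$species_id[1],
                                                         config$threshold)))
  })
  rownames(summaries) <- NULL

  ch <- run_stage("chplot",
                  ch_panel(records, config$ch_sample_size, config$seed))

  gstats <- run_stage("groups", group_stats(summaries, meta, config$headline_measure))
  bins <- run_stage("groups", taxonomic_bins(summaries, meta, config$headline_measure))
  corr <- run_stage("groups", size_disorder_correlation(summaries, config$headline_measure))

  class_pairs <- setdiff(THERMAL_CLASSES, "mesophile")
  cls <- meta$thermal_class[match(summaries$species_id, meta$species_id)]
  headline <- summaries[[config$headline_measure]]
  comparisons <- run_stage("groups", {
    rows <- lapply(class_pairs, function(k) {
      a <- headline[cls == k]; b <- headline[cls == "mesophile"]
      if (length(a) == 0L || length(b) == 0L) return(NULL)
      mann_whitney(a, b, k, "mesophile")
    })
    do.call(rbind, rows)
  })

  tf <- run_stage("tf", tf_comparison(records, tracks, go, meta, config$threshold))

  bands_df <- run_stage("goprofile",
                        disorder_band_groups(summaries, meta, config$bands,
                                             config$headline_measure))
  groups <- list(H = meta$species_id[meta$thermal_class == "hyperthermophile"])
  for (nm in names(config$bands)) {
    groups[[nm]] <- bands_df$species_id[!is.na(bands_df$band) & bands_df$band == nm]
  }
  groups <- Filter(length, groups)
  go_profile <- run_stage("goprofile", {
    if (length(groups)) {
      suppressWarnings(go_profile_long_idr(per_protein, records, go, groups))
    } else NULL
  })

  result <- list(
    config = config,
    panel = panel,
    metadata = meta,
    per_protein = per_protein,
    summaries = summaries,
    ch = ch,
    group_stats = gstats,
    genus_bins = bins,
    size_correlation = corr,
    class_comparisons = comparisons,
    tf = tf,
    band_assignment = bands_df,
    go_profile = go_profile,
    provenance = list(
      package = "thermidp",
      scorer = attr(tracks, "provenance")$scorer,
      window = config$window,
      threshold = config$threshold,
      min_idr_len = config$min_idr_len,
      headline_measure = config$headline_measure,
      seed = config$seed
    )
  )
  class(result) <- "thermal_disorder_run"

  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

# Write the full report bundle of a run; deterministic byte-for-byte.
write_run <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- file.path(out_dir, "MANIFEST")
  writeLines("status: INCOMPLETE", manifest)
  if (!is.null(result$panel)) write_panel(result$panel, file.path(out_dir, "panel"))
  tables <- list(
    metadata = result$metadata,
    protein_disorder = result$per_protein,
    proteome_summary = result$summaries,
    chpoints = as.data.frame(result$ch),
    group_stats = result$group_stats,
    genus_bins = result$genus_bins,
    correlation = data.frame(statistic = "spearman_rho",
                             value = result$size_correlation$rho,
                             p_value = result$size_correlation$p_value,
                             n = result$size_correlation$n),
    class_comparisons = result$class_comparisons,
    tf_comparison = result$tf$rows,
    band_assignment = result$band_assignment
  )
  if (!is.null(result$tf$tests)) tables$tf_tests <- result$tf$tests
  if (!is.null(result$go_profile)) tables$go_profile <- result$go_profile
  write_report(tables, out_dir, meta = result$provenance)
  writeLines(summary_lines(result), file.path(out_dir, "summary.txt"))
  writeLines(c("status: COMPLETE",
               paste0("files: ", length(list.files(out_dir, recursive = TRUE)))),
             manifest)
  invisible(out_dir)
}

summary_lines <- function(x) {
  g <- x$group_stats
  lines <- c("thermal-disorder analysis summary",
             sprintf("headline measure: %s", x$config$headline_measure),
             sprintf("species: %d, proteins: %d", nrow(x$metadata),
                     nrow(x$per_protein)),
             "group medians (%):",
             sprintf("  %-17s n=%2d median=%6.2f mean=%6.2f sem=%5.2f range=[%.2f, %.2f]",
                     g$thermal_class, g$n, g$median, g$mean, g$sem, g$min, g$max),
             sprintf("size-disorder Spearman rho: %.3f (n=%d)",
                     x$size_correlation$rho, x$size_correlation$n))
  if (!is.null(x$class_comparisons)) {
    cc <- x$class_comparisons
    lines <- c(lines, "class vs mesophile (Mann-Whitney):",
               sprintf("  %-17s U=%8.1f p=%-10.3g %s", cc$label_a,
                       cc$statistic, cc$p_value, cc$stars))
  }
  lines
}

#' @export
print.thermal_disorder_run <- function(x, ...) {
  cat(summary_lines(x), sep = "\n")
  invisible(x)
}

#' @export
summary.thermal_disorder_run <- function(object, ...) {
  print(object)
  if (!is.null(object$tf$rows)) {
    cat("\ntranscription factors:\n")
    print(object$tf$rows, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
plot.thermal_disorder_run <- function(x, ...) {
  g <- x$group_stats
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  mid <- graphics::barplot(g$median, names.arg = abbreviate(g$thermal_class, 8),
                           ylim = c(0, max(g$max) * 1.1),
                           ylab = paste0(x$config$headline_measure, " (%)"),
                           main = "Disorder by thermal class (median, min-max)")
  graphics::arrows(mid, g$min, mid, g$max, angle = 90, code = 3, length = 0.05)
  invisible(x)
}
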