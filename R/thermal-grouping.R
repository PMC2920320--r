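# OGT resolution and thermal-class assignment; per-class descriptive
# statistics; taxonomic disorder binning; proteome-size/disorder correlation.

#' Resolve the OGT of a species
#'
#' An exact OGT value passes through; a range is replaced by its
#' arithmetic midpoint; a species with neither keeps OGT unknown (NA) and
#' must carry a thermal-class label instead.
#'
#' @param meta species metadata data.frame (columns `ogt_value`,
#'   `ogt_range_low`, `ogt_range_high`).
#' @return numeric vector of resolved OGTs (NA where unknown).
#' @export
resolve_ogt <- function(meta) {
  ogt <- meta$ogt_value
  has_range <- !is.na(meta$ogt_range_low) & !is.na(meta$ogt_range_high)
  use_mid <- is.na(ogt) & has_range
  ogt[use_mid] <- (meta$ogt_range_low[use_mid] + meta$ogt_range_high[use_mid]) / 2
  ogt
}

#' Classify an OGT value into a thermal class
#'
#' Classes: psychrophile (5-17 C), mesophile (20-42 C), thermophile
#' (45-75 C) and hyperthermophile (75-105 C). The printed ranges share the
#' 75 C boundary; 75 C is assigned to the hyperthermophiles. Values in the
#' gaps (17, 20) and (42, 45), or outside 5-105 C, fall in no printed
#' range and are assigned to the class with the nearest range boundary
#' (equidistant values to the colder class) with `flagged = TRUE` so the
#' caller can audit them.
#'
#' @param value OGT in degrees Celsius (vectorised, finite).
#' @return data.frame with columns `thermal_class` and `flagged`.
#' @export
classify_ogt <- function(value) {
  stopifnot(all(is.finite(value)))
  cls <- character(length(value))
  flag <- logical(length(value))
  for (i in seq_along(value)) {
    v <- value[i]
    if (v >= 75)              { cls[i] <- if (v <= 105) "hyperthermophile" else NA }
    else if (v >= 45)         cls[i] <- "thermophile"
    else if (v >= 20 && v <= 42) cls[i] <- "mesophile"
    else if (v >= 5 && v <= 17)  cls[i] <- "psychrophile"
    else                      cls[i] <- NA
    if (is.na(cls[i])) {
      # nearest range boundary; ties go to the colder class
      d <- vapply(THERMAL_CLASSES,
                  function(k) min(abs(v - OGT_RANGES[[k]])), numeric(1))
      cls[i] <- THERMAL_CLASSES[which.min(d)]
      flag[i] <- TRUE
    }
  }
  data.frame(thermal_class = cls, flagged = flag, stringsAsFactors = FALSE)
}

#' Attach resolved OGT and a consistent thermal class to metadata
#'
#' Resolves OGT ([resolve_ogt()]), derives the class from it
#' ([classify_ogt()]) where no class label is present, and keeps the given
#' label where OGT is unknown.
#'
#' @param meta species metadata data.frame.
#' @return `meta` with columns `ogt_resolved`, `thermal_class`,
#'   `ogt_flagged` filled in.
#' @export
assign_thermal_classes <- function(meta) {
  meta$ogt_resolved <- resolve_ogt(meta)
  meta$ogt_flagged <- FALSE
  known <- !is.na(meta$ogt_resolved)
  if (any(known)) {
    cl <- classify_ogt(meta$ogt_resolved[known])
    need <- is.na(meta$thermal_class[known])
    meta$thermal_class[known][need] <- cl$thermal_class[need]
    meta$ogt_flagged[known] <- cl$flagged
  }
  if (anyNA(meta$thermal_class)) {
    stop("species without resolvable thermal class: ",
         paste(meta$species_id[is.na(meta$thermal_class)], collapse = ", "))
  }
  meta
}

#' Per-class descriptive statistics of a disorder measure
#'
#' For each thermal class present, reports n, mean, median, standard error
#' of the mean (0 when n = 1), minimum and maximum of the chosen proteome
#' disorder measure.
#'
#' @param summaries per-species proteome summary table
#'   (see [summarize_proteome()]).
#' @param meta species metadata with `species_id` and `thermal_class`.
#' @param measure one of the proteome measures
#'   (default `"avg_protein_mean_score"`).
#' @return data.frame with one row per non-empty class, in canonical class
#'   order.
#' @export
group_stats <- function(summaries, meta, measure = "avg_protein_mean_score") {
  if (!measure %in% DISORDER_MEASURES) {
    stop("unknown measure '", measure, "'; choose one of: ",
         paste(DISORDER_MEASURES, collapse = ", "))
  }
  cls <- meta$thermal_class[match(summaries$species_id, meta$species_id)]
  if (anyNA(cls)) stop("species missing from metadata: ",
                       paste(summaries$species_id[is.na(cls)], collapse = ", "))
  x <- summaries[[measure]]
  rows <- lapply(THERMAL_CLASSES, function(k) {
    v <- x[cls == k]
    if (length(v) == 0L) return(NULL)
    data.frame(thermal_class = k, n = length(v), mean = mean(v),
               median = stats::median(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Genus-level average-disorder colour bins (percent): half-open on the
# left edge, top bin open-ended.
GENUS_BIN_EDGES <- c(0, 16, 20, 24, 28, Inf)
GENUS_BIN_LABELS <- c("white", "yellow", "ochre", "orange", "red")

#' Bin genera by average disorder
#'
#' Averages the chosen disorder measure per genus and assigns the colour
#' bin used for taxonomic display: white `[0, 16)`, yellow `[16, 20)`,
#' ochre `[20, 24)`, orange `[24, 28)`, red above 28.
#'
#' @inheritParams group_stats
#' @return data.frame with columns `genus`, `n_species`, `mean_disorder`,
#'   `bin`.
#' @export
taxonomic_bins <- function(summaries, meta, measure = "avg_protein_mean_score") {
  genus <- meta$genus[match(summaries$species_id, meta$species_id)]
  if (is.null(genus) || anyNA(genus)) stop("genus labels missing for some species")
  x <- summaries[[measure]]
  agg <- stats::aggregate(x, by = list(genus = genus), FUN = mean)
  cnt <- stats::aggregate(x, by = list(genus = genus), FUN = length)
  bin <- cut(agg$x, breaks = GENUS_BIN_EDGES, labels = GENUS_BIN_LABELS,
             right = FALSE, include.lowest = FALSE)
  data.frame(genus = agg$genus, n_species = cnt$x, mean_disorder = agg$x,
             bin = as.character(bin), stringsAsFactors = FALSE)
}

#' Proteome-size / disorder rank correlation
#'
#' Spearman rank correlation between proteome size (number of proteins)
#' and the chosen disorder measure across species. An ordinal statistic is
#' used because the size-disorder relation is claimed as monotone, not
#' linear.
#'
#' @inheritParams group_stats
#' @param summaries per-species summary table (needs `n_proteins`).
#' @return list with elements `rho`, `p_value`, `n`, `method`.
#' @export
size_disorder_correlation <- function(summaries, measure = "avg_protein_mean_score") {
  if (nrow(summaries) < 3L) stop("need at least 3 species for a correlation")
  x <- summaries$n_proteins
  y <- summaries[[measure]]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(summaries), method = "spearman")
}
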