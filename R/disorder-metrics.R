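# Per-protein and per-proteome disorder measures derived from score tracks.

#' Binarise a score track at the disorder threshold
#'
#' A residue is called disordered when its score is strictly above the
#' threshold (default 0.5).
#'
#' @param scores numeric vector of per-residue scores in `[0, 1]`.
#' @param threshold disorder threshold in (0, 1).
#' @return logical mask of the same length.
#' @export
binarize <- function(scores, threshold = 0.5) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)")
  }
  scores > threshold
}

#' Segment long intrinsically disordered regions
#'
#' Finds maximal runs of disordered residues of length at least
#' `min_idr_len` (default 30 consecutive residues) and returns them as
#' 1-based inclusive intervals.
#'
#' @param mask logical per-residue disorder mask.
#' @param min_idr_len minimum run length to report; >= 1.
#' @return data.frame with columns `start`, `end` (sorted, non-overlapping).
#' @export
segment_idrs <- function(mask, min_idr_len = 30L) {
  if (min_idr_len < 1) stop("min_idr_len must be >= 1")
  if (length(mask) == 0L) return(data.frame(start = integer(), end = integer()))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_idr_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Summarise disorder for one protein
#'
#' Computes the per-protein measures: mean disorder score, number of
#' disordered residues (score strictly above the threshold), the
#' mostly-disordered flag (strictly more than half of the residues
#' disordered), and the long-IDR intervals and residue count.
#'
#' @param scores numeric score vector for one protein.
#' @param protein_id id recorded in the output.
#' @param threshold disorder threshold in (0, 1).
#' @param min_idr_len minimal long-IDR length.
#' @return a list of class `protein_disorder` with fields `protein_id`,
#'   `length`, `mean_score`, `n_disordered`, `mostly_disordered`,
#'   `long_idrs` (interval data.frame) and `n_long_idr_residues`.
#' @export
summarize_protein <- function(scores, protein_id = "protein",
                              threshold = 0.5, min_idr_len = 30L) {
  mask <- binarize(scores, threshold)
  idrs <- segment_idrs(mask, min_idr_len)
  n <- length(scores)
  out <- list(
    protein_id = protein_id,
    length = n,
    mean_score = mean(scores),
    n_disordered = sum(mask),
    mostly_disordered = sum(mask) > n / 2,
    long_idrs = idrs,
    n_long_idr_residues = if (nrow(idrs)) sum(idrs$end - idrs$start + 1L) else 0L
  )
  class(out) <- "protein_disorder"
  out
}

#' @export
print.protein_disorder <- function(x, ...) {
  cat(sprintf("<protein_disorder> %s: %d aa, mean score %.3f, %d disordered, %d long IDR(s)\n",
              x$protein_id, x$length, x$mean_score, x$n_disordered, nrow(x$long_idrs)))
  invisible(x)
}

#' Per-protein disorder table for a set of score tracks
#'
#' Applies [summarize_protein()] to every track and binds the results
#' into one data.frame (interval lists reduced to counts).
#'
#' @param tracks named list of score vectors.
#' @inheritParams summarize_protein
#' @return data.frame with one row per protein.
#' @export
protein_disorder_table <- function(tracks, threshold = 0.5, min_idr_len = 30L) {
  rows <- lapply(names(tracks), function(id) {
    p <- summarize_protein(tracks[[id]], id, threshold, min_idr_len)
    data.frame(protein_id = p$protein_id, length = p$length,
               mean_score = p$mean_score, n_disordered = p$n_disordered,
               mostly_disordered = p$mostly_disordered,
               n_long_idrs = nrow(p$long_idrs),
               n_long_idr_residues = p$n_long_idr_residues,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise disorder for one proteome
#'
#' Aggregates per-protein disorder rows into the proteome-level measures,
#' reporting both averaging conventions: the mean of per-protein mean
#' scores (each protein weighted equally) and the pooled residue-level
#' fraction (each residue weighted equally). All measures are percentages.
#'
#' @param proteins per-protein table as built by the pipeline (columns
#'   `length`, `mean_score`, `n_disordered`, `mostly_disordered`,
#'   `n_long_idr_residues`), or a list of `protein_disorder` objects.
#' @param species_id id recorded in the output.
#' @param threshold threshold used upstream (echoed for the
#'   proteins-above-threshold measure).
#' @return one-row data.frame with columns `species_id`,
#'   `avg_protein_mean_score`, `pct_disordered_residues`,
#'   `pct_proteins_mean_above`, `pct_mostly_disordered`,
#'   `pct_long_idr_residues`, `n_proteins`, `n_residues`.
#' @export
summarize_proteome <- function(proteins, species_id = "species", threshold = 0.5) {
  if (is.list(proteins) && !is.data.frame(proteins)) {
    proteins <- do.call(rbind, lapply(proteins, function(p) {
      data.frame(length = p$length, mean_score = p$mean_score,
                 n_disordered = p$n_disordered,
                 mostly_disordered = p$mostly_disordered,
                 n_long_idr_residues = p$n_long_idr_residues)
    }))
  }
  if (is.null(proteins) || nrow(proteins) == 0L) {
    stop("summarize_proteome: empty protein list")
  }
  n_res <- sum(proteins$length)
  data.frame(
    species_id = species_id,
    avg_protein_mean_score = 100 * mean(proteins$mean_score),
    pct_disordered_residues = 100 * sum(proteins$n_disordered) / n_res,
    pct_proteins_mean_above = 100 * mean(proteins$mean_score > threshold),
    pct_mostly_disordered = 100 * mean(proteins$mostly_disordered),
    pct_long_idr_residues = 100 * sum(proteins$n_long_idr_residues) / n_res,
    n_proteins = nrow(proteins),
    n_residues = n_res,
    stringsAsFactors = FALSE
  )
}

# The proteome measures selectable as "headline" disorder measures.
DISORDER_MEASURES <- c("avg_protein_mean_score", "pct_disordered_residues",
                       "pct_proteins_mean_above", "pct_mostly_disordered",
                       "pct_long_idr_residues")
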