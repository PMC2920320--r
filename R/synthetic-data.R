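# Seeded synthetic panels: proteomes with composition-biased ordered and
# disordered segments, species metadata with OGT labels, and GO annotations
# including transcription factors. The generator supplies ground truth so
# every downstream stage is testable without genome downloads.

CLASS_CODES <- c(psychrophile = "PSY", mesophile = "MES",
                 thermophile = "THE", hyperthermophile = "HYP")

#' Configuration of a synthetic prokaryote panel
#'
#' Collects every knob of the synthetic generator. Per-class arguments
#' accept a single value (recycled) or a vector named by thermal class
#' (short forms `psychro`/`meso`/`thermo`/`hyper` accepted).
#'
#' The defaults encode the study conditions the analysis is exercised
#' under: hyperthermophiles with small proteomes (half the mesophile mean)
#' and low disorder (3% of residues in disordered segments), psychrophiles
#' low (4%), thermophiles (10%) and mesophiles (12%) higher, and
#' hyperthermophile transcription factors shorter (factor 0.7) and less
#' disordered (factor 0.5) than mesophilic ones.
#'
#' @param n_species_per_class species count per thermal class.
#' @param proteome_size_by_class mean protein count per class (each
#'   species' size is jittered uniformly by +/-20%).
#' @param disorder_target_by_class target fraction of residues inside
#'   disordered segments, per class, in `[0, 1]`.
#' @param tf_fraction fraction of proteins annotated as transcription
#'   factors (GO:0003700), in `[0, 1]`.
#' @param tf_length_factor_by_class multiplicative length factor applied
#'   to TF proteins, per class.
#' @param tf_disorder_factor_by_class multiplicative factor applied to the
#'   disorder target of TF proteins, per class.
#' @param mean_protein_length mean protein length in residues (>= 1);
#'   individual lengths are jittered by +/-50% with a floor of 30.
#' @param enrichment probability that a residue of a disordered
#'   (respectively ordered) segment is drawn from the disorder-promoting
#'   (order-promoting) residue set; the remaining mass is uniform over the
#'   other canonical residues.
#' @param seg_len_disordered,seg_len_ordered mean geometric segment
#'   lengths; defaults 40 and 80 so both sub-threshold (<30) and long
#'   disordered regions occur.
#' @param seed integer master seed. A per-species stream is split off it,
#'   so adding species to one class does not perturb the others.
#' @return a validated list of class `panel_config`.
#' @export
panel_config <- function(n_species_per_class = c(psychrophile = 6, mesophile = 6,
                                                 thermophile = 6, hyperthermophile = 6),
                         proteome_size_by_class = c(psychrophile = 400, mesophile = 600,
                                                    thermophile = 500, hyperthermophile = 300),
                         disorder_target_by_class = c(psychrophile = 0.04, mesophile = 0.12,
                                                      thermophile = 0.10, hyperthermophile = 0.03),
                         tf_fraction = 0.03,
                         tf_length_factor_by_class = c(psychrophile = 0.7, mesophile = 1,
                                                       thermophile = 1, hyperthermophile = 0.7),
                         tf_disorder_factor_by_class = c(psychrophile = 1, mesophile = 1,
                                                         thermophile = 1, hyperthermophile = 0.5),
                         mean_protein_length = 300,
                         enrichment = 0.8,
                         seg_len_disordered = 40,
                         seg_len_ordered = 80,
                         seed = 1L) {
  cfg <- list(
    n_species_per_class = expand_by_class(n_species_per_class),
    proteome_size_by_class = expand_by_class(proteome_size_by_class),
    disorder_target_by_class = expand_by_class(disorder_target_by_class),
    tf_fraction = tf_fraction,
    tf_length_factor_by_class = expand_by_class(tf_length_factor_by_class, fill = 1),
    tf_disorder_factor_by_class = expand_by_class(tf_disorder_factor_by_class, fill = 1),
    mean_protein_length = mean_protein_length,
    enrichment = enrichment,
    seg_len_disordered = seg_len_disordered,
    seg_len_ordered = seg_len_ordered,
    seed = as.integer(seed)
  )
  if (any(cfg$n_species_per_class < 0)) stop("species counts must be >= 0")
  if (any(cfg$proteome_size_by_class < 0)) stop("proteome sizes must be >= 0")
  if (any(cfg$disorder_target_by_class < 0 | cfg$disorder_target_by_class > 1)) {
    stop("disorder targets must be in [0, 1]")
  }
  if (tf_fraction < 0 || tf_fraction > 1) stop("tf_fraction must be in [0, 1]")
  if (mean_protein_length < 1) stop("mean_protein_length must be >= 1")
  if (enrichment < 0 || enrichment > 1) stop("enrichment must be in [0, 1]")
  class(cfg) <- "panel_config"
  cfg
}

# Recycle / name-normalise a per-class argument into the canonical order;
# classes absent from a partially named vector get `fill`.
expand_by_class <- function(x, fill = 0) {
  if (is.null(names(x)) || all(!nzchar(names(x)))) {
    if (length(x) == 1L) x <- rep(x, length(THERMAL_CLASSES))
    stopifnot(length(x) == length(THERMAL_CLASSES))
    names(x) <- THERMAL_CLASSES
    return(x)
  }
  names(x) <- normalize_class(names(x))
  out <- stats::setNames(rep(fill, length(THERMAL_CLASSES)), THERMAL_CLASSES)
  out[names(x)] <- x
  out
}

# Per-species deterministic seed stream: independent of how many other
# species exist, so adding species never perturbs existing ones. Stage
# separates metadata / proteome / annotation draws.
species_seed <- function(seed, species_index, stage = 0L) {
  ((seed %% 2147483647) * 48271 + species_index * 16807 + stage * 7919) %%
    2147483646 + 1
}

species_index_of <- function(class, within) {
  match(class, THERMAL_CLASSES) * 10000L + within
}

#' Generate species metadata for a synthetic panel
#'
#' One row per species: unique id, order and genus labels (genera hold up
#' to two species), an OGT drawn uniformly within the class OGT range, and
#' the class label. To exercise all metadata conventions, the OGT is
#' reported as an exact value for most species, as a +/-2 C range
#' (midpoint equal to the drawn value) for some, and omitted (class label
#' only) for a few.
#'
#' @param config a [panel_config()].
#' @return data.frame with columns `species_id`, `order`, `genus`,
#'   `ogt_value`, `ogt_range_low`, `ogt_range_high`, `thermal_class`,
#'   plus internal columns `species_index` and `ogt_true`.
#' @export
make_species_metadata <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  if (sum(config$n_species_per_class) == 0) {
    stop("empty panel: every class has zero species")
  }
  rows <- list()
  for (k in THERMAL_CLASSES) {
    n <- config$n_species_per_class[[k]]
    if (n == 0) next
    code <- CLASS_CODES[[k]]
    rng <- OGT_RANGES[[k]]
    for (i in seq_len(n)) {
      idx <- species_index_of(k, i)
      ogt <- local_seed(species_seed(config$seed, idx, 0L), {
        c(stats::runif(1, rng[1], rng[2]), stats::runif(1))
      })
      mode <- if (ogt[2] < 0.6) "exact" else if (ogt[2] < 0.9) "range" else "class"
      v <- round(ogt[1], 1)
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sprintf("%s%02d", code, i),
        order = paste0("order_", code),
        genus = sprintf("%s_genus%02d", code, ceiling(i / 2)),
        ogt_value = if (mode == "exact") v else NA_real_,
        ogt_range_low = if (mode == "range") v - 2 else NA_real_,
        ogt_range_high = if (mode == "range") v + 2 else NA_real_,
        thermal_class = k,
        species_index = idx,
        ogt_true = v,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Residue-sampling probability vectors for the two segment types.
segment_probs <- function(enrichment) {
  dis <- stats::setNames(rep((1 - enrichment) / 12, 20), CANONICAL_AA)
  dis[disorder_promoting] <- enrichment / 8
  ord <- stats::setNames(rep((1 - enrichment) / 13, 20), CANONICAL_AA)
  ord[order_promoting] <- enrichment / 7
  list(disordered = dis, ordered = ord)
}

#' Generate one species' proteome with ground truth
#'
#' Each protein is a concatenation of segments, each independently
#' disordered with probability `p = 2t / (1 + t)` (so that with geometric
#' mean lengths 40 for disordered and 80 for ordered segments the expected
#' fraction of residues in disordered segments equals the class target
#' `t`). Disordered segments draw residues from the disorder-promoting set
#' with probability `enrichment`, ordered segments mirror this with the
#' order-promoting set. A seeded subset of proteins is marked as
#' transcription factors; TF lengths and disorder targets are scaled by
#' the class TF factors.
#'
#' @param meta one metadata row (as from [make_species_metadata()]).
#' @param config a [panel_config()].
#' @return list with `records` (protein-record data.frame), `truth`
#'   (ground-truth disordered intervals: `protein_id`, `start`, `end`,
#'   1-based inclusive) and `tf_ids` (character vector).
#' @export
make_proteome <- function(meta, config) {
  stopifnot(inherits(config, "panel_config"), nrow(meta) == 1L)
  k <- meta$thermal_class
  if (is.na(k)) stop("species ", meta$species_id, " has no thermal class")
  idx <- if (!is.null(meta$species_index)) meta$species_index else 0L
  probs <- segment_probs(config$enrichment)
  t_base <- config$disorder_target_by_class[[k]]
  lf_tf <- config$tf_length_factor_by_class[[k]]
  df_tf <- config$tf_disorder_factor_by_class[[k]]

  local_seed(species_seed(config$seed, idx, 1L), {
    n <- max(1L, round(config$proteome_size_by_class[[k]] * stats::runif(1, 0.8, 1.2)))
    n_tf <- round(config$tf_fraction * n)
    tf_flag <- rep(FALSE, n)
    if (n_tf > 0) tf_flag[sample.int(n, n_tf)] <- TRUE
    ids <- sprintf("%s_P%05d", meta$species_id, seq_len(n))
    seqs <- character(n)
    truth <- vector("list", n)
    for (j in seq_len(n)) {
      lf <- if (tf_flag[j]) lf_tf else 1
      L <- max(30L, round(config$mean_protein_length * lf * stats::runif(1, 0.5, 1.5)))
      t_eff <- min(1, max(0, t_base * (if (tf_flag[j]) df_tf else 1)))
      p_seg <- 2 * t_eff / (1 + t_eff)
      type <- draw_segment_types(L, p_seg, config$seg_len_disordered,
                                 config$seg_len_ordered)
      res <- character(L)
      i_dis <- which(type); i_ord <- which(!type)
      if (length(i_dis)) {
        res[i_dis] <- sample(CANONICAL_AA, length(i_dis), replace = TRUE,
                             prob = probs$disordered)
      }
      if (length(i_ord)) {
        res[i_ord] <- sample(CANONICAL_AA, length(i_ord), replace = TRUE,
                             prob = probs$ordered)
      }
      seqs[j] <- paste(res, collapse = "")
      iv <- segment_idrs(type, 1L)  # maximal true runs = disordered segments
      if (nrow(iv)) {
        truth[[j]] <- data.frame(protein_id = ids[j], start = iv$start,
                                 end = iv$end, stringsAsFactors = FALSE)
      }
    }
    list(
      records = data.frame(protein_id = ids, species_id = meta$species_id,
                           sequence = seqs, stringsAsFactors = FALSE),
      truth = if (length(tr <- truth[!vapply(truth, is.null, logical(1))])) {
        do.call(rbind, tr)
      } else data.frame(protein_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE),
      tf_ids = ids[tf_flag]
    )
  })
}

# Per-residue segment-type vector of length L: TRUE = disordered segment.
draw_segment_types <- function(L, p_seg, mean_dis, mean_ord) {
  if (p_seg <= 0) return(rep(FALSE, L))
  if (p_seg >= 1) return(rep(TRUE, L))
  types <- logical(0)
  lens <- integer(0)
  while (sum(lens) < L) {
    m <- max(4L, ceiling((L - sum(lens)) / (p_seg * mean_dis + (1 - p_seg) * mean_ord)) + 2L)
    ty <- stats::runif(m) < p_seg
    ln <- ifelse(ty, stats::rgeom(m, 1 / mean_dis), stats::rgeom(m, 1 / mean_ord)) + 1L
    types <- c(types, ty)
    lens <- c(lens, ln)
  }
  rep(types, lens)[seq_len(L)]
}

#' Generate GO annotations for a proteome
#'
#' Transcription-factor proteins receive the molecular-function term
#' GO:0003700; every other protein draws one biological-process term from
#' a fixed vocabulary (translation, transport, regulation of
#' transcription, signal transduction, proteolysis, chemotaxis, ...).
#' Deterministic under the config seed.
#'
#' @param records protein-record data.frame.
#' @param tf_ids protein ids to annotate as transcription factors.
#' @param config a [panel_config()] (supplies the seed).
#' @param seed override seed (defaults to the config seed).
#' @return data.frame with columns `protein_id`, `go_id`, `go_name`,
#'   `aspect`, one row per protein, in panel order.
#' @export
make_go_annotations <- function(records, tf_ids = character(), config = panel_config(),
                                seed = config$seed) {
  stopifnot(nrow(records) >= 1L)
  if (config$tf_fraction < 0 || config$tf_fraction > 1) {
    stop("tf_fraction must be in [0, 1]")
  }
  is_tf <- records$protein_id %in% tf_ids
  n_other <- sum(!is_tf)
  bp_idx <- local_seed(seed, sample.int(nrow(GO_BP_VOCAB), n_other, replace = TRUE))
  out <- data.frame(protein_id = records$protein_id,
                    go_id = NA_character_, go_name = NA_character_,
                    aspect = NA_character_, stringsAsFactors = FALSE)
  out$go_id[is_tf] <- GO_TF[["go_id"]]
  out$go_name[is_tf] <- GO_TF[["go_name"]]
  out$aspect[is_tf] <- GO_TF[["aspect"]]
  out$go_id[!is_tf] <- GO_BP_VOCAB$go_id[bp_idx]
  out$go_name[!is_tf] <- GO_BP_VOCAB$go_name[bp_idx]
  out$aspect[!is_tf] <- GO_BP_VOCAB$aspect[bp_idx]
  out
}

#' Simulate a full synthetic panel
#'
#' Runs [make_species_metadata()], [make_proteome()] per species and
#' [make_go_annotations()], and bundles the results.
#'
#' @param config a [panel_config()].
#' @return object of class `idp_panel`: list with `config`, `metadata`,
#'   `records`, `truth`, `tf_ids`, `go`.
#' @export
simulate_panel <- function(config = panel_config()) {
  meta <- make_species_metadata(config)
  parts <- lapply(seq_len(nrow(meta)), function(i) {
    prot <- make_proteome(meta[i, , drop = FALSE], config)
    prot$go <- make_go_annotations(prot$records, prot$tf_ids, config,
                                   seed = species_seed(config$seed,
                                                       meta$species_index[i], 2L))
    prot
  })
  panel <- list(
    config = config,
    metadata = meta,
    records = do.call(rbind, lapply(parts, `[[`, "records")),
    truth = do.call(rbind, lapply(parts, `[[`, "truth")),
    tf_ids = unlist(lapply(parts, `[[`, "tf_ids"), use.names = FALSE),
    go = do.call(rbind, lapply(parts, `[[`, "go"))
  )
  rownames(panel$records) <- rownames(panel$truth) <- rownames(panel$go) <- NULL
  class(panel) <- "idp_panel"
  panel
}

#' @export
print.idp_panel <- function(x, ...) {
  cat(sprintf("<idp_panel> %d species, %d proteins (%d TFs), seed %d\n",
              nrow(x$metadata), nrow(x$records), length(x$tf_ids),
              x$config$seed))
  tab <- table(x$metadata$thermal_class)[THERMAL_CLASSES]
  tab[is.na(tab)] <- 0
  cat("  species per class:",
      paste(sprintf("%s=%d", THERMAL_CLASSES, tab), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth disordered fraction per protein or overall
#'
#' @param panel an `idp_panel`.
#' @return named numeric vector: fraction of residues inside ground-truth
#'   disordered segments, per protein.
#' @export
truth_disordered_fraction <- function(panel) {
  len <- nchar(panel$records$sequence)
  names(len) <- panel$records$protein_id
  dis <- stats::setNames(rep(0, length(len)), names(len))
  if (nrow(panel$truth)) {
    per <- tapply(panel$truth$end - panel$truth$start + 1L,
                  panel$truth$protein_id, sum)
    dis[names(per)] <- per
  }
  dis / len
}

#' Write a synthetic panel to disk
#'
#' One FASTA per species (headers `speciesID|proteinID`), `metadata.tsv`,
#' `go.tsv` and `truth.tsv` (1-based inclusive ground-truth intervals).
#' Byte-identical across reruns with the same config.
#'
#' @param panel an `idp_panel`.
#' @param dir output directory.
#' @return invisibly the directory.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in panel$metadata$species_id) {
    write_fasta(panel$records[panel$records$species_id == sp, , drop = FALSE],
                file.path(dir, paste0(sp, ".fasta")))
  }
  meta_cols <- c("species_id", "order", "genus", "ogt_value",
                 "ogt_range_low", "ogt_range_high", "thermal_class")
  write_tsv(panel$metadata[, meta_cols], file.path(dir, "metadata.tsv"))
  write_tsv(panel$go, file.path(dir, "go.tsv"))
  write_tsv(panel$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
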