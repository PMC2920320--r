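# Accessors for the packaged reference tables. Both tables are SYNTHETIC
# stand-ins: the original study datasets (332 NCBI genomes with OGT
# annotations; SwissProt transcription factors per thermal class) are not
# redistributable here, so the packaged tables reproduce only the
# published marginal counts — 332 species of which 195 carry an exact
# OGT, 124 an OGT range and 13 only a class label; and 18 / 1581 / 62 /
# 101 transcription factors in psychrophiles / mesophiles / thermophiles /
# hyperthermophiles. Row-level content (ids, taxa, exact temperatures,
# lengths) is generated.

#' Packaged synthetic species table
#'
#' Path to (or parsed content of) the packaged species metadata table,
#' a synthetic stand-in whose OGT-availability structure matches the
#' published dataset description (332 species: 195 exact OGT, 124 range,
#' 13 class-only).
#'
#' @return `species_table_path()`: the file path;
#'   `read_packaged_species_table()`: the parsed metadata data.frame.
#' @export
species_table_path <- function() {
  system.file("extdata", "species_ogt_synthetic.tsv", package = "thermidp",
              mustWork = TRUE)
}

#' @rdname species_table_path
#' @export
read_packaged_species_table <- function() {
  read_species_metadata(species_table_path())
}

#' Packaged synthetic transcription-factor table
#'
#' Path to (or parsed content of) the packaged TF table, a synthetic
#' stand-in with one row per annotated transcription factor and the
#' published per-class counts (psychrophiles 18, mesophiles 1581,
#' thermophiles 62, hyperthermophiles 101).
#'
#' @return `tf_table_path()`: the file path; `read_packaged_tf_table()`:
#'   a data.frame with columns `protein_id`, `thermal_class`, `go_id`.
#' @export
tf_table_path <- function() {
  system.file("extdata", "tf_annotations_synthetic.tsv", package = "thermidp",
              mustWork = TRUE)
}

#' @rdname species_table_path
#' @export
read_packaged_tf_table <- function() {
  tab <- read_tsv(tf_table_path())
  tab$thermal_class <- normalize_class(tab$thermal_class)
  tab
}

#' Count species by OGT availability
#'
#' Tabulates a species metadata table into the dataset-descriptive counts:
#' total species, species with an exact OGT value, with an OGT range, and
#' with a thermal class label only.
#'
#' @param meta metadata data.frame as from [read_species_metadata()].
#' @return named list `total`, `exact`, `range`, `class_only`.
#' @export
count_ogt_availability <- function(meta) {
  has_exact <- !is.na(meta$ogt_value)
  has_range <- !has_exact & !is.na(meta$ogt_range_low) & !is.na(meta$ogt_range_high)
  list(total = nrow(meta),
       exact = sum(has_exact),
       range = sum(has_range),
       class_only = sum(!has_exact & !has_range))
}
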