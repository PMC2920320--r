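# Readers and writers for every file format the pipeline touches.
# TSV dialect: tab-separated, UTF-8, mandatory header row, "." for missing.

#' Read a proteome FASTA file
#'
#' Parses a FASTA file of amino-acid sequences into a protein-record table.
#' Headers of the form `"speciesID|proteinID"` populate both id columns;
#' headers without a `"|"` are taken whole as the protein id with the
#' species id falling back to the file name stem. Sequences are upper-cased;
#' the ambiguity codes X, B, Z, U are retained.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `protein_id`, `species_id`,
#'   `sequence`, in file order. An empty file yields zero rows.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0L) return(empty_records())
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA: sequence before header at line ", first)
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  stem <- sub("\\.[^.]*$", "", basename(path))
  has_pipe <- grepl("|", headers, fixed = TRUE)
  species_id <- ifelse(has_pipe, sub("\\|.*$", "", headers), stem)
  protein_id <- ifelse(has_pipe, sub("^[^|]*\\|", "", headers), headers)
  out <- data.frame(protein_id = protein_id, species_id = species_id,
                    sequence = toupper(as.character(seqs)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_records(out)
  out
}

empty_records <- function() {
  data.frame(protein_id = character(), species_id = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

validate_records <- function(records) {
  if (nrow(records) == 0L) return(invisible(records))
  if (any(!nzchar(records$protein_id))) stop("empty protein id in records")
  if (any(!nzchar(records$sequence))) stop("zero-length sequence in records")
  if (any(grepl("\\s", records$sequence))) stop("whitespace inside a sequence")
  invisible(records)
}

#' Write protein records as FASTA
#'
#' Inverse of [read_fasta()]: emits one record per protein with headers
#' `"speciesID|proteinID"`, 60 residues per line.
#'
#' @param records data.frame with `protein_id`, `species_id`, `sequence`.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  validate_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$species_id[i], "|", records$protein_id[i]), con)
    seq <- records$sequence[i]
    starts <- seq(1L, nchar(seq), by = 60L)
    writeLines(substring(seq, starts, pmin(starts + 59L, nchar(seq))), con)
  }
  invisible(path)
}

#' Read IUPred-style per-residue score tracks
#'
#' Parses whitespace-separated three-column blocks (position, residue,
#' score). Lines starting with `#` carry the protein id for the following
#' block (`"# <protein_id>"`); blank lines are ignored. Positions must be
#' consecutive from 1 within each block and scores must lie in `[0, 1]`.
#'
#' @param path path to a score-track file.
#' @return a named list of numeric score vectors, one per protein block.
#' @export
read_score_tracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  tracks <- list()
  cur_id <- NULL
  cur_pos <- integer()
  cur_score <- numeric()
  n_anon <- 0L
  flush <- function() {
    if (length(cur_score) == 0L) return(invisible(NULL))
    if (is.null(cur_id)) {
      n_anon <<- n_anon + 1L
      cur_id <<- sprintf("track%03d", n_anon)
    }
    if (!identical(cur_pos, seq_along(cur_pos))) {
      stop("score track '", cur_id, "': positions not consecutive from 1")
    }
    tracks[[cur_id]] <<- cur_score
    cur_id <<- NULL
    cur_pos <<- integer()
    cur_score <<- numeric()
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      flush()
      id <- trimws(sub("^#+", "", line))
      if (nzchar(id)) cur_id <- id
      next
    }
    fields <- strsplit(line, "\\s+")[[1]]
    if (length(fields) < 3L) stop("line ", i, ": expected 3 columns (position residue score)")
    pos <- suppressWarnings(as.integer(fields[1]))
    score <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(pos) || is.na(score)) stop("line ", i, ": unparseable position or score")
    if (score < 0 || score > 1) stop("line ", i, ": score ", score, " outside [0,1]")
    cur_pos <- c(cur_pos, pos)
    cur_score <- c(cur_score, score)
  }
  flush()
  tracks
}

#' Write score tracks in IUPred-style format
#'
#' @param tracks named list of numeric vectors in `[0, 1]`.
#' @param records optional protein-record table supplying residue letters;
#'   without it the residue column is written as `"-"`.
#' @param path output path.
#' @export
write_score_tracks <- function(tracks, path, records = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  res_by_id <- NULL
  if (!is.null(records)) {
    res_by_id <- stats::setNames(records$sequence, records$protein_id)
  }
  for (id in names(tracks)) {
    sc <- tracks[[id]]
    writeLines(paste0("# ", id), con)
    res <- if (!is.null(res_by_id) && !is.na(res_by_id[id])) {
      split_residues(res_by_id[[id]])
    } else rep("-", length(sc))
    writeLines(sprintf("%d\t%s\t%.6f", seq_along(sc), res, sc), con)
  }
  invisible(path)
}

#' Read species metadata
#'
#' Reads the species table (TSV with columns `species_id`, `order`,
#' `genus`, `ogt_value`, `ogt_range_low`, `ogt_range_high`,
#' `thermal_class`; `"."` marks missing values). A species may carry an
#' exact OGT, an OGT range, or neither — but a species with neither an
#' OGT value, a range, nor a thermal class is rejected.
#'
#' @param path path to the metadata TSV.
#' @return a data.frame with numeric OGT columns (NA where missing) and a
#'   normalised `thermal_class` column (NA where missing).
#' @export
read_species_metadata <- function(path) {
  meta <- read_tsv(path)
  needed <- c("species_id", "ogt_value", "ogt_range_low", "ogt_range_high",
              "thermal_class")
  missing_cols <- setdiff(c("species_id", "thermal_class"), names(meta))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(needed, names(meta))) meta[[col]] <- NA
  for (col in c("ogt_value", "ogt_range_low", "ogt_range_high")) {
    meta[[col]] <- suppressWarnings(as.numeric(meta[[col]]))
  }
  meta$thermal_class <- ifelse(is.na(meta$thermal_class) | meta$thermal_class == ".",
                               NA_character_, meta$thermal_class)
  known <- !is.na(meta$thermal_class)
  meta$thermal_class[known] <- normalize_class(meta$thermal_class[known])
  has_range <- !is.na(meta$ogt_range_low) & !is.na(meta$ogt_range_high)
  if (any(has_range & meta$ogt_range_low > meta$ogt_range_high)) {
    stop("metadata: ogt_range_low > ogt_range_high for some species")
  }
  orphan <- is.na(meta$ogt_value) & !has_range & is.na(meta$thermal_class)
  if (any(orphan)) {
    stop("species without OGT value, range, or thermal class: ",
         paste(meta$species_id[orphan], collapse = ", "))
  }
  meta
}

#' Read a protein-to-GO annotation table
#'
#' @param path TSV with columns `protein_id`, `go_id`, `go_name`, `aspect`.
#' @return the annotation data.frame.
#' @export
read_go_table <- function(path) {
  go <- read_tsv(path)
  needed <- c("protein_id", "go_id")
  missing_cols <- setdiff(needed, names(go))
  if (length(missing_cols)) {
    stop("GO table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  go
}

#' Read a TSV table in the package dialect
#'
#' Tab-separated, UTF-8, mandatory header row, `"."` read as missing.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write a table as TSV
#'
#' Tab-separated, header row, `"."` for missing values; numbers are
#' formatted with up to 6 significant digits so reruns are byte-identical.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  out <- x
  for (col in names(out)) {
    v <- out[[col]]
    if (is.numeric(v)) {
      v <- ifelse(is.na(v), ".", trimws(formatC(v, digits = 6, format = "g")))
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "."
    }
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Check sequence/score-track pairing
#'
#' Rejects a panel in which any score track's length differs from its
#' protein's sequence length, or any panel protein lacks a track.
#'
#' @param records protein-record table.
#' @param tracks named list of score vectors.
#' @return invisibly TRUE when the pairing is complete and consistent.
#' @export
check_track_pairing <- function(records, tracks) {
  missing_ids <- setdiff(records$protein_id, names(tracks))
  if (length(missing_ids)) {
    stop("score tracks missing for protein(s): ",
         paste(utils::head(missing_ids, 10L), collapse = ", "),
         if (length(missing_ids) > 10L) ", ..." else "")
  }
  len_seq <- nchar(records$sequence)
  len_trk <- vapply(tracks[records$protein_id], length, integer(1))
  bad <- records$protein_id[len_seq != len_trk]
  if (length(bad)) {
    stop("track length != sequence length for: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write the report tables of a run
#'
#' Writes each table of a named list as a TSV file and mirrors the whole
#' list into one JSON report.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @param meta optional provenance list echoed into the JSON report.
#' @return invisibly the paths written.
#' @export
write_report <- function(tables, dir, meta = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  payload <- c(if (!is.null(meta)) list(provenance = meta), list(tables = tables))
  jsonlite::write_json(payload, jp, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(paths, jp))
}
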