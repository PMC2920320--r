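# Charge-hydropathy (Uversky) analysis and amino-acid composition profiles.
# The separating line H = (R + 1.151) / 2.785 divides predicted disordered
# (low hydropathy) from ordered proteins.

CH_SLOPE_DIV <- 2.785
CH_OFFSET <- 1.151

#' Mean net charge of a sequence
#'
#' `R = |n(Arg) + n(Lys) - n(Asp) - n(Glu)| / n`, where `n` counts all
#' non-ambiguous residues; only Arg, Lys, Glu and Asp contribute charge
#' (His is treated as neutral). Ambiguity codes X, B, Z, U are excluded
#' from both numerator and denominator.
#'
#' @param sequence amino-acid string.
#' @return mean absolute net charge per residue, in `[0, 1]`.
#' @export
mean_net_charge <- function(sequence) {
  res <- counted_residues(sequence)
  pos <- sum(res %in% c("R", "K"))
  neg <- sum(res %in% c("D", "E"))
  abs(pos - neg) / length(res)
}

#' Mean normalised Kyte-Doolittle hydropathy
#'
#' Per-residue hydropathy on the min-max normalised Kyte-Doolittle scale
#' (`(kd + 4.5) / 9`; Ile 1, Arg 0), averaged over all non-ambiguous
#' residues.
#'
#' @param sequence amino-acid string.
#' @return mean hydropathy in `[0, 1]`.
#' @export
mean_hydropathy <- function(sequence) {
  res <- counted_residues(sequence)
  mean(kd_normalized[res])
}

counted_residues <- function(sequence) {
  res <- split_residues(sequence)
  res <- res[res %in% CANONICAL_AA]
  if (length(res) == 0L) {
    stop("sequence contains no canonical residues; charge/hydropathy undefined")
  }
  res
}

#' Charge-hydropathy boundary and classification
#'
#' `ch_boundary()` evaluates the separating line `H = (R + 1.151) / 2.785`;
#' `ch_classify()` calls a protein disordered when its mean hydropathy lies
#' strictly below the boundary at its mean net charge, and ordered
#' otherwise (a point exactly on the line is called ordered).
#'
#' @param R mean net charge (vectorised).
#' @param H mean normalised hydropathy (vectorised).
#' @return `ch_boundary`: boundary hydropathy; `ch_classify`: character
#'   vector `"ordered"`/`"disordered"`.
#' @export
ch_boundary <- function(R) (R + CH_OFFSET) / CH_SLOPE_DIV

#' @rdname ch_boundary
#' @export
ch_classify <- function(R, H) {
  stopifnot(all(is.finite(R)), all(is.finite(H)))
  ifelse(H < ch_boundary(R), "disordered", "ordered")
}

#' Charge-hydropathy points for a protein panel
#'
#' Computes one CH point (mean net charge, mean normalised hydropathy,
#' order/disorder call) per protein. Panels larger than `sample_size` are
#' first reduced to a seeded uniform sample without replacement, mirroring
#' the use of 2000 randomly selected proteins per thermal category.
#'
#' @param records protein-record table.
#' @param sample_size maximum number of proteins to use (default 2000).
#' @param seed integer seed for the subsample.
#' @return data.frame of class `ch_panel` with columns `protein_id`, `R`,
#'   `H`, `boundary_H`, `call`.
#' @export
ch_panel <- function(records, sample_size = 2000L, seed = 1L) {
  stopifnot(nrow(records) >= 1L)
  idx <- seq_len(nrow(records))
  if (nrow(records) > sample_size) {
    idx <- local_seed(seed, sample(idx, sample_size))
  }
  recs <- records[idx, , drop = FALSE]
  R <- vapply(recs$sequence, mean_net_charge, numeric(1), USE.NAMES = FALSE)
  H <- vapply(recs$sequence, mean_hydropathy, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(protein_id = recs$protein_id, R = R, H = H,
                    boundary_H = ch_boundary(R),
                    call = ch_classify(R, H), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ch_panel", class(out))
  out
}

#' @export
plot.ch_panel <- function(x, ...) {
  graphics::plot(x$R, x$H, col = ifelse(x$call == "disordered", "red", "blue"),
                 pch = 20, xlab = "mean net charge R",
                 ylab = "mean normalized hydropathy H",
                 main = "Charge-hydropathy plot", ...)
  rr <- seq(0, max(x$R, 0.4), length.out = 50)
  graphics::lines(rr, ch_boundary(rr), lwd = 2)
  invisible(x)
}

# Run an expression under a temporary seed without disturbing the caller's
# RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Amino-acid composition profile
#'
#' Frequency of each of the 20 canonical residues over all residues of a
#' record set (ambiguity codes excluded). Frequencies sum to 1.
#'
#' @param records protein-record table (or character vector of sequences).
#' @return named numeric vector of length 20, ordered as `CANONICAL_AA`.
#' @export
composition_profile <- function(records) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  stopifnot(length(seqs) >= 1L)
  res <- split_residues(paste(seqs, collapse = ""))
  res <- res[res %in% CANONICAL_AA]
  counts <- table(factor(res, levels = CANONICAL_AA))
  stats::setNames(as.numeric(counts) / sum(counts), CANONICAL_AA)
}
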