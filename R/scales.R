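# Residue-level constant tables shared across modules.

#' Amino-acid residue sets and scales
#'
#' Constant tables used throughout the package: the disorder-promoting and
#' order-promoting residue sets, the composition-derived disorder propensity
#' scale built from them, and the Kyte-Doolittle hydropathy scale with its
#' min-max normalised variant.
#'
#' Disorder-promoting residues (Ala, Arg, Gly, Gln, Ser, Pro, Glu, Lys) get
#' propensity 1, order-promoting residues (Trp, Cys, Phe, Ile, Tyr, Val,
#' Leu) get 0, every other letter (including the ambiguity codes X, B, Z
#' and U) gets a neutral 0.5 so that unusual residues do not bias windowed
#' averages.
#'
#' @format `disorder_promoting` and `order_promoting` are character vectors
#'   of one-letter residue codes. `disorder_propensity` is a named numeric
#'   vector over the 20 canonical residues plus X, B, Z, U.
#'   `kyte_doolittle` is the canonical hydropathy scale (Ile 4.5 ... Arg
#'   -4.5); `kd_normalized` rescales it to `[0, 1]` via (kd + 4.5) / 9.
#' @name residue_scales
#' @keywords internal
NULL

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AMBIGUOUS_AA <- c("X", "B", "Z", "U")

#' @rdname residue_scales
#' @export
disorder_promoting <- c("A", "R", "G", "Q", "S", "P", "E", "K")

#' @rdname residue_scales
#' @export
order_promoting <- c("W", "C", "F", "I", "Y", "V", "L")

#' @rdname residue_scales
#' @export
disorder_propensity <- local({
  letters20 <- c(CANONICAL_AA, AMBIGUOUS_AA)
  p <- rep(0.5, length(letters20))
  names(p) <- letters20
  p[disorder_promoting] <- 1
  p[order_promoting] <- 0
  p
})

#' @rdname residue_scales
#' @export
kyte_doolittle <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' @rdname residue_scales
#' @export
kd_normalized <- (kyte_doolittle + 4.5) / 9

# Thermal class canonical order and OGT ranges (degrees C).
THERMAL_CLASSES <- c("psychrophile", "mesophile", "thermophile", "hyperthermophile")

OGT_RANGES <- list(
  psychrophile     = c(5, 17),
  mesophile        = c(20, 42),
  thermophile      = c(45, 75),
  hyperthermophile = c(75, 105)
)

# GO biological-process vocabulary used by the synthetic annotator; the
# id/name pairs are the standard GO terms for these processes.
GO_TF <- c(go_id = "GO:0003700",
           go_name = "DNA-binding transcription factor activity",
           aspect = "F")

GO_BP_VOCAB <- data.frame(
  go_id = c("GO:0006412", "GO:0006810", "GO:0006355", "GO:0006935",
            "GO:0008152", "GO:0006414", "GO:0055114", "GO:0042254",
            "GO:0007165", "GO:0006508", "GO:0000160", "GO:0018106",
            "GO:0007155", "GO:0009405", "GO:0009306", "GO:0006350"),
  go_name = c("translation", "transport",
              "regulation of transcription, DNA-dependent", "chemotaxis",
              "metabolic process", "translational elongation",
              "oxidation reduction", "ribosome biogenesis",
              "signal transduction", "proteolysis",
              "two-component signal transduction system",
              "peptidyl-histidine phosphorylation", "cell adhesion",
              "pathogenesis", "protein secretion", "transcription"),
  aspect = "P",
  stringsAsFactors = FALSE
)

# Internal: split a sequence string into one-letter codes (upper-cased).
split_residues <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

# Internal: normalise a thermal class label (accepts common short forms).
normalize_class <- function(x) {
  short <- c(psychro = "psychrophile", meso = "mesophile",
             thermo = "thermophile", hyper = "hyperthermophile")
  x <- tolower(trimws(x))
  out <- ifelse(x %in% THERMAL_CLASSES, x, unname(short[x]))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown thermal class label(s): ", paste(bad, collapse = ", "))
  }
  out
}
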