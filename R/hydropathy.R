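#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values for the 20 standard amino acids
#' (one-letter codes). Positive values are hydrophobic. This is the default
#' scale used throughout the package; any named numeric vector covering the
#' 20 standard residues can be substituted for it.
#'
#' @format Named numeric vector of length 20.
#' @references Kyte J, Doolittle RF (1982) J Mol Biol 157:105-132.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# residues tolerated in input but carrying no hydropathy value:
# ambiguity codes, unknowns, stops and gap symbols
.nonstandard_residues <- c("X", "B", "Z", "J", "U", "O", "*", "-", ".")

#' Windowed hydropathy profile of a protein sequence
#'
#' Computes the per-residue hydropathy score S and its centered moving
#' average S_av over a window of `window_size` residues. Positions whose
#' full window does not fit within the sequence carry no S_av value
#' (`NA`); windows are never truncated at the termini. Non-standard
#' residues (X, B, Z, gaps, ...) carry no score, and any window containing
#' one is undefined.
#'
#' @param sequence A single amino-acid string (one-letter codes), or a
#'   character vector of single residues.
#' @param scale Named numeric hydropathy scale covering the 20 standard
#'   residues; default [kyte_doolittle].
#' @param window_size Odd integer window length, `>= 1` and at most the
#'   sequence length. Default 11, a conventional width for membrane-helix
#'   detection.
#' @return An object of class `"hydropathy_profile"`: a list with elements
#'   `residues` (character vector), `S`, `S_av` (numeric, `NA` where
#'   undefined), `window_size`, and (after [select_hydrophobic_sites()])
#'   `selected` and `threshold`.
#' @seealso [select_hydrophobic_sites()], [compute_aav()]
#' @examples
#' p <- hydropathy_profile(strrep("I", 25))
#' which(!is.na(p$S_av))  # positions 6..20
#' @export
hydropathy_profile <- function(sequence, scale = kyte_doolittle,
                               window_size = 11L) {
  residues <- if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    strsplit(toupper(sequence), "")[[1L]]
  } else {
    toupper(as.character(sequence))
  }
  n <- length(residues)
  if (n == 0L) stop("sequence is empty")
  if (length(window_size) != 1L || is.na(window_size) ||
      window_size < 1L || window_size %% 2L != 1L) {
    stop("window_size must be an odd integer >= 1, got ", window_size)
  }
  if (window_size > n) {
    stop("window_size (", window_size, ") exceeds sequence length (", n, ")")
  }
  known <- residues %in% names(scale)
  tolerated <- residues %in% .nonstandard_residues
  bad <- which(!known & !tolerated)
  if (length(bad)) {
    stop("unknown residue '", residues[bad[1L]], "' at position ", bad[1L],
         " (not in the hydropathy scale and not a recognised ambiguity/gap symbol)")
  }
  S <- rep(NA_real_, n)
  S[known] <- unname(scale[residues[known]])
  # centered moving average; stats::filter leaves NA where the window
  # overruns either end and propagates NA from non-standard residues,
  # which is exactly the edge rule this profile promises
  S_av <- as.numeric(stats::filter(S, rep(1 / window_size, window_size),
                                   sides = 2))
  structure(
    list(residues = residues, S = S, S_av = S_av,
         window_size = as.integer(window_size),
         selected = NULL, threshold = NA_real_),
    class = "hydropathy_profile"
  )
}

#' Select hydrophobic sites from a hydropathy profile
#'
#' Marks the positions whose moving-average hydropathy S_av is strictly
#' greater than `threshold`. Positions with undefined S_av are never
#' selected. The default threshold of 1.5 delimits the hydrophobic
#' (membrane-embedded helix) domains in which the amino-acid variables
#' are counted.
#'
#' @param profile A `"hydropathy_profile"` from [hydropathy_profile()].
#' @param threshold Numeric cut-off; selection uses strict `>`.
#' @return The profile with `selected` (logical vector) and `threshold`
#'   filled in. An empty selection is legal.
#' @export
select_hydrophobic_sites <- function(profile, threshold = 1.5) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  profile$selected <- !is.na(profile$S_av) & profile$S_av > threshold
  profile$threshold <- threshold
  profile
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat("Hydropathy profile:", length(x$residues), "residues, window",
      x$window_size, "\n")
  defined <- sum(!is.na(x$S_av))
  cat("  S_av defined at", defined, "positions\n")
  if (!is.null(x$selected)) {
    cat("  ", sum(x$selected), " sites selected (S_av > ", x$threshold,
        ")\n", sep = "")
  }
  invisible(x)
}
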