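#' Default subunit set for amino-acid variable extraction
#'
#' The six large mtDNA-encoded subunits of complexes I, III and IV used by
#' default when pooling hydrophobic domains: ND2, ND4, ND5, CO1, CO3 and
#' CYTB. Together they form the bulk of the proton-pump machinery of the
#' respiratory chain.
#'
#' @export
default_subunits <- c("ND2", "ND4", "ND5", "CO1", "CO3", "CYTB")

#' All thirteen mtDNA-encoded membrane-protein subunits
#' @export
all_subunits <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                  "CO1", "CO2", "CO3", "CYTB", "ATP6", "ATP8")

#' Amino-acid variables of one species' membrane proteins
#'
#' Pools the hydrophobic domains of the requested subunits (sites whose
#' windowed hydropathy `S_av` strictly exceeds `threshold`) and computes
#' the four amino-acid variables:
#' \describe{
#'   \item{SC, TC, CC}{Ser, Thr and Cys contents, as percentages of the
#'     pooled selected sites.}
#'   \item{HYD}{mean `S_av`, either over the selected sites (default) or
#'     over all positions with a defined `S_av` (`hyd_mean = "all"`).}
#' }
#' Pooling counts sites across subunits (total counts over the hydrophobic
#' domains), not per-subunit averages, so subunit order is irrelevant.
#'
#' @param sequences Named character vector of amino-acid sequences for one
#'   species; names are subunit labels (e.g. `"ND2"`).
#' @param subunits Subunit labels to pool; default [default_subunits].
#' @param scale,window_size,threshold Passed to [hydropathy_profile()] and
#'   [select_hydrophobic_sites()].
#' @param hyd_mean `"selected"` (default) averages `S_av` over selected
#'   sites; `"all"` averages over every position with a defined `S_av`.
#' @return An object of class `"aav"`: list with `SC`, `TC`, `CC`, `HYD`,
#'   `n_selected`, `n_total` and the extraction settings.
#' @examples
#' aa <- compute_aav(c(ND2 = strrep("I", 40)), subunits = "ND2")
#' aa$HYD  # 4.5, the Ile hydropathy
#' @export
compute_aav <- function(sequences, subunits = default_subunits,
                        scale = kyte_doolittle, window_size = 11L,
                        threshold = 1.5,
                        hyd_mean = c("selected", "all")) {
  hyd_mean <- match.arg(hyd_mean)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("'sequences' must be a named character vector (names = subunits)")
  }
  missing_sub <- setdiff(subunits, names(sequences))
  if (length(missing_sub)) {
    stop("missing subunit(s): ", paste(missing_sub, collapse = ", "))
  }
  sel_res <- character(0)
  sel_sav <- numeric(0)
  all_sav <- numeric(0)
  n_total <- 0L
  for (su in subunits) {
    prof <- hydropathy_profile(sequences[[su]], scale = scale,
                               window_size = window_size)
    prof <- select_hydrophobic_sites(prof, threshold = threshold)
    sel_res <- c(sel_res, prof$residues[prof$selected])
    sel_sav <- c(sel_sav, prof$S_av[prof$selected])
    all_sav <- c(all_sav, prof$S_av[!is.na(prof$S_av)])
    n_total <- n_total + length(prof$residues)
  }
  n_sel <- length(sel_res)
  if (n_sel == 0L) {
    stop("no sites with S_av > ", threshold, " in the pooled subunits; ",
         "consider lowering the threshold or the window size")
  }
  structure(
    list(
      SC = 100 * sum(sel_res == "S") / n_sel,
      TC = 100 * sum(sel_res == "T") / n_sel,
      CC = 100 * sum(sel_res == "C") / n_sel,
      HYD = if (hyd_mean == "selected") mean(sel_sav) else mean(all_sav),
      n_selected = n_sel,
      n_total = n_total,
      subunits = subunits,
      window_size = as.integer(window_size),
      threshold = threshold,
      hyd_mean = hyd_mean
    ),
    class = "aav"
  )
}

#' @export
print.aav <- function(x, ...) {
  cat(sprintf(
    "AAVs over %d/%d selected sites (%s): SC=%.3f%% TC=%.3f%% CC=%.3f%% HYD=%.3f\n",
    x$n_selected, x$n_total, paste(x$subunits, collapse = "+"),
    x$SC, x$TC, x$CC, x$HYD))
  invisible(x)
}

#' Read mtDNA-encoded protein sequences from FASTA
#'
#' Headers follow the `species_id|subunit` convention by default; a custom
#' regular expression with two capture groups (species, subunit) can be
#' supplied. Multi-species multi-subunit FASTA files and per-subunit files
#' (read one at a time and row-bound) are both supported.
#'
#' @param path FASTA file path.
#' @param header_regex Regular expression with exactly two capture groups,
#'   applied to each header; group 1 = species id, group 2 = subunit.
#' @return `data.frame` with columns `species`, `subunit`, `sequence`.
#' @export
read_protein_fasta <- function(path,
                               header_regex = "^\\s*([^|]+?)\\s*\\|\\s*(\\S+)") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  m <- regmatches(headers, regexec(header_regex, headers))
  bad <- which(vapply(m, length, 1L) < 3L)
  if (length(bad)) {
    stop("FASTA header does not match the species|subunit convention: '",
         headers[bad[1L]], "'")
  }
  out <- data.frame(
    species = vapply(m, `[`, "", 2L),
    subunit = toupper(vapply(m, `[`, "", 3L)),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE, row.names = NULL
  )
  dup <- duplicated(out[c("species", "subunit")])
  if (any(dup)) {
    stop("duplicated (species, subunit) pairs in FASTA: ",
         paste(unique(paste(out$species[dup], out$subunit[dup], sep = "|")),
               collapse = ", "))
  }
  out
}

#' Per-species amino-acid variable table
#'
#' Runs [compute_aav()] for every species in a sequence table (as returned
#' by [read_protein_fasta()]).
#'
#' @param sequences `data.frame` with columns `species`, `subunit`,
#'   `sequence`.
#' @inheritParams compute_aav
#' @return `data.frame` with columns `species`, `SC`, `TC`, `CC`, `HYD`,
#'   `n_selected`, `n_total`.
#' @export
aav_table <- function(sequences, subunits = default_subunits,
                      scale = kyte_doolittle, window_size = 11L,
                      threshold = 1.5, hyd_mean = c("selected", "all")) {
  hyd_mean <- match.arg(hyd_mean)
  stopifnot(all(c("species", "subunit", "sequence") %in% names(sequences)))
  rows <- lapply(split(sequences, sequences$species), function(d) {
    sq <- stats::setNames(d$sequence, d$subunit)
    v <- compute_aav(sq, subunits = subunits, scale = scale,
                     window_size = window_size, threshold = threshold,
                     hyd_mean = hyd_mean)
    data.frame(species = d$species[1L], SC = v$SC, TC = v$TC, CC = v$CC,
               HYD = v$HYD, n_selected = v$n_selected, n_total = v$n_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write an AAV table as CSV
#'
#' @param path CSV path. Columns: `species, SC, TC, CC, HYD` (extra columns
#'   are kept).
#' @return `read_aav_table`: the validated `data.frame`.
#' @export
read_aav_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "SC", "TC", "CC", "HYD")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("AAV table misses column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$species)) stop("duplicated species in AAV table")
  x
}

#' @rdname read_aav_table
#' @param aav AAV `data.frame` to write.
#' @export
write_aav_table <- function(aav, path) {
  utils::write.csv(aav, path, row.names = FALSE)
  invisible(path)
}
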