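# Approximate real lengths of the six default mtDNA-encoded subunits in
# mammals; used as defaults by the constructive sequence generator.
.default_subunit_lengths <- c(ND2 = 347L, ND4 = 459L, ND5 = 603L,
                              CO1 = 513L, CO3 = 261L, CYTB = 380L)

# distribute `total` counts over bins proportional to `sizes` (largest
# remainder), so per-bin integers sum exactly to `total`
.largest_remainder <- function(total, sizes) {
  quota <- total * sizes / sum(sizes)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# build one subunit sequence: hydrophobic Ile/Ala background with
# Ser/Thr/Cys placed at evenly spaced full-window positions
.build_subunit <- function(L, counts, hyd_target, scale, window_size,
                           threshold) {
  h <- (window_size - 1L) %/% 2L
  n_sel <- L - window_size + 1L
  n_spec <- sum(counts)
  if (n_spec > n_sel) {
    stop("infeasible target: ", n_spec, " marked residues exceed the ",
         n_sel, " selectable sites of a length-", L, " subunit")
  }
  # interleave the three residue types evenly along the selected range
  keys <- c(if (counts[1L]) (seq_len(counts[1L]) - 0.5) / counts[1L],
            if (counts[2L]) (seq_len(counts[2L]) - 0.5) / counts[2L],
            if (counts[3L]) (seq_len(counts[3L]) - 0.5) / counts[3L])
  letters_spec <- rep(c("S", "T", "C"), counts)[order(keys)]
  pos_spec <- if (n_spec > 0) {
    unique(h + ceiling((seq_len(n_spec) - 0.5) * n_sel / n_spec))
  } else integer(0)
  if (length(pos_spec) != n_spec) {
    stop("infeasible target: marked residues too dense to place at ",
         "distinct sites (", n_spec, " on ", n_sel, " selectable sites)")
  }
  bg_pos <- setdiff(seq_len(L), pos_spec)
  n_bg <- length(bg_pos)
  make_seq <- function(n_ala) {
    res <- rep("I", L)
    if (n_spec > 0) res[pos_spec] <- letters_spec
    if (n_ala > 0) {
      j <- seq_len(n_bg)
      is_ala <- floor(j * n_ala / n_bg) > floor((j - 1L) * n_ala / n_bg)
      res[bg_pos[is_ala]] <- "A"
    }
    paste(res, collapse = "")
  }
  achieved_hyd <- function(n_ala) {
    prof <- select_hydrophobic_sites(
      hydropathy_profile(make_seq(n_ala), scale = scale,
                         window_size = window_size), threshold)
    if (sum(prof$selected) != n_sel) return(NA_real_)
    mean(prof$S_av[prof$selected])
  }
  # achieved HYD decreases monotonically in the Ala count (each Ile->Ala
  # swap lowers every window mean it touches), so a binary search over the
  # integer Ala count finds the closest achievable value; NA (selection
  # broken by too low a background) counts as "below target"
  lo <- 0L
  v_lo <- achieved_hyd(lo)
  if (is.na(v_lo)) {
    stop("infeasible target: the marked residues alone push windows ",
         "below the selection threshold ", threshold)
  }
  hi <- n_bg
  v_hi <- achieved_hyd(hi)
  best <- if (!is.na(v_hi) && v_hi >= hyd_target) {
    hi
  } else if (v_lo <= hyd_target) {
    lo
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      v <- achieved_hyd(mid)
      if (!is.na(v) && v > hyd_target) { lo <- mid; v_lo <- v }
      else { hi <- mid; v_hi <- v }
    }
    if (!is.na(v_hi) &&
        abs(v_hi - hyd_target) < abs(v_lo - hyd_target)) hi else lo
  }
  make_seq(best)
}

#' Construct protein sequences realizing prescribed amino-acid variables
#'
#' Builds, for each target row, subunit sequences whose hydrophobic
#' domains reproduce the prescribed SC/TC/CC exactly (at the resolution
#' of integer residue counts over the pooled selected sites) and HYD
#' approximately: a strongly hydrophobic Ile/Ala background keeps every
#' full-window site selected, Ser/Thr/Cys are interspersed at evenly
#' spaced selected positions (their windows stay above the threshold),
#' and the Ile:Ala mix is tuned to the HYD target. The construction is
#' deterministic.
#'
#' @param aav_targets `data.frame` with columns `species`, `SC`, `TC`,
#'   `CC` (percent) and `HYD` (hydropathy units, achievable range about
#'   1.7-4.5 under the default scale).
#' @param subunit_lengths Named integer vector of subunit lengths;
#'   defaults to realistic lengths for the six default subunits.
#' @param scale,window_size,threshold Extraction settings the sequences
#'   are built against (must match those used by [compute_aav()]).
#' @return `data.frame(species, subunit, sequence)`, the same layout
#'   [read_protein_fasta()] returns. Construction is verified by
#'   re-extraction; an unreachable target raises an error naming the
#'   violated bound.
#' @export
generate_sequences <- function(aav_targets,
                               subunit_lengths = .default_subunit_lengths,
                               scale = kyte_doolittle, window_size = 11L,
                               threshold = 1.5) {
  need <- c("species", "SC", "TC", "CC", "HYD")
  miss <- setdiff(need, names(aav_targets))
  if (length(miss)) stop("aav_targets misses column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(names(subunit_lengths))) stop("subunit_lengths must be named")
  if (any(subunit_lengths < window_size)) {
    stop("every subunit length must be at least the window size")
  }
  n_sel_i <- subunit_lengths - window_size + 1L
  n_sel <- sum(n_sel_i)
  rows <- list()
  for (r in seq_len(nrow(aav_targets))) {
    tg <- aav_targets[r, ]
    if (any(c(tg$SC, tg$TC, tg$CC) < 0)) {
      stop("negative content target for ", tg$species)
    }
    if (tg$SC + tg$TC + tg$CC > 100) {
      stop("infeasible target for ", tg$species,
           ": SC + TC + CC = ", tg$SC + tg$TC + tg$CC, " exceeds 100")
    }
    if (tg$HYD <= threshold) {
      stop("infeasible target for ", tg$species, ": HYD = ", tg$HYD,
           " must exceed the selection threshold ", threshold)
    }
    counts <- round(c(S = tg$SC, T = tg$TC, C = tg$CC) * n_sel / 100)
    per_sub <- vapply(c("S", "T", "C"), function(ltr) {
      .largest_remainder(counts[ltr], n_sel_i)
    }, integer(length(subunit_lengths)))
    if (length(subunit_lengths) == 1L) per_sub <- matrix(per_sub, nrow = 1L)
    seqs <- character(length(subunit_lengths))
    for (s in seq_along(subunit_lengths)) {
      seqs[s] <- .build_subunit(subunit_lengths[s], per_sub[s, ],
                                tg$HYD, scale, window_size, threshold)
    }
    # verify the construction by re-extraction
    got <- compute_aav(stats::setNames(seqs, names(subunit_lengths)),
                       subunits = names(subunit_lengths), scale = scale,
                       window_size = window_size, threshold = threshold)
    got_counts <- round(c(got$SC, got$TC, got$CC) * got$n_selected / 100)
    if (got$n_selected != n_sel || any(got_counts != unname(counts))) {
      stop("infeasible target for ", tg$species, ": the prescribed HYD ",
           "and contents cannot keep all marked sites selected ",
           "(achieved ", got$n_selected, "/", n_sel, " selected sites)")
    }
    rows[[r]] <- data.frame(species = tg$species,
                            subunit = names(subunit_lengths),
                            sequence = seqs, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a species/subunit sequence table as FASTA
#'
#' Headers follow the `species|subunit` convention that
#' [read_protein_fasta()] reads back.
#'
#' @param sequences `data.frame(species, subunit, sequence)`.
#' @param path Output FASTA path.
#' @export
write_protein_fasta <- function(sequences, path) {
  stopifnot(all(c("species", "subunit", "sequence") %in% names(sequences)))
  ss <- Biostrings::AAStringSet(sequences$sequence)
  names(ss) <- paste(sequences$species, sequences$subunit, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
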