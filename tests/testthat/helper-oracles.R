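# Brute-force oracles, written independently of the implementation:
# plain loops, no stats::filter, no vectorized shortcuts.

# naive windowed mean of per-residue hydropathy; NA where the window
# overruns the sequence or touches a residue without a scale value
oracle_windowed_mean <- function(seq_chars, scale, window_size) {
  n <- length(seq_chars)
  h <- (window_size - 1) / 2
  s_av <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - h < 1 || i + h > n) next
    vals <- numeric(window_size)
    ok <- TRUE
    for (k in seq_len(window_size)) {
      res <- seq_chars[i - h - 1 + k]
      if (!res %in% names(scale)) { ok <- FALSE; break }
      vals[k] <- scale[[res]]
    }
    if (ok) s_av[i] <- sum(vals) / window_size
  }
  s_av
}

# naive AAV extraction: windowed mean + strict threshold + counting,
# pooled over subunits
oracle_aav <- function(sequences, subunits, scale, window_size, threshold) {
  sel_res <- character(0)
  sel_sav <- numeric(0)
  for (su in subunits) {
    ch <- strsplit(sequences[[su]], "")[[1]]
    s_av <- oracle_windowed_mean(ch, scale, window_size)
    for (i in seq_along(ch)) {
      if (!is.na(s_av[i]) && s_av[i] > threshold) {
        sel_res <- c(sel_res, ch[i])
        sel_sav <- c(sel_sav, s_av[i])
      }
    }
  }
  list(SC = 100 * sum(sel_res == "S") / length(sel_res),
       TC = 100 * sum(sel_res == "T") / length(sel_res),
       CC = 100 * sum(sel_res == "C") / length(sel_res),
       HYD = mean(sel_sav),
       n_selected = length(sel_res))
}

# random amino-acid sequence over the 20 standard residues
random_aa <- function(n) {
  paste(sample(names(kyte_doolittle), n, replace = TRUE), collapse = "")
}

# noiseless trait table following BMR = a * M^b exactly
make_clean_traits <- function(n = 20, a = 0.02, b = 0.75,
                              mass = 10^seq(1, 8, length.out = n)) {
  data.frame(species = sprintf("s%02d", seq_len(n)), group = "all",
             mass_g = mass, bmr_w = a * mass^b, mls_yr = 10,
             stringsAsFactors = FALSE)
}
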