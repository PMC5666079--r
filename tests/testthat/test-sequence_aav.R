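test_that("windowed hydropathy profile matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(15:60, 1)
    w <- sample(c(1, 3, 5, 7, 11), 1)
    if (w > n) w <- 1
    sq <- random_aa(n)
    prof <- hydropathy_profile(sq, window_size = w)
    expected <- oracle_windowed_mean(strsplit(sq, "")[[1]],
                                     kyte_doolittle, w)
    expect_equal(prof$S_av, expected, tolerance = 1e-12)
  }
})

test_that("profile honours the edge rule and degenerate windows", {
  p <- hydropathy_profile(strrep("I", 25), window_size = 11)
  expect_equal(which(!is.na(p$S_av)), 6:20)
  expect_true(all(abs(p$S_av[6:20] - 4.5) < 1e-12))
  # window of 1 is the identity
  sq <- "MKTAYIAWLV"
  p1 <- hydropathy_profile(sq, window_size = 1)
  expect_equal(p1$S_av, p1$S)
  # non-standard residues poison their windows
  px <- hydropathy_profile("IIIIIXIIIII", window_size = 3)
  expect_true(all(is.na(px$S_av[5:7])))
  expect_false(anyNA(px$S_av[c(2:4, 8:10)]))
  expect_error(hydropathy_profile("III?III", window_size = 3),
               "unknown residue '\\?' at position 4")
  expect_error(hydropathy_profile("IIII", window_size = 5), "exceeds")
  expect_error(hydropathy_profile("IIII", window_size = 2), "odd")
})

test_that("site selection uses strict inequality and reports empties", {
  p <- select_hydrophobic_sites(hydropathy_profile(strrep("G", 20),
                                                   window_size = 5))
  expect_equal(sum(p$selected), 0)
  p <- select_hydrophobic_sites(hydropathy_profile(strrep("I", 20),
                                                   window_size = 5))
  expect_equal(which(p$selected), 3:18)
  # threshold exactly at S_av: not selected
  p_eq <- select_hydrophobic_sites(hydropathy_profile(strrep("I", 20),
                                                      window_size = 5),
                                   threshold = 4.5)
  expect_equal(sum(p_eq$selected), 0)
})

test_that("AAV extraction agrees exactly with the enumeration oracle", {
  set.seed(99)
  for (rep in 1:10) {
    sqs <- c(A = random_aa(80), B = random_aa(120), C = random_aa(60))
    w <- sample(c(3, 5, 7), 1)
    th <- runif(1, -1, 1.5)
    got <- tryCatch(
      compute_aav(sqs, subunits = c("A", "B", "C"), window_size = w,
                  threshold = th),
      error = function(e) NULL)
    want <- oracle_aav(sqs, c("A", "B", "C"), kyte_doolittle, w, th)
    if (is.null(got)) {
      expect_equal(want$n_selected, 0)
    } else {
      expect_equal(got$SC, want$SC, tolerance = 1e-12)
      expect_equal(got$TC, want$TC, tolerance = 1e-12)
      expect_equal(got$CC, want$CC, tolerance = 1e-12)
      expect_equal(got$HYD, want$HYD, tolerance = 1e-12)
      expect_equal(got$n_selected, want$n_selected)
    }
  }
})

test_that("isolated Ser inside a hydrophobic run stays selected", {
  # 10% of selected residues are Ser by construction; their windows stay
  # hydrophobic so they are counted
  core <- strsplit(strrep("I", 110), "")[[1]]
  core[seq(10, 100, by = 10)] <- "S"
  sq <- c(X = paste(core, collapse = ""))
  v <- compute_aav(sq, subunits = "X", window_size = 11)
  expect_equal(v$n_selected, 100)
  expect_equal(v$SC, 10)
  expect_equal(v$TC, 0)
  expect_equal(v$CC, 0)
})

test_that("all-Ile subunit gives zero contents and the Ile hydropathy", {
  v <- compute_aav(c(ND2 = strrep("I", 50)), subunits = "ND2")
  expect_equal(c(v$SC, v$TC, v$CC), c(0, 0, 0))
  expect_equal(v$HYD, 4.5)
})

test_that("pooling is order-free and missing subunits are named", {
  set.seed(7)
  sqs <- c(ND2 = random_aa(150), ND4 = random_aa(200), CO1 = random_aa(180))
  v1 <- compute_aav(sqs, subunits = c("ND2", "ND4", "CO1"))
  v2 <- compute_aav(sqs, subunits = c("CO1", "ND2", "ND4"))
  expect_equal(v1[c("SC", "TC", "CC", "HYD", "n_selected", "n_total")],
               v2[c("SC", "TC", "CC", "HYD", "n_selected", "n_total")])
  expect_error(compute_aav(sqs), "ND5")
  expect_error(compute_aav(sqs[1:2], subunits = c("ND2", "ND4", "CO1")),
               "CO1")
})

test_that("shrinking the threshold monotonically grows the selection", {
  set.seed(21)
  sq <- c(A = random_aa(300))
  prev <- -1
  for (th in c(3, 2, 1.5, 0.5, -1, -5)) {
    v <- tryCatch(compute_aav(sq, subunits = "A", threshold = th),
                  error = function(e) list(n_selected = 0))
    expect_gte(v$n_selected, prev)
    prev <- v$n_selected
  }
})

test_that("HYD conventions: selected-site mean exceeds the threshold", {
  set.seed(3)
  sq <- c(A = random_aa(400))
  v_sel <- compute_aav(sq, subunits = "A")
  v_all <- compute_aav(sq, subunits = "A", hyd_mean = "all")
  expect_gt(v_sel$HYD, 1.5)
  expect_lt(v_all$HYD, v_sel$HYD)  # mean over all defined sites is lower
})

test_that("FASTA round trip preserves the per-species AAV table", {
  tg <- data.frame(species = c("sp_a", "sp_b"),
                   SC = c(6, 9), TC = c(8, 7), CC = c(1, 2),
                   HYD = c(2.3, 2.9))
  seqs <- generate_sequences(tg, subunit_lengths = c(ND2 = 200, ND4 = 300))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(seqs, path)
  back <- read_protein_fasta(path)
  expect_equal(aav_table(back, subunits = c("ND2", "ND4")),
               aav_table(seqs, subunits = c("ND2", "ND4")))
})
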