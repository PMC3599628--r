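# Windowed feature encoding: one-hot tracks, Atchley scaling, PSSM parsing,
# window assembly and whole-protein encoding.

test_that("secondary structure and solvent accessibility one-hot codes match the scheme", {
  expect_equal(unname(encode_ss("C")[1, ]), c(0, 0, 1))
  expect_equal(unname(encode_ss("H")[1, ]), c(1, 0, 0))
  expect_equal(unname(encode_ss("E")[1, ]), c(0, 1, 0))
  expect_equal(unname(encode_sa("b")[1, ]), c(0, 1))
  expect_equal(unname(encode_sa("e")[1, ]), c(1, 0))
  expect_equal(unname(encode_sa("be")), rbind(c(0, 1), c(1, 0)))
  expect_error(encode_ss("HXC"), "position 2")
  expect_error(encode_sa("bq"), "position 2")
})

test_that("Atchley factors are min-max scaled over the 20-residue table", {
  # extreme residues per factor, from an independent reading of the
  # published five-factor table
  expect_equal(atchley_factors("C")[1], 0)
  expect_equal(atchley_factors("K")[1], 1)
  expect_equal(atchley_factors("M")[2], 0)
  expect_equal(atchley_factors("P")[2], 1)
  expect_equal(atchley_factors("S")[3], 0)
  expect_equal(atchley_factors("Y")[3], 1)
  expect_equal(atchley_factors("W")[4], 0)
  expect_equal(atchley_factors("A")[4], 1)
  expect_equal(atchley_factors("D")[5], 0)
  expect_equal(atchley_factors("R")[5], 1)
  # alanine, recomputed by hand from the published raw values
  a_raw <- c(-0.591, -1.302, -0.733, 1.570, -0.146)
  mins <- c(-1.343, -1.524, -4.760, -2.128, -3.242)
  maxs <- c(1.831, 2.081, 3.097, 1.570, 2.897)
  expect_equal(atchley_factors("A"), (a_raw - mins) / (maxs - mins),
               tolerance = 1e-12)
  # unknowns sit at the neutral midpoint
  expect_equal(atchley_factors("X"), rep(0.5, 5))
  for (aa in rownames(idrboost:::ATCHLEY_RAW)) {
    v <- atchley_factors(aa)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("parse_pssm reads a hand-written matrix and scales it", {
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste("           ", paste(rep(LETTERS[1:20], 2), collapse = "  ")),
    paste("    1 M ", paste(rep("0", 20), collapse = " "),
          " 37 63", paste(rep("0", 18), collapse = " "), " 1.20  0.00"),
    paste("    2 K ", paste(rep("1", 20), collapse = " "),
          paste(rep("5", 20), collapse = " "), " 0.60  0.00"),
    paste("    3 V ", paste(rep("-2", 20), collapse = " "),
          paste(rep("0", 20), collapse = " "), " 0.00  0.00"),
    paste("    4 L ", paste(rep("0", 20), collapse = " "),
          "100", paste(rep("0", 19), collapse = " "), " 4.00  0.00"),
    paste("    5 A ", paste(rep("0", 20), collapse = " "),
          paste(rep("0", 19), collapse = " "), " 100", " 9.00  0.00"))
  p <- parse_pssm(text = lines, sequence = "MKVLA")
  expect_equal(nrow(p$likelihood), 5)
  expect_equal(unname(p$likelihood[1, 1:2]), c(0.37, 0.63))
  expect_equal(unname(p$likelihood[2, ]), rep(0.05, 20))
  expect_equal(unname(p$likelihood[3, ]), rep(0, 20))  # all-zero row
  expect_equal(unname(p$likelihood[4, 1]), 1.0)
  expect_equal(p$info_raw, c(1.20, 0.60, 0, 4.00, 9.00))
  # info scaled by clamped division by 6
  expect_equal(p$info, c(0.20, 0.10, 0, 4 / 6, 1.0))
  # mismatch and malformed input raise named errors
  expect_error(parse_pssm(text = lines, sequence = "MKVLW"),
               "position 5")
  expect_error(parse_pssm(text = lines[1:3]), "no matrix rows")
  bad <- lines; bad[5] <- "    2 K  1 2 3"
  expect_error(parse_pssm(text = bad), "line 5")
})

test_that("global features count exposure and structure fractions", {
  tk <- make_track("MKVLAMKVLA", ss = "HHHEECCCCC", sa = "eeeebbbbbb")
  expect_equal(unname(global_features(tk$track)),
               c(0.4, 0.3, 0.2))
  all_coil <- make_track("MKVLA", ss = "CCCCC", sa = "bbbbb")
  expect_equal(unname(global_features(all_coil$track)), c(0, 0, 0))
  all_helix <- make_track("MKVLA", ss = "HHHHH", sa = "eeeee")
  expect_equal(unname(global_features(all_helix$track)), c(1, 1, 0))
})

test_that("window dimensionality follows 32 * l_in + 4", {
  expect_equal(window_input_dim(20), 644)
  expect_equal(window_input_dim(30), 964)
  expect_equal(window_input_dim(25), 804)
  tk <- make_track(paste(rep("A", 40), collapse = ""),
                   ss = paste(rep("C", 40), collapse = ""),
                   sa = paste(rep("b", 40), collapse = ""))
  for (combo in list(c(20, 3), c(25, 5), c(30, 7))) {
    w <- build_window(tk$track, 20, combo[1], combo[2])
    expect_length(w$x, 32 * combo[1] + 4)
    expect_true(all(w$x >= 0 & w$x <= 1))
  }
})

test_that("build_window matches a direct slot-by-slot construction", {
  set.seed(4)
  tk <- make_track("MKVLAWRNDC", ss = "CHHEECCHEC", sa = "ebbeebbeeb",
                   info = round(runif(10), 2),
                   lik = matrix(round(runif(200), 2), 10, 20))
  for (center in c(1, 2, 5, 9, 10)) {
    w <- build_window(tk$track, center, 20, 3)
    expect_equal(w$x, build_window_direct(tk$track, center, 20, 3))
  }
})

test_that("out-of-sequence slots are all zero with a zero bounds flag", {
  tk <- make_track("MKVLA", ss = "CCCCC", sa = "bbbbb")
  w <- build_window(tk$track, 1, 20, 3)
  # at center 1 the target window starts at residue 0: nine context slots
  # plus that masked target slot precede the sequence
  for (k in 1:10) {
    block <- w$x[((k - 1) * 32 + 1):(k * 32)]
    expect_equal(block, rep(0, 32))
  }
  in_block <- w$x[(10 * 32 + 1):(11 * 32)]
  expect_equal(in_block[32], 1)        # bounds flag set
  expect_equal(sum(in_block[1:2]), 1)  # sa one-hot
  expect_equal(sum(in_block[3:5]), 1)  # ss one-hot
})

test_that("window encoding is position-covariant under sequence reversal", {
  set.seed(9)
  tk <- make_track("MKVLAWRNDCMKVLAW", ss = "CHHEECCHECCHHEEC",
                   sa = "ebbeebbeebebbeeb",
                   info = round(runif(16), 2),
                   lik = matrix(round(runif(320), 2), 16, 20))
  n <- 16
  rev_rec <- protein_record("rev",
                            paste(rev(strsplit(tk$record$sequence, "")[[1]]),
                                  collapse = ""))
  rev_pssm <- list(info = rev(tk$track$pssm_info),
                   info_raw = rev(tk$track$pssm_info) * 6,
                   likelihood = tk$track$pssm_likelihood[n:1, ],
                   residues = rev(strsplit(tk$record$sequence, "")[[1]]))
  rev_ss <- paste(rev(c("H", "E", "C")[max.col(tk$track$ss)]), collapse = "")
  rev_sa <- paste(rev(c("e", "b")[max.col(tk$track$sa)]), collapse = "")
  rev_track <- residue_track(rev_rec, rev_pssm, rev_ss, rev_sa)
  for (center in c(3, 8, 14)) {
    fwd <- build_window(tk$track, center, 20, 3)$x
    # mirrored centering convention (right-heavy) on the reversed protein
    mir <- build_window_direct(rev_track, n + 1 - center, 20, 3,
                               left_heavy = FALSE)
    # slot blocks come out in reverse order; global block has the same
    # fractions and mirrored relative position
    fwd_slots <- matrix(fwd[1:(32 * 20)], nrow = 32)
    mir_slots <- matrix(mir[1:(32 * 20)], nrow = 32)
    expect_equal(fwd_slots, mir_slots[, 20:1])
    expect_equal(fwd[32 * 20 + 4], center / n)
    expect_equal(mir[32 * 20 + 4], (n + 1 - center) / n)
  }
})

test_that("encode_protein yields one example per residue with valid targets", {
  seq50 <- paste(rep(c("M", "K", "V", "L", "A"), 10), collapse = "")
  labels <- paste(c(rep("D", 4), rep("O", 20), "X", rep("O", 20),
                    rep("D", 5)), collapse = "")
  tk <- make_track(seq50, ss = paste(rep("C", 50), collapse = ""),
                   sa = paste(rep("b", 50), collapse = ""), labels = labels)
  ex <- encode_protein(tk$record, tk$track, 20, 3)
  expect_equal(nrow(ex$X), 50)
  expect_equal(ncol(ex$X), 644)
  expect_true(all(ex$X >= 0 & ex$X <= 1))
  # X-labelled residue 25: target 0 and masked wherever it appears
  expect_equal(ex$Y[25, 2], 0)
  expect_equal(ex$M[25, 2], 0)
  expect_equal(ex$M[24, 3], 0)  # residue 25 in the right slot of window 24
  expect_equal(ex$M[26, 1], 0)
  # terminal windows mask the out-of-sequence positions
  expect_equal(ex$M[1, 1], 0)
  expect_equal(ex$M[50, 3], 0)
  # disorder labels land in the target
  expect_equal(ex$Y[2, ], c(1, 1, 1))
  # one-hot groups sum to 1 on in-bounds slots, 0 outside
  w <- build_window(tk$track, 25, 25, 5)
  for (k in 1:25) {
    block <- w$x[((k - 1) * 32 + 1):(k * 32)]
    expect_equal(sum(block[1:2]), block[32])
    expect_equal(sum(block[3:5]), block[32])
  }
  expect_error(build_window(tk$track, 0, 20, 3), "out of range")
  expect_error(build_window(tk$track, 51, 20, 3), "out of range")
})

test_that("pooling stacks examples and keeps provenance", {
  tka <- make_track("MKVLAMKVLA", ss = "CCCCCCCCCC", sa = "bbbbbbbbbb",
                    labels = "DDDOOOOOOO", id = "a")
  tkb <- make_track("WRNDC", ss = "HHHHH", sa = "eeeee",
                    labels = "OODDD", id = "b")
  pool <- pool_examples(list(
    encode_protein(tka$record, tka$track, 20, 3),
    encode_protein(tkb$record, tkb$track, 20, 3)))
  expect_equal(nrow(pool$X), 15)
  expect_equal(pool$protein, rep(c("a", "b"), c(10, 5)))
  expect_equal(pool$centers, c(1:10, 1:5))
})
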