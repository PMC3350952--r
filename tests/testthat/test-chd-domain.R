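test_that("chromodomain group classification covers the full truth table", {
  # group I needs Y24 and W45; group II keeps W45 without Y24; no W45 means
  # unclassified, whatever Y48 says
  for (y24 in c(TRUE, FALSE)) for (w45 in c(TRUE, FALSE)) for (y48 in c(TRUE, FALSE)) {
    want <- if (!w45) "unclassified" else if (y24) "CHD_I" else "CHD_II"
    expect_identical(classify_chd(y24, w45, y48), want)
  }
})

test_that("anchored calls reproduce the Diluvium-style group II case", {
  # peptide with Y at alignment position 1, W at 28, Y at 31
  p1 <- chromosel:::chd_peptide("CHD_I")
  call1 <- chd_call(p1)
  expect_true(call1$y24 && call1$w45 && call1$y48)
  expect_identical(call1$group, "CHD_I")

  # lacking the position-1 tyrosine but keeping W45 and Y48
  p2 <- chromosel:::chd_peptide("CHD_II")
  call2 <- chd_call(p2)
  expect_false(call2$y24)
  expect_true(call2$w45 && call2$y48)
  expect_identical(call2$group, "CHD_II")
})

test_that("single-residue corruptions flip groups exactly as the rules say", {
  p1 <- chromosel:::chd_peptide("CHD_I")
  anchor <- chd_call(p1)$anchor
  swap <- function(p, i, ch) {
    substring(p, i, i) <- ch
    p
  }
  # Y -> S at position 1: group I -> group II
  expect_identical(chd_call(swap(p1, anchor[["y24"]], "S"))$group, "CHD_II")
  # W -> S at position 28: -> unclassified
  expect_identical(chd_call(swap(p1, anchor[["w45"]], "S"))$group, "unclassified")
})

test_that("motif scores follow the prominent/minor weighting", {
  box <- chd_motif_patterns()$chromo_box
  full <- motif_scan("YLIKWKG", box)
  expect_equal(full$score, 6)            # 5 prominent + 2 minor
  expect_equal(full$max_score, 6)
  minor <- motif_scan("FLIKYKG", box)    # f and y are minor variants
  expect_equal(minor$score, 5)
  expect_gte(minor$score, box$min_score)
  expect_null(motif_scan("AAAAAAA", box))

  # monotone non-increasing under single-position corruption
  set.seed(2)
  for (i in 1:7) {
    corrupt <- paste0(substring("YLIKWKG", 1, i - 1), "A",
                      substring("YLIKWKG", i + 1, 7))
    sc <- motif_scan(corrupt, box, min_score = 0)$score
    expect_lte(sc, full$score)
  }
})

test_that("clade motifs are detected independently", {
  expect_true(all(c("tekay_EExTWExE", "twe_core") %in%
                    detect_clade_motifs("DDDEELTWEAEDDD")))
  expect_true("tekay_KxLRxK" %in% detect_clade_motifs("DDDKALRQKDDD"))
  hits <- detect_clade_motifs("DDDYLVKWKGDDD")
  expect_true(all(c("chromo_box", "galadriel_box") %in% hits))
  expect_length(detect_clade_motifs("AAAAAAAAAA"), 0)
})

test_that("chromodomain extraction finds planted windows", {
  set.seed(33)
  filler <- function(n) paste(sample(c("A", "D", "E", "G", "N", "S", "T"), n,
                                     replace = TRUE), collapse = "")
  chd <- chromosel:::chd_peptide("CHD_I")
  poly <- paste0(filler(400), chd)
  win <- extract_chd(poly)
  expect_false(is.null(win))
  expect_equal(win$start, 401)
  expect_identical(chd_call(win$peptide)$group, "CHD_I")

  expect_null(extract_chd(strrep("A", 300)))

  mid <- paste0(filler(200), chd, filler(250))
  win2 <- extract_chd(mid, int_end_hint = 150)
  expect_equal(win2$start, 201)
})

test_that("classification of protein sets yields a tidy table", {
  prots <- c(one = paste0(strrep("G", 200), chromosel:::chd_peptide("CHD_I")),
             two = paste0(strrep("G", 200), chromosel:::chd_peptide("CHD_II")),
             none = strrep("A", 200))
  tab <- classify_chd_sequences(prots)
  expect_identical(tab$group, c("CHD_I", "CHD_II", "unclassified"))
  expect_true(is.na(tab$window_start[3]))
})
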