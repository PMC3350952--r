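make_ltr_genome <- function(ltr, interior_len, seed) {
  set.seed(seed)
  paste0(random_dna(800), ltr$ltr5, random_dna(interior_len), ltr$ltr3,
         random_dna(800))
}

test_that("find_ltr_pairs recovers planted repeats at their identity", {
  set.seed(20)
  ltr <- paste0("TG", random_dna(496), "CA")
  g <- make_ltr_genome(list(ltr5 = ltr, ltr3 = ltr), 1500, seed = 21)
  hits <- find_ltr_pairs(g)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$identity, 100)
  expect_equal(diff(hits[[1]]$ltr5), 500)

  pair <- mutate_ltr_pair(ltr, 0.03, seed = 3)   # ~97% identity
  g2 <- make_ltr_genome(pair, 1500, seed = 22)
  hits2 <- find_ltr_pairs(g2)
  expect_length(hits2, 1)
  truth <- identity_pct(pair$ltr5, pair$ltr3)
  expect_lt(abs(hits2[[1]]$identity - truth), 1)
})

test_that("ltr identity is symmetric and 100 iff identical", {
  set.seed(9)
  a <- random_dna(300)
  b <- mutate_ltr_pair(paste0("TG", a, "CA"), 0.05, seed = 2)
  expect_equal(identity_pct(b$ltr5, b$ltr3), identity_pct(b$ltr3, b$ltr5))
  expect_equal(identity_pct(b$ltr5, b$ltr5), 100)
  expect_lt(identity_pct(b$ltr5, b$ltr3), 100)
})

test_that("inverted terminal repeat check is TG...CA", {
  expect_true(check_itr("TGAAACA"))
  expect_false(check_itr("TAAAACA"))
  expect_false(check_itr("TGAAAGA"))
  expect_error(check_itr("TG"), "4 bp")
})

test_that("TSD detection finds the longest immediate flank duplication", {
  elem <- strrep("G", 50)
  seq5 <- paste0(strrep("T", 20), "CCTAT", elem, "CCTAT", strrep("T", 20))
  expect_identical(detect_tsd(seq5, c(25, 75)), "CCTAT")
  seq6 <- paste0(strrep("A", 20), "GTTTCT", elem, "GTTTCT", strrep("A", 20))
  expect_identical(detect_tsd(seq6, c(26, 76)), "GTTTCT")
  set.seed(8)
  seqr <- paste0(random_dna(20), elem, random_dna(20))
  expect_null(detect_tsd(seqr, c(20, 70)))
})

test_that("PBS detection respects length, spacer and threshold", {
  trna <- default_trna_3ends()[[1]]
  mk <- function(len, spacer) {
    pbs <- revcomp(substring(trna, nchar(trna) - len + 1, nchar(trna)))
    # trailing C padding cannot extend the complementarity for these lengths
    paste0(strrep("T", 50), strrep("A", spacer), pbs, strrep("C", 50))
  }
  hit13 <- find_pbs(mk(13, 1), 50)
  expect_equal(hit13$match_len, 13)
  expect_equal(hit13$spacer, 1)
  hit12 <- find_pbs(mk(12, 2), 50)
  expect_equal(hit12$match_len, 12)
  expect_equal(hit12$spacer, 2)
  expect_null(find_pbs(mk(10, 0), 50))   # below min_len
})

test_that("PPT detection finds purine runs at the boundary conditions", {
  mk <- function(run, gap) {
    paste0(strrep("C", 60), strrep("A", run %/% 2), strrep("G", run - run %/% 2),
           strrep("C", gap))
  }
  hit <- find_ppt(mk(14, 0), 74)
  expect_equal(hit$length, 14)
  expect_equal(hit$interval, c(60, 74))
  expect_equal(find_ppt(mk(12, 2), 74)$length, 12)
  expect_null(find_ppt(paste0(strrep("AC", 40)), 80))
  expect_null(find_ppt(mk(11, 0), 71))
})

test_that("ORF detection reports ATG-to-stop spans with the stop included", {
  orf <- paste0("ATG", strrep("AAA", 100), "TAA")
  seq <- paste0(strrep("C", 30), orf, strrep("C", 30))
  hits <- find_orfs(seq)
  fwd <- Filter(function(o) o$strand == "+", hits)
  expect_length(fwd, 1)
  expect_equal(diff(fwd[[1]]$interval), 306)
  expect_equal(fwd[[1]]$interval, c(30, 336))
  expect_length(find_orfs(paste0(strrep("C", 30), strrep("AAA", 110))), 0)
})

test_that("pseudo-ORF reconstruction marks internal stops without repair", {
  clean <- paste0("ATG", strrep("GCT", 20))
  expect_equal(reconstruct_pseudo_orf(clean)$n_stops, 0)
  broken <- paste0("ATG", strrep("GCT", 5), "TAA", strrep("GCT", 5), "TGA",
                   strrep("GCT", 5), "TAG", strrep("GCT", 5))
  res <- reconstruct_pseudo_orf(broken)
  expect_equal(res$n_stops, 3)
  expect_equal(res$stop_positions, c(7, 13, 19))
  expect_error(reconstruct_pseudo_orf(paste0("A", clean)), "out of frame")
})

test_that("domain order check accepts exactly subsequences of the canonical order", {
  expect_true(check_domain_order(c("CCHC", "PR", "RT", "RNH", "INT", "CHD"))$ok)
  expect_true(check_domain_order(c("PR", "RT", "CHD"))$ok)
  expect_false(check_domain_order(c("RT", "PR"))$ok)
  expect_false(check_domain_order(c("PR", "PR"))$ok)
  expect_false(check_domain_order(c("PR", "XYZ"))$ok)
})

test_that("family clustering follows the 80 percent single-linkage rule", {
  set.seed(14)
  master <- random_dna(600)
  mut <- function(s, rate, seed) {
    set.seed(seed)
    x <- strsplit(s, "")[[1]]
    hit <- which(runif(length(x)) < rate)
    for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    paste(x, collapse = "")
  }
  near <- c(e1 = master, e2 = mut(master, 0.05, 1))       # ~95%
  fams <- cluster_families(near)
  expect_length(fams, 1)
  expect_setequal(fams[[1]]$members, c("e1", "e2"))
  far <- c(e1 = master, e2 = mut(master, 0.30, 2))        # ~70%
  expect_length(cluster_families(far), 2)

  # two radiations: ~85% within, ~60% between
  m2 <- mut(master, 0.40, 3)
  rad <- c(a1 = mut(master, 0.075, 4), a2 = mut(master, 0.075, 5),
           b1 = mut(m2, 0.075, 6), b2 = mut(m2, 0.075, 7))
  fams2 <- cluster_families(rad)
  expect_length(fams2, 2)
  expect_setequal(fams2[[1]]$members, c("a1", "a2"))
  expect_setequal(fams2[[2]]$members, c("b1", "b2"))
})

test_that("consensus reconstruction is column-majority with stable ties", {
  copies <- c(x = "ACGT", y = "ACGA", z = "ACGT")
  expect_identical(build_consensus(copies), "ACGT")
  expect_identical(build_consensus(c(x = "AAAA", y = "AAAA")), "AAAA")
  # tie on the last column: first-listed copy wins
  expect_identical(build_consensus(c(x = "ACGT", y = "ACGA")), "ACGT")
  # gap wins only above 50 percent
  expect_identical(build_consensus(c(x = "A-", y = "--", z = "A-")), "A-")

  set.seed(6)
  master <- random_dna(500)
  copies10 <- vapply(1:10, function(i) {
    x <- strsplit(master, "")[[1]]
    hit <- which(runif(500) < 0.03)
    for (j in hit) x[j] <- sample(setdiff(c("A", "C", "G", "T"), x[j]), 1)
    paste(x, collapse = "")
  }, character(1))
  names(copies10) <- paste0("c", 1:10)
  cons <- build_consensus(copies10)
  agree <- mean(strsplit(cons, "")[[1]] == strsplit(master, "")[[1]])
  expect_gte(agree, 0.99)
})

test_that("annotation is deterministic: same input gives identical GFF3 bytes", {
  g <- plant_elements(15000, seed = 13)
  f1 <- tempfile(); f2 <- tempfile()
  write_gff3(annotate_genome(g$seq, "toy"), f1)
  write_gff3(annotate_genome(g$seq, "toy"), f2)
  expect_identical(readLines(f1), readLines(f2))
})
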