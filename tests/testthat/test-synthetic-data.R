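test_that("alignment simulation is deterministic given the seed", {
  tr <- study_tree()
  m <- study_model(6)
  a <- simulate_codon_alignment(tr, m, 50, seed = 9)
  b <- simulate_codon_alignment(tr, m, 50, seed = 9)
  expect_identical(a$alignment$codons, b$alignment$codons)
  expect_identical(a$site_classes, b$site_classes)
  c2 <- simulate_codon_alignment(tr, m, 50, seed = 10)
  expect_false(identical(a$alignment$codons, c2$alignment$codons))
})

test_that("site-class proportions converge to the model proportions", {
  tr <- study_tree()
  m <- study_model(6)
  sim <- simulate_codon_alignment(tr, m, 2000, seed = 77)
  props <- vapply(m$classes, `[[`, numeric(1), "prop")
  emp <- tabulate(sim$site_classes, 4) / 2000
  se <- sqrt(props * (1 - props) / 2000)
  expect_true(all(abs(emp - props) <= 3 * se))
})

test_that("degenerate trees simulate as contracted data", {
  phy <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  tr <- labeled_tree(phy)
  expect_warning(sim <- simulate_codon_alignment(tr, model_m0(2, 0.5), 30, seed = 1),
                 "identical")
  expect_true(all(apply(sim$alignment$codons, 2, function(x) length(unique(x)) == 1)))
  expect_error(model_a(2, 0.5, 0.3, 0.1, 0, "FG"))   # omega must be > 0
})

test_that("M0 simulation produces dN/dS-consistent substitution counts", {
  # omega = 0.2 < 1: per-site nonsyn/syn substitution count ratio, scaled by
  # the opportunity ratio, must stay below 1
  tr <- study_tree()
  m <- model_m0(2, 0.2)
  sim <- simulate_codon_alignment(tr, m, 500, seed = 31)
  gcode <- genetic_code()
  aa <- gcode$table[gcode$sense]
  phy <- tr$phylo
  ord <- ape::reorder.phylo(phy, "postorder")
  nsyn <- 0; nnon <- 0
  for (e in seq_len(nrow(ord$edge))) {
    p <- sim$node_states[ord$edge[e, 1], ]
    c2 <- sim$node_states[ord$edge[e, 2], ]
    ch <- which(p != c2)
    nsyn <- nsyn + sum(aa[p[ch]] == aa[c2[ch]])
    nnon <- nnon + sum(aa[p[ch]] != aa[c2[ch]])
  }
  # opportunity: ~3x more nonsynonymous single-nt neighbours than synonymous
  cls <- codon_pair_classes()
  opp <- sum(cls %in% c(3, 4)) / sum(cls %in% c(1, 2))
  expect_lt((nnon / nsyn) / opp, 1)
})

test_that("LTR pair mutation hits the requested divergence and spares termini", {
  p0 <- mutate_ltr_pair(paste0("TG", strrep("ACGT", 50), "CA"), 0, seed = 1)
  expect_identical(p0$ltr5, p0$ltr3)

  ltr <- paste0("TG", paste(sample(c("A", "C", "G", "T"), 996, replace = TRUE),
                            collapse = ""), "CA")
  ids <- vapply(1:200, function(i) {
    pair <- mutate_ltr_pair(ltr, 0.003, seed = i)
    expect_true(startsWith(pair$ltr3, "TG") && endsWith(pair$ltr3, "CA"))
    identity_pct(pair$ltr5, pair$ltr3)
  }, numeric(1))
  expect_gte(mean(ids), 99.5)
  expect_lte(mean(ids), 99.9)
  expect_error(mutate_ltr_pair(ltr, 0.7), "0, 0.5")
})

test_that("planted genomes carry the TSD on both immediate flanks", {
  g <- plant_elements(15000, seed = 5)
  for (tr in g$truth) {
    tsd <- tr$spec$tsd
    l <- nchar(tsd)
    s <- tr$element[1]; e <- tr$element[2]
    expect_identical(substring(g$seq, s - l + 1, s), tsd)
    expect_identical(substring(g$seq, e + 1, e + l), tsd)
  }
  # same seed => bit-identical genome
  g2 <- plant_elements(15000, seed = 5)
  expect_identical(g$seq, g2$seq)
})

test_that("element specs validate their structural invariants", {
  expect_error(element_spec(ltr_len = 50), ">= 100")
  expect_error(element_spec(tsd = "CCTATGG"), "4, 5 or 6")
  expect_error(element_spec(pbs_len = 9), "11-13")
  expect_error(element_spec(orf_domains = c("RT", "PR")), "canonical order")
  sp <- element_spec(chd_group = "none")
  expect_false("CHD" %in% sp$orf_domains)
  expect_error(plant_elements(2000, seed = 1), "too short")
})
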