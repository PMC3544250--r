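toy_geno <- function() {
  m <- rbind(
    het_ok   = c("H", "H", "A", "A"),
    hom_a    = c("A", "H", "A", "A"),
    het_miss = c("H", NA,  "A", "A"),
    no_rec   = c("H", "H", "H", "A"),
    rec_miss = c("H", "H", NA,  "A"))
  colnames(m) <- c("FG1", "FG2", "FL1", "BG1")
  m
}

test_that("foreground selection keeps exactly the plants heterozygous at every target marker", {
  g <- toy_geno()
  expect_identical(foreground_select(g, c("FG1", "FG2")),
                   c("het_ok", "no_rec", "rec_miss"))
  # missing at a foreground marker disqualifies
  expect_false("het_miss" %in% foreground_select(g, c("FG1", "FG2")))
  expect_error(foreground_select(g, "RM999"), "configuration error.*RM999")
})

test_that("recombinant selection filters on required flank calls, missing disqualifies", {
  g <- toy_geno()
  fg <- foreground_select(g, c("FG1", "FG2"))
  kept <- recombinant_select(g[fg, , drop = FALSE], c(FL1 = "A"))
  expect_identical(kept, "het_ok")
  expect_error(recombinant_select(g, c(FLX = "A")), "configuration error.*FLX")
})

test_that("foreground retention in BC1 matches the joint-heterozygosity expectation", {
  # the two target markers are ~0.7 Mb apart, so joint heterozygosity is
  # close to the single-locus 1/2; check against 99% binomial bounds
  set.seed(61)
  bc1 <- simulate_bc_population(300, 1, genetic_map())
  geno <- genotype_plants(bc1, saltol_panel())
  kept <- foreground_select(geno, c("RM493", "RM3412b"))
  bounds <- qbinom(c(0.005, 0.995), 300, 0.5)
  expect_gte(length(kept), bounds[1])
  expect_lte(length(kept), bounds[2])
})

test_that("background ranking on the toy fixture equals brute-force enumeration", {
  g <- read_genotype_matrix(toy_matrix_path())
  expect_equal(dim(g), c(4L, 6L))
  markers <- colnames(g)

  # independent oracle: enumerate (%R, %A, id) triples and sort
  triples <- t(vapply(rownames(g), function(id) naive_rpg(g[id, markers]),
                      numeric(2)))
  oracle <- rownames(g)[order(-triples[, "percent_R"], -triples[, "percent_A"],
                              rownames(g))]

  ranked <- background_select(g, markers, k = 4)
  expect_identical(ranked$plant_id, oracle)
  expect_identical(ranked$plant_id, c("P3", "P1", "P4", "P2"))
  # missing excluded from denominators
  expect_equal(ranked$percent_R[ranked$plant_id == "P1"], 90)
  # %R tie between P4 and P2 broken by %A
  expect_equal(ranked$percent_R[3:4], c(250 / 3, 250 / 3))
  expect_gt(ranked$percent_A[3], ranked$percent_A[4])
})

test_that("background selection boundaries: k overflow warns, empty set warns", {
  g <- read_genotype_matrix(toy_matrix_path())
  expect_warning(all4 <- background_select(g, colnames(g), k = 10),
                 "exceeds")
  expect_equal(nrow(all4), 4L)
  expect_warning(none <- background_select(g[0, , drop = FALSE],
                                           colnames(g), k = 2),
                 "empty candidate set")
  expect_equal(nrow(none), 0L)
})

test_that("fixed-ledger markers enter ranking as recipient-homozygous calls", {
  g <- rbind(p1 = c("H", "A"), p2 = c("A", "A"))
  colnames(g) <- c("B1", "B2")
  r <- background_rank(g, c("B1", "B2"), n_fixed = 8L)
  expect_equal(r$n_A, c(10, 9))
  expect_equal(r$percent_R[r$plant_id == "p1"], 100 * 9.5 / 10)
})

test_that("fixed-marker dropping follows the all-recipient rule with missing uninformative", {
  g <- rbind(s1 = c("A", "A", "A", NA),
             s2 = c("A", "H", "A", "A"))
  colnames(g) <- paste0("B", 1:4)
  res <- drop_fixed_markers(g, c("s1", "s2"), paste0("B", 1:4))
  expect_identical(res$dropped, c("B1", "B3"))   # B2 segregates, B4 has missing
  expect_identical(res$retained, c("B2", "B4"))
  expect_identical(sort(c(res$retained, res$dropped)), paste0("B", 1:4))

  # all markers fixed: screening list empties, %R computed from ledger alone
  all_a <- rbind(s1 = c("A", "A"), s2 = c("A", "A"))
  colnames(all_a) <- c("B1", "B2")
  res2 <- drop_fixed_markers(all_a, c("s1", "s2"), c("B1", "B2"))
  expect_identical(res2$retained, character(0))
  ledger_only <- compute_rpg(character(0), n_fixed = length(res2$dropped))
  expect_equal(ledger_only$percent_R, 100)
})

test_that("a campaign trace satisfies nesting, monotone improvement and ledger conservation", {
  cfg <- default_campaign_config(seed = 418, pop_size = 150)
  tr <- run_campaign(cfg)
  expect_length(tr$generations, 3L)
  n_bg <- length(cfg$roles$background)
  for (g in tr$generations) {
    expect_true(all(g$recombinant_ids %in% g$foreground_ids))
    expect_true(all(g$foreground_ids %in% rownames(g$genotypes)))
    expect_lte(length(g$recombinant_ids), length(g$foreground_ids))
    expect_lte(length(g$foreground_ids), nrow(g$genotypes))
    # fixed-marker ledger conservation at every generation
    expect_equal(length(g$screened_markers) + length(g$fixed_markers), n_bg)
    # background selection improves on its candidate pool
    sel <- g$ranking$percent_R[g$ranking$plant_id %in% g$advanced_ids]
    expect_gte(mean(sel), mean(g$ranking$percent_R))
    # no donor homozygote anywhere in a backcross program
    expect_false(any(g$genotypes == "B", na.rm = TRUE))
  }
  # selection is pure filtering: survivors' genotypes unchanged
  g1 <- tr$generations[[1]]
  expect_identical(g1$genotypes[g1$recombinant_ids, , drop = FALSE],
                   g1$genotypes[rownames(g1$genotypes) %in% g1$recombinant_ids, ,
                                drop = FALSE])
})

test_that("identical seed and config reproduce an identical selection trace", {
  cfg <- default_campaign_config(seed = 418, pop_size = 150)
  t1 <- run_campaign(cfg)
  t2 <- run_campaign(cfg)
  expect_identical(t1$summary, t2$summary)
  for (i in seq_along(t1$generations)) {
    expect_identical(t1$generations[[i]]$genotypes,
                     t2$generations[[i]]$genotypes)
    expect_identical(t1$generations[[i]]$advanced_ids,
                     t2$generations[[i]]$advanced_ids)
  }
})

test_that("the campaign halts with a named-generation diagnostic when selection empties", {
  # all calls missing: nothing can pass foreground selection
  cfg <- default_campaign_config(seed = 7, pop_size = 10, missing_rate = 1)
  expect_error(run_campaign(cfg), "halted at generation BC1.*foreground")

  # an unsatisfiable flank requirement (donor homozygosity never occurs in
  # a backcross to the recipient) empties recombinant selection
  roles <- selection_roles(
    flanks_by_generation = list(`1` = c(RM10825 = "B"),
                                `2` = c(RM10694 = "A"),
                                `3` = c(RM10694 = "A")),
    background = synthetic_background_panel()$name)
  cfg2 <- default_campaign_config(seed = 7, pop_size = 30, roles = roles)
  expect_error(run_campaign(cfg2), "halted at generation BC1.*recombinant")
})

test_that("campaign configuration is validated", {
  panel <- study_panel()
  expect_error(campaign_config(panel, pop_size = 1, n_parents = 2),
               "pop_size >= n_parents")
  roles <- selection_roles(foreground = c("RM493", "NOPE"),
                           background = "BG01.1")
  expect_error(campaign_config(panel, roles = roles),
               "configuration error.*NOPE")
  expect_error(selection_roles(foreground = "RM493",
                               background = c("RM493", "BG01.1")),
               "both foreground and background")
})
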