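test_that("compute_rpg evaluates the %A and %R formulas", {
  all_a <- compute_rpg(rep("A", 89))
  expect_equal(c(all_a$percent_A, all_a$percent_R), c(100, 100))

  all_h <- compute_rpg(rep("H", 89))
  expect_equal(c(all_h$percent_A, all_h$percent_R), c(0, 50))

  one_h <- compute_rpg(c(rep("A", 88), "H"))
  expect_equal(round(one_h$percent_A, 2), 98.88)
  expect_equal(round(one_h$percent_R, 2), 99.44)
  expect_equal(one_h$n_A, 88)
  expect_equal(one_h$n_H, 1)
})

test_that("compute_rpg is permutation-invariant and handles missing and ledger input", {
  set.seed(21)
  calls <- sample(c("A", "H", "B", NA), 60, replace = TRUE,
                  prob = c(0.6, 0.2, 0.1, 0.1))
  a <- compute_rpg(calls)
  b <- compute_rpg(sample(calls))
  expect_equal(a[, -1], b[, -1])

  # missing excluded from denominators; independent first-principles check
  expect_equal(unname(a$percent_R), unname(naive_rpg(calls)["percent_R"]))

  with_ledger <- compute_rpg(c("A", "H"), n_fixed = 3)
  expect_equal(with_ledger$percent_R, 100 * 4.5 / 5)

  expect_error(compute_rpg(c(NA_character_, NA)), "undefined result")
  expect_error(compute_rpg(c("A", "X")), "A, B, H or NA")
})

test_that("percent_R dominates percent_A with equality exactly when no heterozygote", {
  set.seed(33)
  for (i in 1:50) {
    calls <- sample(c("A", "H", "B"), 30, replace = TRUE)
    s <- compute_rpg(calls)
    expect_gte(s$percent_R, s$percent_A)
    if (s$n_H == 0) expect_equal(s$percent_R, s$percent_A)
    if (s$percent_R == 100) expect_true(s$n_H == 0 && s$n_B == 0)
  }
})

test_that("RPG histograms conserve counts with a closed final bin at 100", {
  h1 <- rpg_histogram(100, bin_width = 5)
  expect_equal(sum(h1$counts), 1)
  expect_equal(h1$counts[length(h1$counts)], 1)

  set.seed(8)
  x <- runif(500, 60, 100)
  h <- rpg_histogram(x, bin_width = 2.5)
  expect_equal(sum(h$counts), 500)
  expect_equal(h$n_plants, 500)
  expect_lte(h$breaks[1], min(x))

  expect_error(rpg_histogram(numeric(0)), "empty")
  expect_error(rpg_histogram(50, bin_width = 0))
})

test_that("the %R distribution of an unselected BC3 population peaks near 93.75", {
  set.seed(12)
  bc3 <- simulate_bc_population(400, 3, genetic_map())
  geno <- genotype_plants(bc3, study_panel())
  summ <- rpg_summaries(geno, markers = synthetic_background_panel()$name)
  h <- rpg_histogram(summ$percent_R, bin_width = 2.5)
  mode_bin <- which.max(h$counts)
  target_bin <- findInterval(93.75, h$breaks, rightmost.closed = TRUE)
  expect_lte(abs(mode_bin - target_bin), 1)
})

test_that("marker %R tracks the bp-weighted truth and tightens with marker density", {
  map <- genetic_map()
  set.seed(14)
  plants <- simulate_bc_population(150, 2, map)
  truth <- vapply(plants, true_rpg, numeric(1))

  panel89 <- synthetic_background_panel()
  g89 <- genotype_plants(plants, panel89)
  r89 <- rpg_summaries(g89)$percent_R
  expect_gte(mean(abs(r89 - truth) <= 5), 0.95)

  sparse <- synthetic_background_panel(48, min_per_chromosome = 4)
  dense <- synthetic_background_panel(480, min_per_chromosome = 40)
  r_sparse <- rpg_summaries(genotype_plants(plants, sparse))$percent_R
  r_dense <- rpg_summaries(genotype_plants(plants, dense))$percent_R
  expect_lt(mean(abs(r_dense - truth)), mean(abs(r_sparse - truth)))
})

test_that("graphical genotypes classify intervals from flanking calls", {
  panel <- study_panel()
  markers <- panel$name
  all_a <- matrix("A", 1, length(markers),
                  dimnames = list("pureline", markers))
  gg <- graphical_genotype(all_a, panel, "pureline")
  expect_true(all(unlist(lapply(gg$chromosomes, `[[`, "glyphs")) == "."))

  # heterozygous only at the two target markers: one introgression block on
  # chromosome 1, all other chromosomes uniformly recipient
  intro <- all_a
  rownames(intro) <- "IL"
  intro[, c("RM493", "RM3412b")] <- "H"
  gg2 <- graphical_genotype(intro, panel, "IL")
  chr1 <- gg2$chromosomes[["1"]]
  expect_true(any(chr1$glyphs == "+"))
  runs <- rle(chr1$glyphs)
  expect_equal(sum(runs$values == "+"), 1)  # a single contiguous block
  for (ch in setdiff(names(gg2$chromosomes), "1")) {
    expect_true(all(gg2$chromosomes[[ch]]$glyphs == "."))
  }

  expect_error(graphical_genotype(all_a, panel, "nope"), "lookup error")
})

test_that("text graphical genotypes round-trip exactly", {
  panel <- study_panel()
  set.seed(15)
  plants <- simulate_bc_population(3, 1, genetic_map())
  geno <- genotype_plants(plants, panel, missing_rate = 0.05)
  for (id in rownames(geno)) {
    gg <- graphical_genotype(geno, panel, id)
    parsed <- parse_graphical_genotype(format(gg))
    expect_identical(parsed,
                     lapply(gg$chromosomes, `[[`, "glyphs"))
  }
})

test_that("Duncan's test separates and joins groups as its ranges dictate", {
  # identical groups share a letter
  same <- duncan_mrt(list(g1 = c(5, 5, 5), g2 = c(5, 5, 5)))
  expect_equal(same$table$letters, c("a", "a"))

  # widely separated groups with tiny variance get distinct letters
  apart <- duncan_mrt(list(lo = c(1, 1.01, 0.99), hi = c(9, 9.01, 8.99)))
  expect_setequal(apart$table$letters, c("a", "b"))

  expect_error(duncan_mrt(list(a = 1:3)), "at least 2 groups")
  expect_error(duncan_mrt(list(a = 1:3, b = 2)), "at least 2 replicates")
})

test_that("with two groups Duncan's decision equals the pooled t-test at alpha", {
  set.seed(40)
  for (i in 1:25) {
    x <- rnorm(4, 10, 1)
    y <- rnorm(4, 10 + runif(1, 0, 2.5), 1)
    d <- duncan_mrt(list(x = x, y = y))
    duncan_sig <- !identical(d$table$letters[1], d$table$letters[2])
    t_sig <- t.test(x, y, var.equal = TRUE)$p.value < d$alpha
    expect_identical(duncan_sig, t_sig)
  }
})

test_that("the agronomic letter partition is reproduced under a variance consistent with it", {
  # plant-height style means; spread chosen so the first and fourth group
  # are homogeneous while the second and third separate
  means <- c(BT7 = 107.5, FL478 = 101.2, IL30 = 110.3, IL32 = 106.5)
  groups <- lapply(means, reps3, d = 0.8)
  res <- duncan_mrt(groups)
  expect_identical(res$table$letters, c("a", "b", "c", "a"))
  expect_equal(res$mse, 0.8^2, tolerance = 1e-10)
  # LSD reported alongside: t-based, two-sided
  expect_equal(res$lsd, qt(0.975, 8) * sqrt(2 * 0.64 / 3), tolerance = 1e-10)
})

test_that("salinity yield loss is zero to the threshold, linear beyond, clamped at 100", {
  expect_equal(salinity_yield_loss(c(0, 3)), c(0, 0))
  expect_equal(salinity_yield_loss(4), 12)
  expect_equal(salinity_yield_loss(6), 36)
  expect_equal(salinity_yield_loss(50), 100)
  expect_error(salinity_yield_loss(-1), "non-negative")
  # alternative threshold/slope parametrisation
  expect_equal(salinity_yield_loss(5, threshold = 4, slope = 10), 10)
})
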