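test_that("mean-centring divides each cell by its across-strain mean", {
  d <- tiny_design(3, 1, 1, 2)
  tab <- full_table(d, values = c(1, 2, 1, 4, 1, 6))  # g1: 2, 4, 6
  fc <- mean_center(tab, d)
  expect_equal(value_kind(fc), "fold_change")
  expect_equal(sort(fc$value[fc$gene == "g1"]), c(0.5, 1.0, 1.5))
  expect_equal(mean(fc$value[fc$gene == "g1"]), 1)
  # all-equal cell -> all fold changes exactly 1
  expect_equal(fc$value[fc$gene == "REF"], rep(1, 3))
})

test_that("centring leaves every complete cell with mean 1 (property)", {
  set.seed(11)
  for (i in 1:40) {
    d <- tiny_design(sample(2:5, 1), sample(1:3, 1), sample(1:3, 1),
                     sample(2:4, 1))
    fc <- mean_center(full_table(d, seed = i), d)
    df <- as.data.frame(fc)
    cell_means <- tapply(df$value,
                         paste(df$gene, df$condition, df$timepoint_h),
                         mean)
    expect_true(all(abs(cell_means - 1) <= 1e-12))
  }
})

test_that("degenerate cells yield missing output, not fabricated values", {
  d <- tiny_design(3, 1, 1, 2)
  tab <- full_table(d, seed = 1)
  # single-strain cell for g1: drop the other strains' rows
  solo <- tab[!(tab$gene == "g1" & tab$strain != "wt"), ]
  fc <- mean_center(solo)
  expect_false("g1" %in% fc$gene)
  expect_true("REF" %in% fc$gene)
  # all-zero cell: dropped with a warning
  zero <- tab
  zero$value[zero$gene == "g1"] <- 0
  expect_warning(fc0 <- mean_center(zero), "all-zero")
  expect_false("g1" %in% fc0$gene)
})

test_that("log2 transform floors zeros instead of dropping them", {
  d <- tiny_design(3, 1, 1, 2)
  fc <- full_table(d, values = rep(c(1, 8, 0), 2), value_kind = "fold_change")
  lt <- log2_transform(fc, floor = 2^-10)
  expect_equal(value_kind(lt), "log2_fold_change")
  expect_equal(sort(unique(lt$value)), c(-10, 0, 3))
  expect_equal(nrow(lt), nrow(fc))
  expect_error(log2_transform(fc, floor = 0), "floor")
})

test_that("the exclusion mask drops only profiled own-mutants plus leave-outs", {
  d <- default_design()
  expect_equal(exclusion_mask("CYG56", d), "cyg56")
  expect_equal(exclusion_mask("42.49CG1", d), character())
  expect_equal(exclusion_mask("42.49CG1", d, "54.10"), "54.10")
  expect_equal(sort(exclusion_mask("CDP1", d, "54.10")),
               c("54.10", "cdp1"))
  expect_error(exclusion_mask("NOPE", d), "unknown gene")
  expect_error(exclusion_mask("CYG56", d, "notastrain"), "leave-out")
})

test_that("pearson_cor matches hand-computed and boundary cases", {
  res <- pearson_cor(c(1, 2, 3), c(1, 3, 2))
  expect_equal(res$r, 0.5)
  expect_equal(res$r2, 0.25)
  expect_equal(res$n, 3)
  # perfect linear relations
  x <- c(1, 4, 2, 9, 5)
  up <- pearson_cor(x, 2 * x + 1)
  expect_equal(up$r, 1); expect_equal(up$r2, 1)
  expect_equal(up$p, .Machine$double.xmin)
  down <- pearson_cor(x, -x)
  expect_equal(down$r, -1); expect_equal(down$r2, 1)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 2:1), "insufficient")
})

test_that("pearson_cor agrees with cor.test across random vectors", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(3:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    mine <- pearson_cor(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("invert_pearson_p is the inverse of the p computation", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:150, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0, 2)
    res <- pearson_cor(x, y)
    expect_equal(invert_pearson_p(res$p, n), res$r2, tolerance = 1e-8)
  }
})

test_that("the screen matches a brute-force oracle on random small tables", {
  set.seed(31)
  for (i in 1:50) {
    d <- tiny_design(sample(3:5, 1), sample(1:2, 1), sample(1:2, 1),
                     sample(3:4, 1), with_mutants = (i %% 2 == 0))
    tab <- full_table(d, seed = 1000 + i)
    # random missingness
    if (i %% 3 == 0) tab <- tab[-sample(nrow(tab), 2), ]
    log_tab <- log2_transform(mean_center(tab, d))
    scr <- coexpression_screen(log_tab, d)
    orc <- oracle_screen(log_tab, d, "REF")
    for (g in names(orc)) {
      row <- scr$results[scr$results$gene == g, ]
      expect_equal(row$r, orc[[g]]$r, tolerance = 1e-10)
      expect_equal(row$p, orc[[g]]$p, tolerance = 1e-10)
      expect_equal(row$n, orc[[g]]$n)
    }
  }
})

test_that("sample counts follow the union exclusion rule on the full design", {
  tab <- simulate_dataset(default_config(), seed = 2)
  scr <- coexpression_screen(tab, default_design())
  res <- scr$results
  # unprofiled-mutant gene: only reference's mutant excluded
  expect_equal(res$n[res$gene == "42.49CG1"], 128)
  # profiled-mutant gene: both excluded
  expect_equal(res$n[res$gene == "CDP1"], 112)
  # leave-strain-out removes 16 more
  scr2 <- coexpression_screen(tab, default_design(), leave_out = "54.10")
  expect_equal(scr2$results$n[scr2$results$gene == "42.49CG1"], 112)
  # per-gene exclusion keeps the reference's mutant samples when fed a
  # fold-change table that still carries them
  fc_all <- mean_center(tab, default_design())
  scr3 <- coexpression_screen(fc_all, default_design(),
                              pair_exclusion = "per_gene")
  expect_equal(scr3$results$n[scr3$results$gene == "42.49CG1"], 144)
  # raw input: own-mutant rows are dropped before centring, so the
  # reference is simply absent in its own mutant either way
  scr4 <- coexpression_screen(tab, default_design(),
                              pair_exclusion = "per_gene")
  expect_equal(scr4$results$n[scr4$results$gene == "42.49CG1"], 128)
})

test_that("an artifact planted in a gene's own profiled mutant changes nothing", {
  tab <- simulate_dataset(default_config(), seed = 6)
  base <- coexpression_screen(tab, default_design())
  poisoned <- tab
  sel <- poisoned$gene == "CDP1" & poisoned$strain == "cdp1"
  poisoned$value[sel] <- 1e6
  after <- coexpression_screen(poisoned, default_design())
  row_b <- base$results[base$results$gene == "CDP1", ]
  row_a <- after$results[after$results$gene == "CDP1", ]
  expect_equal(row_a$r, row_b$r, tolerance = 1e-12)
  expect_equal(row_a$p, row_b$p, tolerance = 1e-12)
  expect_equal(row_a$n, row_b$n)
})

test_that("results are ranked by r2 with the reference control row at 1", {
  tab <- simulate_dataset(default_config(), seed = 3)
  scr <- coexpression_screen(tab, default_design())
  res <- scr$results
  expect_equal(res$gene[1], "CYG56")
  expect_equal(res$r2[1], 1)
  r2 <- res$r2[!is.na(res$r2)]
  expect_true(all(diff(r2) <= 0))
  expect_equal(res$r2, res$r^2, tolerance = 1e-12)
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
})

test_that("degenerate genes surface as flagged rows, not errors", {
  d <- tiny_design(3, 2, 2, 3)
  tab <- full_table(d, seed = 9)
  tab$value[tab$gene == "g2"] <- 5  # constant -> fold change constant 1
  scr <- coexpression_screen(tab, d)
  row <- scr$results[scr$results$gene == "g2", ]
  expect_true(is.na(row$r))
  expect_match(row$note, "constant")
})

test_that("planted co-regulation is recovered and controls stay weak", {
  # minimal shared-regulator setting: -3 log2 in one strain on the
  # reference and one target, noise 0.5
  d <- default_design()
  hits <- 0
  for (s in 1:25) {
    geno <- matrix(-3, 2, 1, dimnames = list(c("CYG56", "42.49CG1"), "54.10"))
    cfg <- generator_config(d, genotype_effects = geno, noise_sd_log2 = 0.5,
                            seed = s)
    r2 <- coef(coexpression_screen(simulate_dataset(cfg), d))
    if (names(r2)[1] == "42.49CG1") hits <- hits + 1
  }
  expect_gte(hits, 24)
  # stable genes stay below the co-regulated gene in the default config
  tab <- simulate_dataset(default_config(), seed = 13)
  r2 <- coef(coexpression_screen(tab, default_design()))
  expect_true(all(r2["42.49CG1"] > r2[c("20.40CG1", "258.90CG", "CG-A", "CG-B")]))
})
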