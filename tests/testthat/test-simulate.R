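test_that("the default config generates the full 144-sample panel table", {
  tab <- simulate_dataset(default_config(), seed = 5)
  expect_s3_class(tab, "measurement_table")
  expect_equal(length(unique(tab$sample_id)), 144)
  expect_equal(nrow(tab), 144 * 12)
  expect_equal(value_kind(tab), "relative_expression")
})

test_that("identical seeds give bit-identical tables, different seeds differ", {
  cfg <- default_config()
  a <- simulate_dataset(cfg, seed = 11)
  b <- simulate_dataset(cfg, seed = 11)
  c <- simulate_dataset(cfg, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$value, c$value))
  # deterministic components identical across seeds at noise 0
  cfg0 <- default_config(noise_sd_log2 = 0)
  expect_identical(simulate_dataset(cfg0, seed = 1)$value,
                   simulate_dataset(cfg0, seed = 2)$value)
})

test_that("zero effects and zero noise give expression exactly 1", {
  d <- tiny_design(3, 2, 2, 3)
  cfg <- generator_config(d, noise_sd_log2 = 0)
  tab <- simulate_dataset(cfg)
  expect_true(all(tab$value == 1))
})

test_that("a knocked-out gene takes the knockout floor in its own mutant only", {
  d <- tiny_design(3, 2, 2, 3, with_mutants = TRUE)  # g1 -> mut1, g2 -> mut2
  cfg <- generator_config(d, knockout_floor_log2 = -10,
                          detection_floor = 2^-10, noise_sd_log2 = 0.4)
  tab <- simulate_dataset(cfg, seed = 8)
  own <- tab$value[tab$gene == "g1" & tab$strain == "mut1"]
  expect_length(own, 4)  # 2 conditions x 2 timepoints
  expect_true(all(own == 2^-10))
  expect_true(all(tab$value[tab$gene == "g1" & tab$strain != "mut1"] > 2^-10))
})

test_that("own-mutant knockout cells of the default config are at the floor", {
  tab <- simulate_dataset(default_config(), seed = 4)
  for (g in c("CYG56", "CDP1", "20.40CG1", "258.90CG")) {
    mut <- unname(default_design()$gene_to_mutant[g])
    expect_identical(tab$value[tab$gene == g & tab$strain == mut],
                     rep(2^-10, 16))
  }
  # hit gene's mutant not profiled: no knockout anywhere
  expect_true(all(tab$value[tab$gene == "42.49CG1"] > 2^-10))
})

test_that("effects add on the log2 scale", {
  d <- tiny_design(3, 2, 2, 3)
  geno <- matrix(1.5, 1, 1, dimnames = list("g1", "mut1"))
  cfg1 <- generator_config(d, genotype_effects = geno, noise_sd_log2 = 0)
  geno2 <- geno * 2
  cfg2 <- generator_config(d, genotype_effects = geno2, noise_sd_log2 = 0)
  t1 <- simulate_dataset(cfg1)
  t2 <- simulate_dataset(cfg2)
  sel <- t1$gene == "g1" & t1$strain == "mut1"
  expect_equal(log2(t2$value[sel]) - log2(t1$value[sel]),
               rep(1.5, sum(sel)))
  # condition + time + genotype stack
  cond <- matrix(0.5, 1, 1, dimnames = list("g1", "cond1"))
  tim <- matrix(-0.25, 1, 1, dimnames = list("g1", "2"))
  cfg3 <- generator_config(d, condition_effects = cond, time_effects = tim,
                           genotype_effects = geno, noise_sd_log2 = 0)
  t3 <- simulate_dataset(cfg3)
  v <- t3$value[t3$gene == "g1" & t3$strain == "mut1" &
                t3$condition == "cond1" & t3$timepoint_h == 2]
  expect_equal(log2(v), rep(1.5 + 0.5 - 0.25, length(v)))
})

test_that("values never fall below the detection floor", {
  d <- tiny_design(3, 2, 2, 3)
  geno <- matrix(-30, 1, 1, dimnames = list("g1", "mut1"))
  cfg <- generator_config(d, genotype_effects = geno, noise_sd_log2 = 1,
                          detection_floor = 2^-8)
  tab <- simulate_dataset(cfg, seed = 2)
  expect_true(all(tab$value >= 2^-8))
  expect_true(all(tab$value[tab$gene == "g1" & tab$strain == "mut1"] == 2^-8))
})

test_that("the null config removes all genotype structure", {
  cfg0 <- null_config(default_config(noise_sd_log2 = 0))
  tab <- simulate_dataset(cfg0)
  # all strains identical within each condition x time cell
  df <- as.data.frame(tab)
  spread <- tapply(df$value,
                   paste(df$gene, df$condition, df$timepoint_h),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  # and no knockouts survive
  expect_true(all(tab$value[tab$gene == "CYG56" & tab$strain == "cyg56"] ==
                  tab$value[tab$gene == "CYG56" & tab$strain == "704"]))
})

test_that("the Ct layer inverts expression around the reference Ct and caps", {
  d <- tiny_design(2, 1, 1, 3)
  tab <- full_table(d, values = rep(c(1, 0.25, 2^-25), times = 2))
  ct <- ct_layer(tab, d, reference_ct = 20, ct_cap = 40)
  expect_equal(value_kind(ct), "ct")
  expect_equal(ct$value[ct$gene == "REF"][1],
               20 - log2(tab$value[tab$gene == "REF"][1]))
  # expression 1 -> Ct 20; 0.25 -> 22; 2^-25 -> 45 > cap, absent
  expect_true(all(abs(ct$value[match(paste(tab$sample_id, tab$gene)[tab$value == 1],
                                     paste(ct$sample_id, ct$gene))] - 20) < 1e-12))
  expect_equal(sort(unique(round(ct$value[ct$gene != "STD"], 6))), c(20, 22))
  expect_equal(sum(!paste(tab$sample_id, tab$gene) %in%
                     paste(ct$sample_id, ct$gene)),
               sum(tab$value == 2^-25))
  # one internal-standard row per sample at exactly the reference Ct
  expect_equal(sum(ct$gene == "STD"), 2)
  expect_true(all(ct$value[ct$gene == "STD"] == 20))
  expect_error(ct_layer(full_table(d, values = 0), d), "nonpositive")
})

test_that("invalid generator configs are rejected", {
  d <- tiny_design()
  expect_error(generator_config(d, noise_sd_log2 = -1), "noise_sd_log2")
  expect_error(generator_config(d, detection_floor = 0), "detection_floor")
  expect_error(generator_config(
    d, genotype_effects = matrix(1, 1, 1, dimnames = list("nope", "mut1"))),
    "unknown gene")
  expect_error(generator_config(
    d, condition_effects = matrix(1, 1, 1, dimnames = list("g1", "nope"))),
    "unknown condition")
})

test_that("the shipped YAML config reproduces the in-code default", {
  path <- system.file("extdata", "non1_screen.yaml", package = "coexscreen")
  cfg <- read_config(path)
  ref <- default_config()
  expect_equal(cfg$genotype_effects, ref$genotype_effects)
  expect_equal(cfg$condition_effects, ref$condition_effects)
  expect_identical(simulate_dataset(cfg, seed = 3)$value,
                   simulate_dataset(ref, seed = 3)$value)
})
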