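test_that("resampling is stratified, size-preserving and species-linked", {
  d <- simulate_dataset(simulation_spec(n_pirna = 8, n_other = 30, seed = 5))
  set.seed(1)
  r <- resample_dataset(d)
  expect_equal(sum(r$class_map$gene_class == "piRNA"), 8L)
  expect_equal(sum(r$class_map$gene_class == "other"), 30L)
  expect_equal(nrow(r$counts), nrow(d$counts))
  # every drawn gene carries all its species rows jointly
  tab <- table(r$counts$gene_id)
  expect_true(all(tab == length(d$species)))

  # a singleton stratum reproduces the original counts up to gene ids
  one <- mk_dataset(
    data.frame(gene_id = c("p", "o"), species = "s",
               dn = c(3, 1), ds = c(1, 2), pn = c(2, 2), ps = c(1, 3)),
    data.frame(gene_id = c("p", "o"), gene_class = c("piRNA", "other")))
  set.seed(2)
  r1 <- resample_dataset(one)
  expect_equal(r1$counts[order(r1$counts$gene_class),
                         c("dn", "ds", "pn", "ps")],
               one$counts[order(one$counts$gene_class),
                          c("dn", "ds", "pn", "ps")],
               ignore_attr = TRUE)
})

test_that("bootstrap means of pooled counts track the original pooled counts", {
  d <- simulate_dataset(simulation_spec(n_pirna = 10, n_other = 60,
                                        mean_div = 10, mean_poly = 10,
                                        seed = 23))
  orig <- pool_counts(d, context = "divergence", gene_class = "piRNA")["ns"]
  per_gene <- tapply(d$counts$dn[d$counts$gene_class == "piRNA"],
                     d$counts$gene_id[d$counts$gene_class == "piRNA"], sum)
  B <- 400
  set.seed(99)
  reps <- replicate(B, sum(sample(per_gene, length(per_gene),
                                  replace = TRUE)))
  se <- sd(reps) / sqrt(B)
  set.seed(99)
  reps2 <- vapply(seq_len(B), function(i) {
    r <- resample_dataset(d)
    unname(pool_counts(r, context = "divergence", gene_class = "piRNA")["ns"])
  }, numeric(1))
  expect_lt(abs(mean(reps2) - orig), 3 * max(se, sd(reps2) / sqrt(B)))
})

test_that("bootstrap_statistics is reproducible and conserves strata", {
  d <- simulate_dataset(selected_truth_spec(seed = 61, n_other = 120))
  b1 <- bootstrap_statistics(d, model = "full", B = 60, seed = 42)
  b2 <- bootstrap_statistics(d, model = "full", B = 60, seed = 42)
  expect_identical(b1$chi, b2$chi)
  expect_identical(b1$zeta, b2$zeta)
  expect_identical(b1$contrasts, b2$contrasts)
  b3 <- bootstrap_statistics(d, model = "full", B = 60, seed = 43)
  expect_false(identical(b1$zeta, b3$zeta))

  expect_equal(nrow(b1$chi), 60L)
  expect_true(all(b1$contrasts$p_value >= 0 & b1$contrasts$p_value <= 1,
                  na.rm = TRUE))
  # point estimates equal the direct count-based statistics (full model)
  for (sp in d$species)
    expect_equal(unname(b1$point_zeta[sp]), zeta_from_counts(d, sp),
                 tolerance = 1e-12)
})

test_that("B = 1 with a fixed seed gives a reproducible single replicate", {
  d <- simulate_dataset(selected_truth_spec(seed = 62, n_other = 80))
  b <- bootstrap_statistics(d, model = "selected", B = 1, seed = 7)
  b2 <- bootstrap_statistics(d, model = "selected", B = 1, seed = 7)
  expect_identical(b$zeta, b2$zeta)
  expect_equal(dim(b$zeta), c(1L, 3L))
})

test_that("sign p-value counts opposing replicates, zeros conservatively", {
  expect_equal(sign_pvalue(c(1, -1, 1, 1), 0.5), 0.25)
  expect_equal(sign_pvalue(c(1, 1, 1, 1), 0.5), 0)
  expect_equal(sign_pvalue(c(-1, -1), 2), 1)
  expect_equal(sign_pvalue(c(0, 1, 1, 1), 0.5), 0.25)   # zero opposes
  expect_equal(sign_pvalue(c(1, NA, -1, 1), 0.5), 1 / 3)
  expect_equal(sign_pvalue(c(1, -1, 1, 1), 0.5, add_one = TRUE), 2 / 5)
  expect_error(sign_pvalue(c(1, -1), 0), "nonzero")
  expect_error(sign_pvalue(c(NA_real_, NA_real_), 1), "no valid")
})

test_that("contrast p-values shrink as the true between-species effect grows", {
  base <- selected_truth()
  make_spec <- function(effect, seed) {
    beta <- base
    beta["mel.div.piRNA"] <- base["ana.wil.div.piRNA"] * effect *
      base["mel.div.other"] / base["ana.div.other"]
    sp <- selected_truth_spec(seed = seed, n_other = 250)
    sp$beta <- beta[sp$beta_model$params]
    sp
  }
  pv <- function(effect, seed) {
    d <- simulate_dataset(make_spec(effect, seed))
    b <- bootstrap_statistics(d, model = "selected", B = 300, seed = 11)
    ct <- b$contrasts
    ct$p_value[ct$species_1 == "mel" & ct$species_2 == "ana" &
                 ct$statistic == "zeta"]
  }
  # weak effect (zeta ratio ~1.2) vs strong effect (~4): average over a few
  # seeds to damp simulation noise
  weak <- mean(vapply(1:3, function(s) pv(1.2, 100 + s), numeric(1)))
  strong <- mean(vapply(1:3, function(s) pv(4, 200 + s), numeric(1)))
  expect_lt(strong, weak + 1e-12)
})
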