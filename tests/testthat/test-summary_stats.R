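test_that("chi and zeta reduce to 1 when the contrasted odds are equal", {
  # balanced counts in every cell: all pooled odds identical
  counts <- expand.grid(gene_id = sprintf("g%02d", 1:8),
                        species = c("s1", "s2"), stringsAsFactors = FALSE)
  counts$dn <- 3L; counts$ds <- 6L; counts$pn <- 3L; counts$ps <- 6L
  cm <- data.frame(gene_id = sprintf("g%02d", 1:8),
                   gene_class = rep(c("piRNA", "other"), 4))
  d <- mk_dataset(counts, cm)
  f <- fit_model(d, model_full(d$species))
  for (sp in d$species) {
    expect_equal(chi_statistic(f, sp), 1)
    expect_equal(zeta_statistic(f, sp), 1)
    expect_equal(chi_from_counts(d, sp), 1)
    expect_equal(zeta_from_counts(d, sp), 1)
  }
})

test_that("fit-based and count-based chi/zeta agree under the full model", {
  d <- simulate_dataset(simulation_spec(n_pirna = 15, n_other = 60,
                                        mean_div = 20, mean_poly = 20,
                                        seed = 31))
  f <- fit_model(d, model_full(d$species))
  for (sp in d$species) {
    expect_equal(chi_statistic(f, sp), chi_from_counts(d, sp),
                 tolerance = 1e-12)
    expect_equal(zeta_statistic(f, sp), zeta_from_counts(d, sp),
                 tolerance = 1e-12)
  }
})

test_that("chi and zeta are invariant to rescaling the baseline alpha", {
  d <- simulate_dataset(simulation_spec(n_pirna = 10, n_other = 40,
                                        mean_div = 15, mean_poly = 15,
                                        seed = 17))
  for (scale in c(0.1, 2, 37)) {
    f1 <- fit_model(d, model_full(d$species))
    f2 <- fit_model(d, model_full(d$species), alpha = d$alpha * scale)
    for (sp in d$species) {
      expect_equal(chi_statistic(f2, sp), chi_statistic(f1, sp),
                   tolerance = 1e-9)
      expect_equal(zeta_statistic(f2, sp), zeta_statistic(f1, sp),
                   tolerance = 1e-9)
    }
  }
})

test_that("odds_from_fit refuses ambiguous or degenerate cells", {
  d <- simulate_dataset(simulation_spec(n_pirna = 10, n_other = 40,
                                        mean_div = 15, mean_poly = 15,
                                        seed = 19))
  fcomp <- fit_model(d, model_compartment_div("mel", c("ana", "wil")))
  # whole-class piRNA divergence odds span the two compartment parameters
  expect_error(odds_from_fit(fcomp, "mel", "divergence", "piRNA"),
               "several parameters")
  # but each compartment is well-defined
  expect_gt(zeta_statistic(fcomp, "mel", compartment = "nuclear"), 0)
  expect_error(odds_from_fit(fcomp, "mel", "divergence", "piRNA", "plasmid"),
               "no cell")
})

test_that("single-gene 1/NI_TG is the plain odds ratio", {
  d <- mk_dataset(data.frame(gene_id = "g", species = "s",
                             dn = 2, ds = 1, pn = 1, ps = 2),
                  data.frame(gene_id = "g", gene_class = "piRNA"))
  r <- inverse_ni_tg(d, "s", "piRNA")
  expect_equal(r$value, 4)  # (2/1)/(1/2)
  expect_equal(r$n_used, 1L)

  set.seed(88)
  for (i in 1:20) {
    x <- rpois(4, 6) + 1L
    d1 <- mk_dataset(data.frame(gene_id = "g", species = "s",
                                dn = x[1], ds = x[2], pn = x[3], ps = x[4]),
                     data.frame(gene_id = "g", gene_class = "other"))
    expect_equal(inverse_ni_tg(d1, "s", "other")$value,
                 (x[1] * x[4]) / (x[2] * x[3]))
  }
})

test_that("1/NI_TG weights genes and reports zero-denominator exclusions", {
  # two identical symmetric genes give exactly 1
  counts <- data.frame(gene_id = c("a", "b"), species = "s",
                       dn = 2, ds = 2, pn = 2, ps = 2)
  cm <- data.frame(gene_id = c("a", "b"), gene_class = "piRNA")
  expect_equal(inverse_ni_tg(mk_dataset(counts, cm), "s", "piRNA")$value, 1)

  # a gene with Ps + Ds = 0 is excluded and counted
  counts2 <- rbind(counts, data.frame(gene_id = "c", species = "s",
                                      dn = 5, ds = 0, pn = 5, ps = 0))
  cm2 <- rbind(cm, data.frame(gene_id = "c", gene_class = "piRNA"))
  r <- inverse_ni_tg(mk_dataset(counts2, cm2), "s", "piRNA")
  expect_equal(r$value, 1)
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$n_used, 2L)

  # weighted-sum denominator of zero -> undefined
  counts3 <- data.frame(gene_id = "a", species = "s",
                        dn = 3, ds = 2, pn = 0, ps = 2)
  r3 <- mk_dataset(counts3, data.frame(gene_id = "a", gene_class = "other"))
  expect_error(inverse_ni_tg(r3, "s", "other"), "undefined")
  expect_error(inverse_ni_tg(r3, "s", "piRNA"), "no genes")

  # hand-computed weighted ratio on an asymmetric pair
  counts4 <- data.frame(gene_id = c("a", "b"), species = "s",
                        dn = c(6, 1), ds = c(2, 3), pn = c(2, 4),
                        ps = c(4, 2))
  d4 <- mk_dataset(counts4, data.frame(gene_id = c("a", "b"),
                                       gene_class = "other"))
  w <- c(4 + 2, 2 + 3)
  expected <- (6 * 4 / w[1] + 1 * 2 / w[2]) / (2 * 2 / w[1] + 3 * 4 / w[2])
  expect_equal(inverse_ni_tg(d4, "s", "other")$value, expected)
})
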