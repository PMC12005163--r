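test_that("single-observation binomial log-likelihood matches the closed form", {
  # 4 NS of 6 variants at odds 2 (P = 2/3): binomial gives 240/729
  expect_equal(gene_log_likelihood(4, 6, beta = 2, alpha = 1),
               log(choose(6, 4) * (2 / 3)^4 * (1 / 3)^2))
  expect_equal(gene_log_likelihood(4, 6, beta = 2, alpha = 1), log(240 / 729))
  # same odds reached through any beta*alpha factorization
  expect_equal(gene_log_likelihood(4, 6, beta = 2 / 0.308, alpha = 0.308),
               log(240 / 729))

  # n = 0 carries no information: log-likelihood exactly 0
  expect_identical(gene_log_likelihood(0, 0, beta = 5, alpha = 0.3), 0)

  # saturating case ns = n: approaches 0 monotonically as beta grows
  lls <- gene_log_likelihood(3, 3, beta = c(1, 10, 100, 1e6), alpha = 1)
  expect_true(all(diff(lls) > 0))
  expect_true(all(lls <= 0))
  expect_lt(abs(lls[4]), 1e-5)

  expect_error(gene_log_likelihood(7, 6, 1, 1), "ns")
  expect_error(gene_log_likelihood(1, 2, -1, 1), "beta")
  expect_error(gene_log_likelihood(1, 2, 1, 0), "alpha")
})

test_that("model log-likelihood sums observations gene-wise", {
  d1 <- one_obs_dataset(4, 2)
  m <- model_single()
  expect_equal(model_log_likelihood(d1, m, c(all = 2), alpha = 1),
               gene_log_likelihood(4, 6, 2, 1))

  # dataset of genes all with n = 0 has total log-likelihood 0
  z <- mk_dataset(data.frame(gene_id = c("a", "b"), species = "s1",
                             dn = 0, ds = c(0, 1), pn = 0, ps = c(1, 0)),
                  data.frame(gene_id = c("a", "b"), gene_class = "other"))
  zz <- z
  zz$counts$ds <- 0L; zz$counts$ps <- 0L
  zz$alpha <- 1
  expect_equal(model_log_likelihood(zz, m, c(all = 3), alpha = 1), 0)

  expect_error(model_log_likelihood(d1, m, c(1, 2), alpha = 1), "length")
})

test_that("closed-form ML equals pooled odds over alpha, with degeneracy flags", {
  d1 <- one_obs_dataset(4, 2)
  cf <- closed_form_beta(d1, model_single(), alpha = 1)
  expect_equal(unname(cf$beta), 2)
  expect_equal(unname(cf$flags), "ok")

  # pooled ns = s gives beta = 1/alpha
  db <- one_obs_dataset(7, 7)
  cf2 <- closed_form_beta(db, model_single(), alpha = 0.25)
  expect_equal(unname(cf2$beta), 4)

  # degenerate pools are flagged, not silently propagated: divergence with
  # only nonsynonymous variants gives an unbounded divergence modifier
  dinf <- mk_dataset(data.frame(gene_id = "g", species = "s", dn = 3, ds = 0,
                                pn = 2, ps = 2),
                     data.frame(gene_id = "g", gene_class = "other"))
  mctx <- mk_model("ctx", data.frame(context = c("divergence", "polymorphism"),
                                     param = c("div", "poly")))
  expect_warning(cfi <- closed_form_beta(dinf, mctx, alpha = 1), "unbounded")
  expect_identical(unname(cfi$beta[["div"]]), Inf)
  expect_equal(unname(cfi$flags[["div"]]), "nonidentifiable")

  dz <- mk_dataset(data.frame(gene_id = "g", species = "s", dn = 0, ds = 0,
                              pn = 0, ps = 3),
                   data.frame(gene_id = "g", gene_class = "other"))
  m2 <- mk_model("ctx", data.frame(context = c("divergence", "polymorphism"),
                                   param = c("div", "poly")))
  cfz <- closed_form_beta(dz, m2, alpha = 1)
  expect_equal(unname(cfz$flags), c("uninformative", "boundary_zero"))
  expect_equal(unname(cfz$beta), c(1, 0))
})

test_that("closed-form estimate maximizes the likelihood (grid oracle)", {
  d <- random_small_dataset(401, n_genes = 6, n_species = 2)
  m <- model_by(c("species", "context"), d$species)
  f <- fit_model(d, m)
  for (k in seq_along(f$beta)) {
    for (fac in c(0.5, 0.9, 0.99, 1.01, 1.1, 2)) {
      b <- f$beta
      b[k] <- b[k] * fac
      expect_lt(model_log_likelihood(d, m, b, d$alpha), f$loglik)
    }
  }
})

test_that("numerical optimizer agrees with the closed form", {
  for (seed in 1:25) {
    d <- random_small_dataset(seed)
    m <- mk_model("ctx", data.frame(context = c("divergence", "polymorphism"),
                                    param = c("div", "poly")))
    fc <- fit_model(d, m, method = "closed_form")
    fn <- fit_model(d, m, method = "numerical")
    expect_true(fn$converged)
    expect_lt(max(abs(fn$beta - fc$beta) / fc$beta), 1e-6)
    expect_equal(fn$loglik, fc$loglik, tolerance = 1e-10)
  }
})

test_that("log-likelihood is monotone under model nesting", {
  for (seed in c(7, 77, 777)) {
    d <- random_small_dataset(seed, n_genes = 8, n_species = 3)
    chain <- list(model_single(), model_species(d$species),
                  model_species_context(d$species), model_full(d$species))
    lls <- vapply(chain, function(m) fit_model(d, m)$loglik, numeric(1))
    expect_true(all(diff(lls) >= -1e-9))
  }
})

test_that("fit is invariant to gene order and within-cell count splitting", {
  d <- random_small_dataset(55, n_genes = 6, n_species = 2)
  m <- model_species_context(d$species)
  f <- fit_model(d, m)

  perm <- d$counts[sample(nrow(d$counts)),
                   c("gene_id", "species", "dn", "ds", "pn", "ps")]
  dp <- mk_dataset(perm, d$class_map, species = d$species)
  fp <- fit_model(dp, m)
  expect_equal(fp$beta, f$beta)
  expect_equal(fp$loglik, f$loglik)

  # split one gene's counts into two genes in the same cell: beta-hat and
  # LRT statistics are unchanged (loglik shifts by a beta-free constant)
  cn <- d$counts[c("gene_id", "species", "dn", "ds", "pn", "ps")]
  g <- cn$gene_id[1]
  rows <- cn[cn$gene_id == g, , drop = FALSE]
  half <- rows
  half$dn <- rows$dn %/% 2; half$ds <- rows$ds %/% 2
  half$pn <- rows$pn %/% 2; half$ps <- rows$ps %/% 2
  rest <- rows
  rest[c("dn", "ds", "pn", "ps")] <- rows[c("dn", "ds", "pn", "ps")] -
    half[c("dn", "ds", "pn", "ps")]
  rest$gene_id <- paste0(g, "_b")
  cn2 <- rbind(cn[cn$gene_id != g, ], half, rest)
  cm2 <- rbind(d$class_map,
               within(d$class_map[d$class_map$gene_id == g, ],
                      gene_id <- paste0(g, "_b")))
  d2 <- mk_dataset(cn2, cm2, species = d$species)
  f2 <- fit_model(d2, m)
  expect_equal(f2$beta, f$beta)
  f0 <- fit_model(d, model_single())
  f02 <- fit_model(d2, model_single())
  expect_equal(f2$loglik - f02$loglik, f$loglik - f0$loglik,
               tolerance = 1e-10)
})

test_that("fit rejects models leaving parameters or cells unassigned", {
  d <- toy_dataset()
  unused <- mk_model("unused", data.frame(
    species = c("*", "zzz"), context = "*", gene_class = "*",
    compartment = "*", param = c("a", "b")))
  expect_error(fit_model(d, unused), "matching no cell")
  partial <- mk_model("partial", data.frame(
    species = "mel", context = "divergence", gene_class = "*",
    compartment = "*", param = "a"))
  expect_error(fit_model(d, partial), "no parameter")
})
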