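# shared in-code fixtures for the suite

# two-gene toy table: g1 (piRNA) 4/2/1/1, g2 (other) all zero
toy_dataset <- function() {
  counts <- data.frame(gene_id = c("g1", "g2"), species = "mel",
                       dn = c(4L, 0L), ds = c(2L, 0L),
                       pn = c(1L, 0L), ps = c(1L, 0L))
  cm <- data.frame(gene_id = c("g1", "g2"),
                   gene_class = c("piRNA", "other"))
  mk_dataset(counts, cm)
}

# single observation with ns nonsynonymous / s synonymous polymorphisms
one_obs_dataset <- function(ns = 4L, s = 2L) {
  mk_dataset(data.frame(gene_id = "g1", species = "mel",
                        dn = 0L, ds = 0L, pn = ns, ps = s),
             data.frame(gene_id = "g1", gene_class = "other"))
}

# small random dataset with both classes in every cell; counts drawn so all
# cells are identifiable (at least one NS and one S pooled per cell)
random_small_dataset <- function(seed, n_genes = 6L, n_species = 2L,
                                 lambda = 8) {
  set.seed(seed)
  repeat {
    sp <- paste0("sp", seq_len(n_species))
    grid <- expand.grid(gene_id = sprintf("g%02d", seq_len(n_genes)),
                        species = sp, stringsAsFactors = FALSE)
    n <- nrow(grid)
    counts <- data.frame(grid,
                         dn = rpois(n, lambda), ds = rpois(n, lambda),
                         pn = rpois(n, lambda), ps = rpois(n, lambda))
    cm <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                     gene_class = rep(c("piRNA", "other"),
                                      length.out = n_genes))
    d <- mk_dataset(counts, cm)
    pooled <- mkodds:::pooled_by_param(d, model_full(sp))
    if (all(pooled$ns > 0) && all(pooled$s > 0)) return(d)
  }
}

# published selected-model modifier estimates, used as simulation truth
selected_truth <- function() {
  c(mel.div.piRNA = 3.543, ana.wil.div.piRNA = 1.306,
    mel.div.other = 1.209, ana.div.other = 0.692, wil.div.other = 0.516,
    poly.piRNA = 2.67,
    mel.poly.other = 1.100, ana.poly.other = 1.201, wil.poly.other = 1.128)
}

# simulation spec with the selected-model structure as truth
selected_truth_spec <- function(seed, n_pirna = 31L, n_other = 600L,
                                mean_div = 25, mean_poly = 30,
                                dispersion = 1.2) {
  model <- model_selected_preset(c("mel", "ana", "wil"))
  simulation_spec(species = c("mel", "ana", "wil"),
                  n_pirna = n_pirna, n_other = n_other,
                  alpha = 0.308, beta_model = model,
                  beta = selected_truth(),
                  mean_div = mean_div, mean_poly = mean_poly,
                  dispersion = dispersion, seed = seed)
}
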