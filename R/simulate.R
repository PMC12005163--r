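#' Specify a synthetic count-table simulation
#'
#' Defines the generative model for synthetic datasets with the structure the
#' likelihood assumes: for every gene x species x context observation a total
#' variant count \eqn{N} is drawn, then the nonsynonymous count
#' \eqn{NS \sim Binomial(N, \beta\alpha/(\beta\alpha + 1))} with the
#' \eqn{\beta} of the observation's cell.  Per-gene totals are negative
#' binomial by default: each gene carries a gamma-distributed intensity
#' shared across its species and contexts, which produces the heavy-tailed,
#' gene-correlated counts real variant tables show (and that the gene-wise
#' bootstrap exists to respect).  Defaults mirror the study conditions: 3
#' species, 31 piRNA genes (11 nuclear, 20 cytoplasmic) among 8,747
#' orthologs, baseline odds 0.308, beta = 1 everywhere.
#'
#' @param species species labels
#' @param n_pirna,n_other genes per class
#' @param n_nuclear number of piRNA genes labelled nuclear (the rest are
#'   cytoplasmic); \code{NULL} keeps the default 11:20 nuclear:cytoplasmic
#'   proportion; set to \code{NA} to omit compartment labels
#' @param alpha true baseline N:S odds
#' @param beta_model an \code{mk_model} naming the true-beta partition
#' @param beta named numeric vector of true modifiers, one per
#'   \code{beta_model} parameter
#' @param mean_div,mean_poly expected total variants per gene per species for
#'   divergence and polymorphism
#' @param dispersion negative binomial size parameter of the per-gene
#'   intensity (smaller = heavier tail); \code{Inf} gives Poisson counts
#' @param seed integer seed (required for reproducibility)
#' @return object of class \code{mk_simspec}
#' @export
simulation_spec <- function(species = c("mel", "ana", "wil"),
                            n_pirna = 31L, n_other = 8716L,
                            n_nuclear = NULL,
                            alpha = 0.308,
                            beta_model = model_single(),
                            beta = c(all = 1),
                            mean_div = 25, mean_poly = 30,
                            dispersion = 1.2,
                            seed = 1L) {
  stopifnot(inherits(beta_model, "mk_model"))
  if (length(beta) != length(beta_model$params))
    stop("beta must have one value per beta_model parameter")
  if (!is.null(names(beta))) {
    if (!setequal(names(beta), beta_model$params))
      stop("names of beta do not match beta_model's parameters")
    beta <- beta[beta_model$params]
  } else names(beta) <- beta_model$params
  if (any(beta <= 0)) stop("all true beta must be > 0")
  if (alpha <= 0) stop("alpha must be > 0")
  if (n_pirna < 1 || n_other < 1) stop("need at least one gene per class")
  if (is.null(n_nuclear)) n_nuclear <- as.integer(round(n_pirna * 11 / 31))
  if (!is.na(n_nuclear) && (n_nuclear < 0 || n_nuclear > n_pirna))
    stop("n_nuclear must be between 0 and n_pirna")
  if (mean_div < 0 || mean_poly < 0) stop("mean counts must be >= 0")
  structure(list(species = species, n_pirna = as.integer(n_pirna),
                 n_other = as.integer(n_other),
                 n_nuclear = if (is.na(n_nuclear)) NA_integer_
                 else as.integer(n_nuclear),
                 alpha = alpha, beta_model = beta_model, beta = beta,
                 mean_div = mean_div, mean_poly = mean_poly,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "mk_simspec")
}

#' Simulate a count dataset
#'
#' Draws a full \code{mk_dataset} from a \code{\link{simulation_spec}}.  The
#' per-cell empirical N:S odds converge to \eqn{\beta\alpha} as counts grow,
#' so fits on simulated data recover the true modifiers.  Deterministic given
#' the spec's seed; the caller's RNG state is left untouched.
#'
#' @param spec an \code{mk_simspec}
#' @return an \code{mk_dataset}
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "mk_simspec"))
  with_seed(spec$seed, simulate_dataset_impl(spec))
}

simulate_dataset_impl <- function(spec) {
  n_genes <- spec$n_pirna + spec$n_other
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  gene_class <- rep(c("piRNA", "other"), c(spec$n_pirna, spec$n_other))
  compartment <- rep(NA_character_, n_genes)
  if (!is.na(spec$n_nuclear) && spec$n_nuclear >= 0) {
    compartment[seq_len(spec$n_pirna)] <-
      rep(c("nuclear", "cytoplasmic"),
          c(spec$n_nuclear, spec$n_pirna - spec$n_nuclear))
  }
  class_map <- data.frame(gene_id = gene_id, gene_class = gene_class,
                          compartment = compartment)

  # gene intensity shared across species and contexts -> NB marginal counts
  g <- if (is.finite(spec$dispersion))
    stats::rgamma(n_genes, shape = spec$dispersion, rate = spec$dispersion)
  else rep(1, n_genes)

  grid <- expand.grid(gene = seq_len(n_genes), species = spec$species,
                      stringsAsFactors = FALSE)
  n_rows <- nrow(grid)
  cell <- function(ctx) data.frame(
    species = grid$species, context = ctx,
    gene_class = gene_class[grid$gene],
    compartment = compartment[grid$gene])
  b_div <- spec$beta[assign_params(spec$beta_model, cell("divergence"))]
  b_poly <- spec$beta[assign_params(spec$beta_model, cell("polymorphism"))]
  p_of <- function(b) b * spec$alpha / (b * spec$alpha + 1)

  n_div <- stats::rpois(n_rows, spec$mean_div * g[grid$gene])
  n_poly <- stats::rpois(n_rows, spec$mean_poly * g[grid$gene])
  dn <- stats::rbinom(n_rows, n_div, p_of(b_div))
  pn <- stats::rbinom(n_rows, n_poly, p_of(b_poly))

  counts <- data.frame(gene_id = gene_id[grid$gene], species = grid$species,
                       dn = dn, ds = n_div - dn, pn = pn, ps = n_poly - pn)
  mk_dataset(counts, class_map, species = spec$species)
}

#' Stream of null datasets for LRT calibration
#'
#' Generates independent datasets from the same spec (which should use a
#' single shared true beta across the cells a tested split would separate)
#' for type-I-error estimation.  Child seeds are derived deterministically
#' from the spec's seed, so the stream is reproducible and robust to changes
#' in the per-dataset gene count.
#'
#' @param spec an \code{mk_simspec}
#' @param n_datasets number of datasets
#' @return list of \code{mk_dataset}
#' @export
simulate_null_ladder_inputs <- function(spec, n_datasets) {
  stopifnot(inherits(spec, "mk_simspec"), n_datasets >= 1)
  seeds <- with_seed(spec$seed,
                     sample.int(.Machine$integer.max, n_datasets))
  lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- s
    simulate_dataset(sp)
  })
}

#' Deterministic dominant-gene scenario
#'
#' A fixed dataset illustrating how a single variant-rich gene dominates a
#' pooled odds estimate: one piRNA gene with 100 divergent variants (75
#' nonsynonymous), and 30 piRNA genes with 2 divergent variants each (1
#' nonsynonymous, 1 synonymous).  The pooled divergence odds of the class is
#' 105:55 even though 30 of 31 genes have odds 1.  A matched block of
#' background genes is included so the dataset is complete.
#'
#' @param n_other number of background genes (each with balanced counts)
#' @return an \code{mk_dataset}
#' @export
dataset_dominant_gene <- function(n_other = 100L) {
  pirna <- data.frame(
    gene_id = sprintf("pi%02d", 1:31), species = "mel",
    dn = c(75, rep(1, 30)), ds = c(25, rep(1, 30)),
    pn = 2L, ps = 2L)
  other <- data.frame(
    gene_id = sprintf("o%04d", seq_len(n_other)), species = "mel",
    dn = 2L, ds = 2L, pn = 2L, ps = 2L)
  counts <- rbind(pirna, other)
  cm <- data.frame(gene_id = counts$gene_id,
                   gene_class = rep(c("piRNA", "other"), c(31, n_other)))
  mk_dataset(counts, cm)
}
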