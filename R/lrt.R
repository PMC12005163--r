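#' Likelihood-ratio test between nested partition models
#'
#' Compares two fitted models of the same dataset: the statistic is
#' \eqn{2(\ell_{richer} - \ell_{nested})} and the p-value comes from the upper
#' tail of the \eqn{\chi^2} distribution with degrees of freedom equal to the
#' number of additional parameters.  Nesting is verified structurally: every
#' parameter class of the richer model must lie within one parameter class of
#' the nested model.  Flagged (unidentifiable/uninformative) parameters added
#' by the richer model are excluded from the degrees of freedom with a loud
#' warning.
#'
#' @param nested,richer \code{mk_fit} objects fitted to the same dataset with
#'   the same alpha
#' @return object of class \code{mk_lrt}: statistic, df, p_value and the two
#'   fits
#' @export
likelihood_ratio_test <- function(nested, richer) {
  stopifnot(inherits(nested, "mk_fit"), inherits(richer, "mk_fit"))
  if (!isTRUE(all.equal(nested$alpha, richer$alpha)))
    stop("fits use different baseline alpha values")

  cr <- richer$cells
  cn <- nested$cells
  key <- function(d) paste(d$species, d$context, d$gene_class, d$compartment)
  if (!setequal(key(cr), key(cn)))
    stop("fits cover different observation cells; refit on the same dataset")
  nested_par <- cn$param[match(key(cr), key(cn))]
  refines <- all(tapply(nested_par, cr$param,
                        function(p) length(unique(p)) == 1L))
  if (!refines)
    stop("model '", richer$model$name, "' does not refine model '",
         nested$model$name, "'")

  df <- richer$K - nested$K
  if (df < 1) stop("richer model adds no parameters (df = ", df, ")")
  bad_r <- sum(richer$flags != "ok")
  bad_n <- sum(nested$flags != "ok")
  drop <- max(bad_r - bad_n, 0L)
  if (drop > 0) {
    warning("richer model adds ", drop, " degenerate parameter(s) ",
            "(unidentifiable or uninformative); excluded from df")
    df <- df - drop
    if (df < 1) stop("no identifiable added parameters to test")
  }

  stat <- 2 * (richer$loglik - nested$loglik)
  if (stat < -1e-6)
    warning("negative LRT statistic (", format(stat), "); check fits")
  stat <- max(stat, 0)
  structure(list(nested_fit = nested, richer_fit = richer,
                 statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "mk_lrt")
}

#' @export
print.mk_lrt <- function(x, ...) {
  cat("LRT: '", x$nested_fit$model$name, "' (K=", x$nested_fit$K,
      ") vs '", x$richer_fit$model$name, "' (K=", x$richer_fit$K, ")\n",
      sep = "")
  cat("  statistic =", format(x$statistic, digits = 6), " df =", x$df,
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Stepwise model-selection ladder over explicit candidate tiers
#'
#' Starting from a baseline model, each tier's candidate models (all refining
#' the currently selected model) are fitted; the candidate with the highest
#' likelihood is tested against the current selection by LRT.  If the p-value
#' is below the threshold the candidate is adopted and the search continues
#' with the next tier, otherwise the ladder stops.  All fits and the per-tier
#' test are reported.  Ties in likelihood break lexicographically by model
#' name, so the procedure is deterministic.
#'
#' @param dataset an \code{mk_dataset}
#' @param tiers list of tiers, each a list of \code{mk_model} candidates
#' @param threshold adoption threshold on the LRT p-value (default 0.05)
#' @param start baseline \code{mk_model} (default the single-modifier model)
#' @param alpha baseline odds (default the dataset's)
#' @param method fitting method passed to \code{\link{fit_model}}
#' @return object of class \code{mk_ladder}: a \code{steps} data.frame (one
#'   row per fitted candidate with the tier's LRT on its best candidate), the
#'   \code{selected} fit and the threshold
#' @export
run_ladder <- function(dataset, tiers, threshold = 0.05,
                       start = model_single(), alpha = dataset$alpha,
                       method = "closed_form") {
  stopifnot(inherits(dataset, "mk_dataset"))
  if (!length(tiers)) stop("empty ladder: no candidate tiers")
  if (inherits(tiers[[1]], "mk_model")) tiers <- list(tiers)

  current <- fit_model(dataset, start, alpha = alpha, method = method)
  steps <- NULL
  for (ti in seq_along(tiers)) {
    cand <- tiers[[ti]]
    if (!length(cand)) stop("tier ", ti, " has no candidate models")
    fits <- lapply(cand, function(m)
      fit_model(dataset, m, alpha = alpha, method = method))
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    nms <- vapply(fits, function(f) f$model$name, character(1))
    best <- order(-lls, nms)[1]
    lrt <- likelihood_ratio_test(current, fits[[best]])
    adopt <- lrt$p_value < threshold
    steps <- rbind(steps, data.frame(
      tier = ti, model = nms, K = vapply(fits, `[[`, integer(1), "K"),
      loglik = lls, best = seq_along(fits) == best,
      statistic = ifelse(seq_along(fits) == best, lrt$statistic, NA_real_),
      df = ifelse(seq_along(fits) == best, lrt$df, NA_integer_),
      p_value = ifelse(seq_along(fits) == best, lrt$p_value, NA_real_),
      decision = ifelse(seq_along(fits) == best,
                        ifelse(adopt, "adopt", "stop"), "")))
    if (!adopt) break
    current <- fits[[best]]
  }
  structure(list(steps = steps, selected = current, threshold = threshold),
            class = "mk_ladder")
}

#' @export
print.mk_ladder <- function(x, digits = 4, ...) {
  cat("mk_ladder: selected model '", x$selected$model$name, "' (K=",
      x$selected$K, "), threshold ", x$threshold, "\n", sep = "")
  tab <- x$steps
  tab$loglik <- round(tab$loglik, 3)
  tab$statistic <- round(tab$statistic, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# model whose rules are one explicit rule per observation cell.
# compartment-specific rules are ordered first so "*" never shadows them.
cell_model <- function(name, cells) {
  rules <- cells[c("species", "context", "gene_class", "compartment", "param")]
  rules$compartment[is.na(rules$compartment)] <- "*"
  rules <- rules[order(rules$compartment == "*"), , drop = FALSE]
  mk_model(name, rules)
}

# all single-split (df = 1) refinements of a fitted cell partition:
# for each parameter class and dimension, peel one level off
refinement_candidates <- function(cells, dims) {
  out <- list()
  for (par in unique(cells$param)) {
    rows <- which(cells$param == par)
    for (d in dims) {
      v <- cells[[d]][rows]
      v[is.na(v)] <- ".na"
      levs <- unique(v)
      if (length(levs) < 2) next
      seen <- character(0)
      for (lv in levs) {
        split_sig <- paste(par, d, paste(v == lv, collapse = ""))
        # peeling lv vs its complement; for 2 levels both peels coincide
        comp_sig <- paste(par, d, paste(v != lv, collapse = ""))
        if (comp_sig %in% seen) next
        seen <- c(seen, split_sig)
        new_cells <- cells
        new_cells$param[rows][v == lv] <- paste(par, lv, sep = ".")
        nm <- paste0(par, "+", d, ":", lv)
        out[[nm]] <- cell_model(nm, new_cells)
      }
    }
  }
  out
}

#' Greedy stepwise refinement search
#'
#' Reconstruction of the nested single-split search: starting from a baseline
#' model, every candidate obtained by splitting one current parameter class
#' along one of the requested dimensions (peeling a single level, so each test
#' has df = 1) is fitted; the best candidate is adopted while its LRT against
#' the current model is significant.  Deterministic: likelihood ties break
#' lexicographically by candidate name.
#'
#' @inheritParams run_ladder
#' @param dims dimensions the search may split on, subset of
#'   \code{c("species", "context", "gene_class", "compartment")}
#' @param max_steps safety cap on adopted refinements
#' @return an \code{mk_ladder}
#' @export
select_model <- function(dataset, dims = c("species", "context"),
                         threshold = 0.05, start = model_single(),
                         alpha = dataset$alpha, max_steps = 30L) {
  stopifnot(inherits(dataset, "mk_dataset"))
  dims <- match.arg(dims, c("species", "context", "gene_class", "compartment"),
                    several.ok = TRUE)
  current <- fit_model(dataset, start, alpha = alpha)
  steps <- NULL
  for (step in seq_len(max_steps)) {
    cand <- refinement_candidates(current$cells, dims)
    if (!length(cand)) break
    lad <- run_ladder(dataset, list(cand), threshold = threshold,
                      start = current$model, alpha = alpha)
    st <- lad$steps
    st$tier <- step
    steps <- rbind(steps, st)
    if (!any(st$decision == "adopt")) break
    current <- lad$selected
  }
  structure(list(steps = steps, selected = current, threshold = threshold),
            class = "mk_ladder")
}
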