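#' Fitted N:S odds of a data cell
#'
#' Returns the fitted odds \eqn{\hat\beta \cdot \alpha} of the parameter a
#' fitted model assigns to the requested cell.  Errors if the matching cells
#' are split across several parameters (e.g. asking for a whole-class odds
#' under a compartment-split model) or if the parameter is degenerate.
#'
#' @param fit an \code{mk_fit}
#' @param species,context,gene_class,compartment cell selectors;
#'   \code{"*"} matches any level
#' @return positive scalar odds
#' @export
odds_from_fit <- function(fit, species, context, gene_class,
                          compartment = "*") {
  stopifnot(inherits(fit, "mk_fit"))
  cells <- fit$cells
  m <- rep(TRUE, nrow(cells))
  if (species != "*") m <- m & cells$species == species
  if (context != "*") m <- m & cells$context == context
  if (gene_class != "*") m <- m & cells$gene_class == gene_class
  if (compartment != "*")
    m <- m & !is.na(cells$compartment) & cells$compartment == compartment
  lab <- paste0("(", species, ", ", context, ", ", gene_class,
                if (compartment != "*") paste0(", ", compartment), ")")
  if (!any(m)) stop("no cell matches ", lab)
  pars <- unique(cells$param[m])
  if (length(pars) > 1)
    stop("cell ", lab, " spans several parameters (",
         paste(pars, collapse = ", "), "); odds not unique")
  if (fit$flags[[pars]] != "ok")
    stop("parameter '", pars, "' for cell ", lab, " is ",
         fit$flags[[pars]], "; odds unavailable")
  unname(fit$beta[[pars]] * fit$alpha)
}

#' The chi statistic: MK-style odds-ratio contrast against background
#'
#' For one species,
#' \deqn{\chi = \frac{Odds_{div,piRNA} / Odds_{poly,piRNA}}
#'                  {Odds_{div,other} / Odds_{poly,other}}}
#' i.e. the divergence-to-polymorphism N:S odds-ratio of the piRNA machinery
#' normalized by the same ratio for all other genes.  The baseline
#' \eqn{\alpha} cancels, so \eqn{\chi} depends only on the fitted modifiers.
#'
#' @param fit an \code{mk_fit} whose model distinguishes the four
#'   div/poly x piRNA/other odds for the species (directly or via shared
#'   parameters)
#' @param species species label
#' @return positive scalar
#' @export
chi_statistic <- function(fit, species) {
  (odds_from_fit(fit, species, "divergence", "piRNA") /
     odds_from_fit(fit, species, "polymorphism", "piRNA")) /
    (odds_from_fit(fit, species, "divergence", "other") /
       odds_from_fit(fit, species, "polymorphism", "other"))
}

#' The zeta statistic: divergence-only odds-ratio contrast
#'
#' For one species, \eqn{\zeta = Odds_{div,piRNA} / Odds_{div,other}}, the
#' N:S divergence odds of the piRNA machinery relative to all other genes.
#' With \code{compartment} set, the numerator is restricted to the nuclear or
#' cytoplasmic piRNA components.
#'
#' @inheritParams chi_statistic
#' @param compartment \code{"*"} (whole piRNA class), \code{"nuclear"} or
#'   \code{"cytoplasmic"}
#' @return positive scalar
#' @export
zeta_statistic <- function(fit, species, compartment = "*") {
  odds_from_fit(fit, species, "divergence", "piRNA", compartment) /
    odds_from_fit(fit, species, "divergence", "other")
}

#' chi and zeta directly from pooled counts
#'
#' Count-level counterparts of \code{\link{chi_statistic}} and
#' \code{\link{zeta_statistic}}: each odds is the pooled NS/S ratio of the
#' corresponding cell.  Under the full per-cell model the fit-based and
#' count-based routes coincide (the pooled ratio is the ML).
#'
#' @param dataset an \code{mk_dataset}
#' @param species species label
#' @return positive scalar
#' @export
chi_from_counts <- function(dataset, species) {
  po <- function(ctx, cls) {
    x <- pool_counts(dataset, species, ctx, cls)
    if (x["s"] == 0 || x["ns"] == 0)
      stop("pooled ", ctx, "/", cls, " odds degenerate for ", species)
    unname(x["ns"] / x["s"])
  }
  (po("divergence", "piRNA") / po("polymorphism", "piRNA")) /
    (po("divergence", "other") / po("polymorphism", "other"))
}

#' @rdname chi_from_counts
#' @export
zeta_from_counts <- function(dataset, species) {
  po <- function(cls) {
    x <- pool_counts(dataset, species, "divergence", cls)
    if (x["s"] == 0 || x["ns"] == 0)
      stop("pooled divergence/", cls, " odds degenerate for ", species)
    unname(x["ns"] / x["s"])
  }
  po("piRNA") / po("other")
}

#' Weighted inverse neutrality index 1/NI_TG
#'
#' The per-gene neutrality index is \eqn{NI = (P_n/P_s)/(D_n/D_s)}; its
#' count-weighted multi-gene average (Tarone--Greenland-style weighting, which
#' reduces the bias of summing sparse 2x2 tables) is
#' \deqn{NI_{TG} = \frac{\sum_i D_{s,i} P_{n,i} / (P_{s,i} + D_{s,i})}
#'                     {\sum_i D_{n,i} P_{s,i} / (P_{s,i} + D_{s,i})}}
#' Values of the reciprocal \eqn{1/NI_{TG} > 1} indicate an excess of
#' nonsynonymous divergence (positive selection).  Genes with
#' \eqn{P_s + D_s = 0} carry an undefined weight and are excluded (their
#' number is reported).  For a single gene with positive counts the index
#' reduces to the plain odds-ratio \eqn{(D_n P_s)/(D_s P_n)}.
#'
#' @param dataset an \code{mk_dataset}
#' @param species species label
#' @param gene_class \code{"piRNA"} or \code{"other"}
#' @return object of class \code{mk_nitg}: list with \code{label},
#'   \code{value} (the reciprocal index), \code{n_used}, \code{n_excluded}
#' @export
inverse_ni_tg <- function(dataset, species, gene_class) {
  stopifnot(inherits(dataset, "mk_dataset"))
  cn <- dataset$counts
  cn <- cn[cn$species == species & cn$gene_class == gene_class, , drop = FALSE]
  if (!nrow(cn)) stop("no genes for species ", species, ", class ", gene_class)
  w <- cn$ps + cn$ds
  keep <- w > 0
  n_excluded <- sum(!keep)
  cn <- cn[keep, , drop = FALSE]
  w <- w[keep]
  if (!nrow(cn))
    stop("all genes have Ps + Ds = 0; index undefined")
  num <- sum(cn$dn * cn$ps / w)   # numerator of 1/NI_TG
  den <- sum(cn$ds * cn$pn / w)
  if (den == 0)
    stop("weighted sum of Ds*Pn is zero; 1/NI_TG undefined")
  structure(list(label = paste(species, gene_class, sep = "/"),
                 value = num / den, n_used = nrow(cn),
                 n_excluded = n_excluded),
            class = "mk_nitg")
}

#' @export
print.mk_nitg <- function(x, ...) {
  cat("1/NI_TG [", x$label, "] = ", format(x$value, digits = 4),
      "  (", x$n_used, " genes used, ", x$n_excluded, " excluded)\n", sep = "")
  invisible(x)
}
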