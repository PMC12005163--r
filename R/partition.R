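#' Define a partition model
#'
#' A partition model assigns every observation cell — a combination of
#' species, context (divergence/polymorphism), gene class (piRNA/other) and,
#' for piRNA genes, optionally compartment (nuclear/cytoplasmic) — to one
#' modifier parameter \eqn{\beta}.  Rules are matched in order and the first
#' matching rule wins; \code{"*"} matches any level (including a missing
#' compartment).  Several rules may share a parameter name, which is how joint
#' parameters across species are expressed.
#'
#' @param name model name (used in reports and tie-breaking)
#' @param rules data.frame with columns \code{species}, \code{context},
#'   \code{gene_class}, \code{compartment} (values or \code{"*"}) and
#'   \code{param} (parameter name)
#' @return object of class \code{mk_model}
#' @examples
#' m <- mk_model("div_vs_poly", data.frame(
#'   species = "*", context = c("divergence", "polymorphism"),
#'   gene_class = "*", compartment = "*", param = c("div", "poly")))
#' @export
mk_model <- function(name, rules) {
  rules <- as.data.frame(rules)
  need <- c("species", "context", "gene_class", "compartment", "param")
  for (cc in setdiff(need, names(rules)))
    if (cc == "param") stop("rules need a `param` column") else rules[[cc]] <- "*"
  rules <- rules[need]
  for (cc in need) rules[[cc]] <- as.character(rules[[cc]])
  if (anyNA(rules$param) || any(rules$param == ""))
    stop("every rule needs a nonempty parameter name")
  structure(list(name = name, rules = rules,
                 params = unique(rules$param)),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("mk_model '", x$name, "': ", length(x$params), " parameter(s)\n", sep = "")
  print(x$rules, row.names = FALSE)
  invisible(x)
}

# match observation rows (or cells) to parameter indices; first rule wins.
# returns integer vector indexing into model$params; errors on unmatched rows.
assign_params <- function(model, obs) {
  stopifnot(inherits(model, "mk_model"))
  n <- nrow(obs)
  idx <- rep(NA_integer_, n)
  comp <- obs$compartment
  for (r in seq_len(nrow(model$rules))) {
    ru <- model$rules[r, ]
    m <- rep(TRUE, n)
    if (ru$species != "*") m <- m & obs$species == ru$species
    if (ru$context != "*") m <- m & obs$context == ru$context
    if (ru$gene_class != "*") m <- m & obs$gene_class == ru$gene_class
    if (ru$compartment != "*") m <- m & !is.na(comp) & comp == ru$compartment
    take <- m & is.na(idx)
    idx[take] <- match(ru$param, model$params)
  }
  if (anyNA(idx)) {
    bad <- obs[which(is.na(idx))[1], ]
    stop("model '", model$name, "' assigns no parameter to cell (",
         bad$species, ", ", bad$context, ", ", bad$gene_class,
         if (!is.na(bad$compartment)) paste0(", ", bad$compartment), ")")
  }
  idx
}

# unique observation cells of a dataset with their parameter assignment
model_cells <- function(model, dataset) {
  obs <- observations(dataset)
  cells <- unique(obs[c("species", "context", "gene_class", "compartment")])
  rownames(cells) <- NULL
  cells$param <- model$params[assign_params(model, cells)]
  cells
}

# TRUE if `richer` refines `nested` on the dataset's cells: every richer
# parameter class is contained in exactly one nested parameter class
model_refines <- function(richer, nested, dataset) {
  cr <- model_cells(richer, dataset)
  cn <- model_cells(nested, dataset)
  key <- paste(cr$species, cr$context, cr$gene_class, cr$compartment)
  keyn <- paste(cn$species, cn$context, cn$gene_class, cn$compartment)
  nested_par <- cn$param[match(key, keyn)]
  all(tapply(nested_par, cr$param, function(p) length(unique(p)) == 1L))
}

#' Preset partition models
#'
#' Constructors for the commonly used model family: a single modifier for the
#' whole dataset, per-species modifiers, per-species modifiers split by
#' context (divergence vs polymorphism), and the full species x context x
#' class grid (12 parameters for 3 species).  \code{model_by} is the generic
#' builder: it crosses the requested dimensions.
#'
#' @param dims character subset of \code{c("species", "context", "gene_class",
#'   "compartment")}; \code{"compartment"} implies \code{"gene_class"} and
#'   only splits the piRNA class.
#' @param species character vector of species labels
#' @param name optional model name
#' @return an \code{mk_model}
#' @export
model_by <- function(dims, species, name = NULL) {
  dims <- match.arg(dims, c("species", "context", "gene_class", "compartment"),
                    several.ok = TRUE)
  if ("compartment" %in% dims) dims <- union(dims, "gene_class")
  lev <- list(species = species,
              context = c("divergence", "polymorphism"),
              gene_class = c("piRNA", "other"))
  use <- lapply(c("species", "context", "gene_class"), function(d)
    if (d %in% dims) lev[[d]] else "*")
  names(use) <- c("species", "context", "gene_class")
  g <- expand.grid(species = use$species, context = use$context,
                   gene_class = use$gene_class, stringsAsFactors = FALSE)
  rules <- NULL
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    comp_levels <- if ("compartment" %in% dims &&
                       identical(row$gene_class, "piRNA"))
      c("nuclear", "cytoplasmic") else "*"
    for (cp in comp_levels) {
      parts <- c(row$species, row$context, row$gene_class, cp)
      lab <- paste(parts[parts != "*"], collapse = ".")
      if (lab == "") lab <- "all"
      rules <- rbind(rules, data.frame(species = row$species,
                                       context = row$context,
                                       gene_class = row$gene_class,
                                       compartment = cp, param = lab))
    }
  }
  if (is.null(name)) name <- if (length(dims)) paste(dims, collapse = "_") else "single"
  mk_model(name, rules)
}

#' @rdname model_by
#' @export
model_single <- function(name = "single") {
  mk_model(name, data.frame(species = "*", context = "*", gene_class = "*",
                            compartment = "*", param = "all"))
}

#' @rdname model_by
#' @export
model_species <- function(species) model_by("species", species, "species")

#' @rdname model_by
#' @export
model_species_context <- function(species)
  model_by(c("species", "context"), species, "species_context")

#' @rdname model_by
#' @export
model_full <- function(species)
  model_by(c("species", "context", "gene_class"), species, "full")

#' Preset: the published selected model structure
#'
#' The 8-parameter structure chosen by the stepwise search on the real data:
#' a distinct divergence modifier for the piRNA machinery of the first
#' species, a joint divergence modifier for the piRNA machinery of the
#' remaining species, per-species divergence modifiers for other genes, a
#' single polymorphism modifier shared by the piRNA machinery of all species,
#' and per-species polymorphism modifiers for other genes.
#'
#' @param species species labels; the first is the focal species that gets
#'   its own piRNA divergence parameter (e.g. \emph{D. melanogaster})
#' @return an \code{mk_model}
#' @export
model_selected_preset <- function(species) {
  stopifnot(length(species) >= 2)
  sp1 <- species[1]
  rest <- species[-1]
  rules <- rbind(
    data.frame(species = sp1, context = "divergence", gene_class = "piRNA",
               compartment = "*", param = paste0(sp1, ".div.piRNA")),
    data.frame(species = rest, context = "divergence", gene_class = "piRNA",
               compartment = "*",
               param = paste0(paste(rest, collapse = "."), ".div.piRNA")),
    data.frame(species = species, context = "divergence", gene_class = "other",
               compartment = "*", param = paste0(species, ".div.other")),
    data.frame(species = "*", context = "polymorphism", gene_class = "piRNA",
               compartment = "*", param = "poly.piRNA"),
    data.frame(species = species, context = "polymorphism",
               gene_class = "other", compartment = "*",
               param = paste0(species, ".poly.other")))
  mk_model("selected", rules)
}

#' Preset: divergence split by piRNA compartment
#'
#' Divergence-only model in which the piRNA machinery of a focal species is
#' split into nuclear and cytoplasmic components, a comparison species keeps a
#' single piRNA divergence modifier, and other genes get per-species
#' modifiers.  Polymorphism cells share per-species modifiers so the model
#' still covers the whole dataset.
#'
#' @param focal species whose piRNA machinery is split by compartment
#' @param others remaining species (single shared piRNA divergence modifier
#'   each)
#' @return an \code{mk_model}
#' @export
model_compartment_div <- function(focal, others) {
  species <- c(focal, others)
  rules <- rbind(
    data.frame(species = focal, context = "divergence", gene_class = "piRNA",
               compartment = c("nuclear", "cytoplasmic"),
               param = paste0(focal, ".div.piRNA.", c("nuc", "cyt"))),
    data.frame(species = others, context = "divergence", gene_class = "piRNA",
               compartment = "*", param = paste0(others, ".div.piRNA")),
    data.frame(species = species, context = "divergence", gene_class = "other",
               compartment = "*", param = paste0(species, ".div.other")),
    data.frame(species = species, context = "polymorphism", gene_class = "*",
               compartment = "*", param = paste0(species, ".poly")))
  mk_model("compartment_div", rules)
}
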