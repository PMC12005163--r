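#' Assemble a validated per-gene variant count dataset
#'
#' Bundles a long-format table of per-gene, per-species variant counts with a
#' gene-class map into the container used by all downstream fitting.  Each row
#' of \code{counts} holds the four McDonald--Kreitman cells for one gene in one
#' species: nonsynonymous divergence (\code{dn}), synonymous divergence
#' (\code{ds}), nonsynonymous polymorphism (\code{pn}) and synonymous
#' polymorphism (\code{ps}).  The global baseline N:S odds
#' \eqn{\alpha = (\sum D_n + \sum P_n) / (\sum D_s + \sum P_s)} is computed at
#' construction and carried with the dataset.
#'
#' @param counts data.frame with columns \code{gene_id}, \code{species},
#'   \code{dn}, \code{ds}, \code{pn}, \code{ps}; counts must be nonnegative
#'   integers and (gene_id, species) pairs unique.
#' @param class_map data.frame with columns \code{gene_id}, \code{gene_class}
#'   (\code{"piRNA"} or \code{"other"}) and optionally \code{compartment}
#'   (\code{"nuclear"} or \code{"cytoplasmic"}, piRNA genes only).
#' @param species optional character vector fixing species order; defaults to
#'   order of first appearance.
#' @return An object of class \code{mk_dataset}: a list with elements
#'   \code{counts} (with gene_class/compartment merged in), \code{class_map},
#'   \code{species} and \code{alpha}.
#' @examples
#' counts <- data.frame(gene_id = c("g1", "g2"), species = "mel",
#'                      dn = c(4, 0), ds = c(2, 0), pn = c(1, 0), ps = c(1, 0))
#' cm <- data.frame(gene_id = c("g1", "g2"), gene_class = c("piRNA", "other"))
#' d <- mk_dataset(counts, cm)
#' d$alpha  # (4 + 1) / (2 + 1)
#' @export
mk_dataset <- function(counts, class_map, species = NULL) {
  counts <- as.data.frame(counts)
  class_map <- as.data.frame(class_map)

  need <- c("gene_id", "species", "dn", "ds", "pn", "ps")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("gene_id", "gene_class") %in% names(class_map)))
    stop("class map must have columns gene_id and gene_class")
  if (!"compartment" %in% names(class_map)) class_map$compartment <- NA_character_

  counts$gene_id <- as.character(counts$gene_id)
  counts$species <- as.character(counts$species)
  class_map$gene_id <- as.character(class_map$gene_id)
  class_map$gene_class <- as.character(class_map$gene_class)
  class_map$compartment <- as.character(class_map$compartment)

  for (cc in c("dn", "ds", "pn", "ps")) {
    v <- counts[[cc]]
    if (!is.numeric(v) || anyNA(v))
      stop("column ", cc, " must be numeric with no missing values")
    bad <- which(v < 0 | v != floor(v))
    if (length(bad))
      stop("column ", cc, " has negative or non-integer values, e.g. row ",
           bad[1], " (gene ", counts$gene_id[bad[1]], ", species ",
           counts$species[bad[1]], ")")
    counts[[cc]] <- as.integer(v)
  }

  key <- paste(counts$gene_id, counts$species, sep = "\r")
  if (anyDuplicated(key)) {
    d1 <- key[duplicated(key)][1]
    stop("duplicate (gene_id, species) pair: ", gsub("\r", " / ", d1))
  }
  if (anyDuplicated(class_map$gene_id))
    stop("duplicate gene_id in class map")

  bad_class <- setdiff(unique(class_map$gene_class), c("piRNA", "other"))
  if (length(bad_class))
    stop("unknown gene_class label(s): ", paste(bad_class, collapse = ", "))
  has_comp <- !is.na(class_map$compartment)
  bad_comp <- setdiff(unique(class_map$compartment[has_comp]),
                      c("nuclear", "cytoplasmic"))
  if (length(bad_comp))
    stop("unknown compartment label(s): ", paste(bad_comp, collapse = ", "))
  if (any(has_comp & class_map$gene_class != "piRNA"))
    stop("compartment labels are only allowed for piRNA-class genes")

  unmapped <- setdiff(unique(counts$gene_id), class_map$gene_id)
  if (length(unmapped))
    stop(length(unmapped), " gene(s) in the count table have no class label, ",
         "e.g. ", unmapped[1])
  extra <- setdiff(class_map$gene_id, counts$gene_id)
  if (length(extra)) {
    warning(length(extra), " gene(s) in the class map are absent from the ",
            "count table and were ignored")
    class_map <- class_map[class_map$gene_id %in% counts$gene_id, , drop = FALSE]
  }

  if (is.null(species)) species <- unique(counts$species)
  else {
    unknown <- setdiff(counts$species, species)
    if (length(unknown))
      stop("species in counts not listed in `species`: ",
           paste(unknown, collapse = ", "))
  }

  # genes absent from some species are tolerated: upstream ortholog filtering
  # normally makes the table complete, so flag incompleteness but accept it
  n_per_gene <- table(counts$gene_id)
  if (length(unique(n_per_gene)) > 1L)
    warning("some genes are present in only a subset of species")

  i <- match(counts$gene_id, class_map$gene_id)
  counts$gene_class <- class_map$gene_class[i]
  counts$compartment <- class_map$compartment[i]
  rownames(counts) <- NULL

  x <- structure(list(counts = counts, class_map = class_map,
                      species = species, alpha = NA_real_),
                 class = "mk_dataset")
  x$alpha <- global_baseline_odds(x)
  x
}

#' Global baseline N:S odds
#'
#' The grand-total nonsynonymous:synonymous odds pooled over every gene, every
#' species and both contexts (divergence and polymorphism):
#' \eqn{(\sum D_n + \sum P_n)/(\sum D_s + \sum P_s)}.  This is the fixed
#' baseline that partition modifiers \eqn{\beta} scale; it is a count-weighted
#' aggregate, not an average of per-gene odds.
#'
#' @param dataset an \code{mk_dataset}
#' @return positive scalar
#' @export
global_baseline_odds <- function(dataset) {
  stopifnot(inherits(dataset, "mk_dataset"))
  cn <- dataset$counts
  num <- sum(cn$dn) + sum(cn$pn)
  den <- sum(cn$ds) + sum(cn$ps)
  if (den == 0)
    stop("baseline odds undefined: no synonymous variants in the dataset")
  num / den
}

#' Pool nonsynonymous and synonymous counts over a data cell
#'
#' Sums counts over all (gene, species, context) observations matching the
#' given cell selectors.  For context \code{"divergence"} the NS/S counts are
#' (dn, ds); for \code{"polymorphism"} they are (pn, ps).  \code{NULL} (or
#' \code{"*"}) selectors match everything; an empty selection pools to
#' \code{c(ns = 0, s = 0)}.
#'
#' @param dataset an \code{mk_dataset}
#' @param species,context,gene_class,compartment cell selectors (each a label,
#'   \code{"*"} or \code{NULL})
#' @return named numeric vector \code{c(ns = ..., s = ...)}
#' @export
pool_counts <- function(dataset, species = NULL, context = NULL,
                        gene_class = NULL, compartment = NULL) {
  stopifnot(inherits(dataset, "mk_dataset"))
  obs <- observations(dataset)
  keep <- rep(TRUE, nrow(obs))
  sel <- function(col, val) {
    if (is.null(val) || identical(val, "*")) rep(TRUE, nrow(obs))
    else !is.na(obs[[col]]) & obs[[col]] %in% val
  }
  keep <- sel("species", species) & sel("context", context) &
    sel("gene_class", gene_class) & sel("compartment", compartment)
  c(ns = sum(obs$ns[keep]), s = sum(obs$s[keep]))
}

#' Long observation table of a dataset
#'
#' Expands each count row into its two observations (divergence and
#' polymorphism), the unit over which the binomial likelihood is summed.
#'
#' @param dataset an \code{mk_dataset}
#' @return data.frame with columns gene_id, species, context, gene_class,
#'   compartment, ns, s, n
#' @export
observations <- function(dataset) {
  stopifnot(inherits(dataset, "mk_dataset"))
  cn <- dataset$counts
  base <- cn[c("gene_id", "species", "gene_class", "compartment")]
  div <- cbind(base, context = "divergence", ns = cn$dn, s = cn$ds)
  pol <- cbind(base, context = "polymorphism", ns = cn$pn, s = cn$ps)
  obs <- rbind(div, pol)
  obs$n <- obs$ns + obs$s
  rownames(obs) <- NULL
  obs[c("gene_id", "species", "context", "gene_class", "compartment",
        "ns", "s", "n")]
}

#' Read variant count tables
#'
#' Reads a tab-separated long-format variant count table (one row per gene and
#' species) and a gene class map, and returns a validated \code{mk_dataset}.
#' Column names can be remapped with \code{col_map} for tables using a
#' different header dialect.
#'
#' @param file path (or connection) to the TSV count table with columns
#'   gene_id, species, dn, ds, pn, ps (any order)
#' @param class_map_file path to the TSV class map with columns gene_id,
#'   gene_class and optional compartment
#' @param col_map optional named character vector mapping standard names to
#'   the file's column names, e.g. \code{c(gene_id = "FBgn", dn = "Dn")}
#' @param species optional fixed species ordering (see \code{\link{mk_dataset}})
#' @return an \code{mk_dataset}
#' @export
read_variant_table <- function(file, class_map_file, col_map = NULL,
                               species = NULL) {
  counts <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  cm <- utils::read.delim(class_map_file, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(counts)[names(counts) == col_map[[std]]] <- std
      names(cm)[names(cm) == col_map[[std]]] <- std
    }
  }
  mk_dataset(counts, cm, species = species)
}

#' Write a dataset back to TSV
#'
#' Echoes the validated count table (and optionally the class map) in the same
#' long TSV dialect read by \code{\link{read_variant_table}}; a read/write
#' round trip reproduces counts exactly.
#'
#' @param dataset an \code{mk_dataset}
#' @param file destination for the count table
#' @param class_map_file optional destination for the class map
#' @export
write_variant_table <- function(dataset, file, class_map_file = NULL) {
  stopifnot(inherits(dataset, "mk_dataset"))
  out <- dataset$counts[c("gene_id", "species", "dn", "ds", "pn", "ps")]
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(class_map_file))
    utils::write.table(dataset$class_map, class_map_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Summarize a dataset
#'
#' @param dataset an \code{mk_dataset}
#' @return list with gene counts per class, per-species pooled totals and the
#'   baseline odds alpha; serializes cleanly to JSON
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "mk_dataset"))
  cm <- dataset$class_map
  per_sp <- lapply(dataset$species, function(sp) {
    cn <- dataset$counts[dataset$counts$species == sp, , drop = FALSE]
    list(dn = sum(cn$dn), ds = sum(cn$ds), pn = sum(cn$pn), ps = sum(cn$ps))
  })
  names(per_sp) <- dataset$species
  list(n_genes = length(unique(cm$gene_id)),
       n_piRNA = sum(cm$gene_class == "piRNA"),
       n_other = sum(cm$gene_class == "other"),
       species = dataset$species,
       totals = per_sp,
       alpha = dataset$alpha)
}

#' @export
print.mk_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat("mk_dataset:", s$n_genes, "genes (", s$n_piRNA, "piRNA /", s$n_other,
      "other ) x", length(x$species), "species\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  baseline N:S odds alpha =", format(x$alpha, digits = 4), "\n")
  invisible(x)
}
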