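# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' One stratified gene-wise bootstrap resample
#'
#' Draws genes with replacement separately within each gene-class stratum
#' (piRNA and other), each drawn gene carrying all its rows — every species
#' and all four counts — jointly, so cross-species gene effects are
#' preserved.  Stratum sizes are conserved.  Resampled genes receive unique
#' synthetic ids (the original id with a draw suffix).  Uses R's global RNG;
#' seed it with \code{set.seed} for reproducibility.
#'
#' @param dataset an \code{mk_dataset}
#' @param linked_species if \code{FALSE}, genes are resampled independently
#'   within each species (stratified by class x species) instead of carrying
#'   all species jointly
#' @return an \code{mk_dataset} of the same shape
#' @export
resample_dataset <- function(dataset, linked_species = TRUE) {
  stopifnot(inherits(dataset, "mk_dataset"))
  cn <- dataset$counts
  cm <- dataset$class_map
  missing_cls <- setdiff(c("piRNA", "other"), unique(cm$gene_class))
  if (length(missing_cls))
    stop("empty stratum: ", paste(missing_cls, collapse = ", "))
  if (linked_species) {
    rows_by_gene <- split(seq_len(nrow(cn)), cn$gene_id)
    draw <- character(0)
    for (cls in unique(cm$gene_class)) {
      genes <- cm$gene_id[cm$gene_class == cls]
      if (!length(genes)) stop("empty stratum: ", cls)
      draw <- c(draw, sample(genes, length(genes), replace = TRUE))
    }
    new_ids <- paste0(draw, "_bs", seq_along(draw))
    blocks <- rows_by_gene[draw]
    lens <- lengths(blocks)
    new_counts <- cn[unlist(blocks, use.names = FALSE), , drop = FALSE]
    new_counts$gene_id <- rep(new_ids, lens)
    new_map <- cm[match(draw, cm$gene_id), , drop = FALSE]
    new_map$gene_id <- new_ids
  } else {
    stratum <- paste(cn$gene_class, cn$species)
    new_counts <- NULL
    new_map <- NULL
    ii <- 0L
    for (st in unique(stratum)) {
      rows <- which(stratum == st)
      draw <- sample(rows, length(rows), replace = TRUE)
      blk <- cn[draw, , drop = FALSE]
      ids <- paste0(blk$gene_id, "_bs", ii + seq_along(draw))
      ii <- ii + length(draw)
      mrow <- cm[match(blk$gene_id, cm$gene_id), , drop = FALSE]
      blk$gene_id <- ids
      mrow$gene_id <- ids
      new_counts <- rbind(new_counts, blk)
      new_map <- rbind(new_map, mrow)
    }
  }
  mk_dataset(new_counts[c("gene_id", "species", "dn", "ds", "pn", "ps")],
             new_map, species = dataset$species)
}

# gene-or-row level pooled-count matrices for fast bootstrap refitting:
# unit x K matrices of NS and S contributions per model parameter
boot_design <- function(dataset, model, linked_species = TRUE) {
  cn <- dataset$counts
  n <- nrow(cn)
  obs <- observations(dataset)
  idx <- assign_params(model, obs)    # first n rows divergence, then poly
  idx_div <- idx[seq_len(n)]
  idx_poly <- idx[n + seq_len(n)]
  K <- length(model$params)

  if (linked_species) {
    genes <- unique(cn$gene_id)
    u <- match(cn$gene_id, genes)
    cls <- dataset$class_map$gene_class[match(genes, dataset$class_map$gene_id)]
    strata <- split(seq_along(genes), cls)
  } else {
    u <- seq_len(n)
    strata <- split(seq_len(n), paste(cn$gene_class, cn$species))
  }
  n_units <- max(u)

  key <- c((u - 1L) * K + idx_div, (u - 1L) * K + idx_poly)
  scatter <- function(vals) {
    agg <- rowsum(vals, key)
    keys <- as.integer(rownames(agg))
    M <- matrix(0, n_units, K)
    M[cbind((keys - 1L) %/% K + 1L, (keys - 1L) %% K + 1L)] <- agg[, 1]
    M
  }
  list(M_ns = scatter(c(cn$dn, cn$pn)), M_s = scatter(c(cn$ds, cn$ps)),
       strata = strata, n_units = n_units, K = K)
}

# per-species parameter indices for the cells chi/zeta need; NA where the
# cell spans several parameters
stat_param_index <- function(model, dataset) {
  cells <- model_cells(model, dataset)
  one <- function(sp, ctx, cls) {
    p <- unique(cells$param[cells$species == sp & cells$context == ctx &
                              cells$gene_class == cls])
    if (length(p) == 1) match(p, model$params) else NA_integer_
  }
  sp <- dataset$species
  list(div_pi = vapply(sp, one, integer(1), ctx = "divergence", cls = "piRNA"),
       poly_pi = vapply(sp, one, integer(1), ctx = "polymorphism", cls = "piRNA"),
       div_o = vapply(sp, one, integer(1), ctx = "divergence", cls = "other"),
       poly_o = vapply(sp, one, integer(1), ctx = "polymorphism", cls = "other"))
}

#' Stratified gene-wise bootstrap of chi and zeta
#'
#' For each of \code{B} replicates, genes are resampled with replacement
#' within the piRNA and other strata (species linked by default), the model's
#' modifiers are refitted by the pooled-count ML on the resampled data (with
#' the baseline alpha recomputed per replicate), and the per-species
#' \eqn{\chi} and \eqn{\zeta} statistics are recorded.  Between-species
#' contrasts get one-sided sign-based p-values: the proportion of replicates
#' whose contrast has the opposite sign to (or equals zero against) the
#' observed contrast.  Deterministic given \code{seed}.
#'
#' @param dataset an \code{mk_dataset}
#' @param model an \code{mk_model}, or \code{"selected"}
#'   (\code{\link{model_selected_preset}}) or \code{"full"}
#'   (\code{\link{model_full}})
#' @param B number of replicates
#' @param seed integer seed
#' @param linked_species see \code{\link{resample_dataset}}
#' @param add_one if \code{TRUE}, apply a +1/(B+1) correction to the sign
#'   p-values (off by default)
#' @return object of class \code{mk_boot}: replicate matrices \code{chi} and
#'   \code{zeta} (B x species, \code{NA} for failed replicates), point
#'   estimates, a \code{contrasts} data.frame, \code{B}, \code{seed} and the
#'   model name
#' @export
bootstrap_statistics <- function(dataset, model = "selected", B = 10000L,
                                 seed = 1L, linked_species = TRUE,
                                 add_one = FALSE) {
  stopifnot(inherits(dataset, "mk_dataset"), B >= 1)
  missing_cls <- setdiff(c("piRNA", "other"),
                         unique(dataset$class_map$gene_class))
  if (length(missing_cls))
    stop("empty stratum: ", paste(missing_cls, collapse = ", "))
  if (is.character(model)) {
    model <- switch(match.arg(model, c("selected", "full")),
                    selected = model_selected_preset(dataset$species),
                    full = model_full(dataset$species))
  }
  des <- boot_design(dataset, model, linked_species)
  pix <- stat_param_index(model, dataset)
  sp <- dataset$species
  nsp <- length(sp)

  stat_from_odds <- function(odds) {
    chi <- (odds[pix$div_pi] / odds[pix$poly_pi]) /
      (odds[pix$div_o] / odds[pix$poly_o])
    zeta <- odds[pix$div_pi] / odds[pix$div_o]
    bad <- function(x) !is.finite(x) | x <= 0
    chi[bad(chi)] <- NA_real_
    zeta[bad(zeta)] <- NA_real_
    names(chi) <- sp
    names(zeta) <- sp
    list(chi = chi, zeta = zeta)
  }
  pooled_stats <- function(w) {
    ns <- as.vector(crossprod(des$M_ns, w))
    s <- as.vector(crossprod(des$M_s, w))
    stat_from_odds(ns / s)   # alpha cancels in both ratios
  }

  point <- pooled_stats(rep(1, des$n_units))
  chi_mat <- matrix(NA_real_, B, nsp, dimnames = list(NULL, sp))
  zeta_mat <- matrix(NA_real_, B, nsp, dimnames = list(NULL, sp))
  with_seed(seed, {
    for (b in seq_len(B)) {
      w <- numeric(des$n_units)
      for (st in des$strata) {
        draw <- st[sample.int(length(st), length(st), replace = TRUE)]
        tb <- tabulate(draw, nbins = des$n_units)
        w <- w + tb
      }
      rs <- pooled_stats(w)
      chi_mat[b, ] <- rs$chi
      zeta_mat[b, ] <- rs$zeta
    }
  })

  contrasts <- NULL
  if (nsp >= 2) {
    for (i in seq_len(nsp - 1)) for (j in seq(i + 1, nsp)) {
      for (statnm in c("chi", "zeta")) {
        pt <- point[[statnm]]
        mat <- if (statnm == "chi") chi_mat else zeta_mat
        obs_c <- pt[i] - pt[j]
        reps <- mat[, i] - mat[, j]
        pv <- if (is.na(obs_c) || obs_c == 0) NA_real_
        else sign_pvalue(reps, obs_c, add_one = add_one)
        contrasts <- rbind(contrasts, data.frame(
          species_1 = sp[i], species_2 = sp[j], statistic = statnm,
          observed = unname(obs_c), p_value = pv,
          n_valid = sum(!is.na(reps))))
      }
    }
  }

  structure(list(B = B, seed = seed, model = model$name,
                 species = sp,
                 point_chi = point$chi, point_zeta = point$zeta,
                 chi = chi_mat, zeta = zeta_mat,
                 n_failed_chi = colSums(is.na(chi_mat)),
                 n_failed_zeta = colSums(is.na(zeta_mat)),
                 contrasts = contrasts,
                 linked_species = linked_species),
            class = "mk_boot")
}

#' Sign-based bootstrap p-value
#'
#' The proportion of valid replicate contrasts whose direction opposes the
#' observed contrast; replicates exactly at zero are counted as opposing
#' (conservative).  One-sided, no continuity correction unless
#' \code{add_one}.
#'
#' @param replicate_contrasts numeric vector of replicate contrast values
#'   (\code{NA} = failed replicate, excluded)
#' @param observed_contrast nonzero observed contrast
#' @param add_one apply the +1/(B+1) correction
#' @return p-value in [0, 1]
#' @examples
#' sign_pvalue(c(1, -1, 1, 1), 0.5)  # 0.25
#' @export
sign_pvalue <- function(replicate_contrasts, observed_contrast,
                        add_one = FALSE) {
  if (length(observed_contrast) != 1 || is.na(observed_contrast) ||
      observed_contrast == 0)
    stop("observed contrast must be a single nonzero value")
  valid <- replicate_contrasts[!is.na(replicate_contrasts)]
  if (!length(valid)) stop("no valid replicates")
  opp <- sum(valid * sign(observed_contrast) <= 0)
  if (add_one) (opp + 1) / (length(valid) + 1) else opp / length(valid)
}

#' @export
print.mk_boot <- function(x, digits = 4, ...) {
  cat("mk_boot: model '", x$model, "', B = ", x$B, ", seed = ", x$seed,
      "\n", sep = "")
  est <- data.frame(species = x$species, chi = x$point_chi,
                    zeta = x$point_zeta,
                    chi_boot_mean = colMeans(x$chi, na.rm = TRUE),
                    zeta_boot_mean = colMeans(x$zeta, na.rm = TRUE))
  print(format(est, digits = digits), row.names = FALSE)
  cat("contrasts (sign p-values):\n")
  print(format(x$contrasts, digits = digits), row.names = FALSE)
  invisible(x)
}
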