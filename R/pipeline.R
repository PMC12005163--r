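#' Write a model-fit report
#'
#' Writes the per-parameter modifier estimates with their pooled counts as a
#' TSV table and, optionally, a JSON companion with the log-likelihood and
#' metadata.
#'
#' @param fit an \code{mk_fit}
#' @param file TSV destination
#' @param json_file optional JSON destination
#' @return the report data.frame, invisibly
#' @export
write_fit_report <- function(fit, file, json_file = NULL) {
  stopifnot(inherits(fit, "mk_fit"))
  tab <- fit$pooled
  tab$beta <- unname(fit$beta[tab$param])
  tab$odds <- tab$beta * fit$alpha
  tab$flag <- unname(fit$flags[tab$param])
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(list(model = fit$model$name, K = fit$K,
                              alpha = fit$alpha, loglik = fit$loglik,
                              method = fit$method, converged = fit$converged,
                              beta = as.list(fit$beta),
                              flags = as.list(fit$flags)),
                         json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(tab)
}

#' Write a ladder report
#'
#' Renders the stepwise-selection trace (model, K, log-likelihood, LRT
#' statistic, df, p, decision) as TSV and optionally JSON.
#'
#' @param ladder an \code{mk_ladder}
#' @param file TSV destination
#' @param json_file optional JSON destination
#' @export
write_ladder_report <- function(ladder, file, json_file = NULL) {
  stopifnot(inherits(ladder, "mk_ladder"))
  utils::write.table(ladder$steps, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(list(selected = ladder$selected$model$name,
                              K = ladder$selected$K,
                              loglik = ladder$selected$loglik,
                              threshold = ladder$threshold,
                              steps = ladder$steps),
                         json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(ladder$steps)
}

#' Run the full analysis pipeline
#'
#' Ties the stages together over one dataset: validation summary, stepwise
#' model selection of the species x context structure, class-contrast fit
#' (full per-cell model plus the preset selected structure), chi/zeta
#' statistics, the stratified gene-wise bootstrap with between-species sign
#' p-values, and 1/NI_TG per species and gene class.  Every artifact plus the
#' echoed configuration is written into \code{outdir}; reruns with the same
#' dataset and seed are identical.
#'
#' @param dataset an \code{mk_dataset}
#' @param outdir output directory (created if needed)
#' @param threshold LRT adoption threshold
#' @param boot_B,boot_seed bootstrap replicate count and seed
#' @param boot_model model for the bootstrap, see
#'   \code{\link{bootstrap_statistics}}
#' @return list of in-memory results (summary, ladder, fits, stats, boot,
#'   nitg), invisibly
#' @export
run_pipeline <- function(dataset, outdir, threshold = 0.05,
                         boot_B = 10000L, boot_seed = 1L,
                         boot_model = "selected") {
  stopifnot(inherits(dataset, "mk_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)

  config <- list(package = "mkodds",
                 version = as.character(utils::packageVersion("mkodds")),
                 threshold = threshold, boot_B = boot_B,
                 boot_seed = boot_seed,
                 boot_model = if (is.character(boot_model)) boot_model
                 else boot_model$name,
                 species = dataset$species)
  jsonlite::write_json(config, pth("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  summ <- dataset_summary(dataset)
  jsonlite::write_json(summ, pth("dataset_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  ladder <- select_model(dataset, dims = c("species", "context"),
                         threshold = threshold)
  write_ladder_report(ladder, pth("ladder.tsv"), pth("ladder.json"))

  fit_full <- fit_model(dataset, model_full(dataset$species))
  write_fit_report(fit_full, pth("fit_full.tsv"), pth("fit_full.json"))
  fit_sel <- fit_model(dataset, model_selected_preset(dataset$species))
  write_fit_report(fit_sel, pth("fit_selected.tsv"), pth("fit_selected.json"))

  stats_tab <- NULL
  for (sp in dataset$species) {
    for (nm in c("chi", "zeta")) {
      val <- tryCatch(
        if (nm == "chi") chi_statistic(fit_full, sp)
        else zeta_statistic(fit_full, sp),
        error = function(e) NA_real_)
      stats_tab <- rbind(stats_tab, data.frame(
        species = sp, statistic = nm, value = val, model = "full"))
    }
  }
  utils::write.table(stats_tab, pth("statistics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  boot <- bootstrap_statistics(dataset, model = boot_model, B = boot_B,
                               seed = boot_seed)
  jsonlite::write_json(list(B = boot$B, seed = boot$seed, model = boot$model,
                            point_chi = as.list(boot$point_chi),
                            point_zeta = as.list(boot$point_zeta),
                            contrasts = boot$contrasts),
                       pth("bootstrap.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(
    data.frame(replicate = seq_len(boot$B), boot$chi, boot$zeta,
               check.names = FALSE),
    pth("bootstrap_replicates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  nitg_tab <- NULL
  for (sp in dataset$species) for (cls in c("piRNA", "other")) {
    r <- tryCatch(inverse_ni_tg(dataset, sp, cls), error = function(e) NULL)
    if (!is.null(r))
      nitg_tab <- rbind(nitg_tab, data.frame(
        species = sp, gene_class = cls, inv_ni_tg = r$value,
        n_used = r$n_used, n_excluded = r$n_excluded))
  }
  utils::write.table(nitg_tab, pth("nitg.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(summary = summ, ladder = ladder, fit_full = fit_full,
                 fit_selected = fit_sel, statistics = stats_tab, boot = boot,
                 nitg = nitg_tab))
}
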