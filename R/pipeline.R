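#' Read a pipeline configuration file
#'
#' The configuration is YAML with two blocks: `inputs` (paths to the model,
#' expression matrix + metadata, evidence table, gene sets + p-values, and
#' the signature gene list) and `parameters` (numeric settings; unspecified
#' parameters fall back to the documented defaults), plus optional `stages`
#' toggles, a `seed` and an `output_dir`.
#'
#' Parameter defaults: Jaccard threshold 0.5, biomass floor 0.028, support
#' threshold 0.01, 1000 bootstrap repetitions of 10 genes, 3 folds, regulator
#' cap 5, TF eligibility at 15 signature targets.
#'
#' @param path YAML file path.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(jaccard_threshold = 0.5, biomass_min = 0.028,
                   support_threshold = 0.01, reps = 1000,
                   genes_per_rep = 10, folds = 3, regulator_cap = 5,
                   min_targets = 15, top_candidates = 9)
  cfg$parameters <- utils::modifyList(defaults, cfg$parameters %||% list())
  cfg$stages <- utils::modifyList(
    list(filter_sets = TRUE, flux = TRUE, regnet = TRUE, reprogram = TRUE),
    cfg$stages %||% list())
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "macrep_out"
  class(cfg) <- "pipeline_config"
  cfg
}

check_paths <- function(inputs, fields) {
  for (f in fields) {
    if (is.null(inputs[[f]]))
      stop("configuration is missing required input path: ", f)
    if (!file.exists(inputs[[f]]))
      stop("input file for '", f, "' not found: ", inputs[[f]])
  }
}

#' Run the full polarization analysis pipeline
#'
#' Executes, in order: gene-set redundancy filtering, flux-bound computation
#' and per-phenotype flux fitting with loop removal, regulatory-network
#' bootstrap and parsimony fitting, in-silico reprogramming and the subset
#' evaluation. All artifacts (selected sets, bounds, per-phenotype fluxes,
#' differential flux percentages, edge scores, activities, bootstrap table,
#' model, reprogramming report, subset table, run report) are written as
#' TSV/JSON under the configured output directory. Failures abort with the
#' failing stage named.
#'
#' @param config A [read_pipeline_config()] result (or a path to one).
#' @return A list of class `run_report` with per-stage summaries.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  par <- config$parameters
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config),
                 version = as.character(utils::packageVersion("macrep")),
                 stages = list())
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$stages[[name]] <<- c(res, list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    res
  }

  if (isTRUE(config$stages$filter_sets)) {
    stage("filter_sets", {
      check_paths(config$inputs, c("gene_sets", "pvalues"))
      coll <- read_gene_sets(config$inputs$gene_sets, config$inputs$pvalues)
      tab <- filter_gene_sets(coll, threshold = par$jaccard_threshold,
                              seed = config$seed)
      write.table(tab, file.path(out, "selected_sets.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(n_sets = nrow(tab), n_selected = sum(tab$selected),
           total_weight = sum(tab$weight[tab$selected]))
    })
  }

  check_paths(config$inputs, c("expression", "metadata"))
  expr <- read_expression(config$inputs$expression, config$inputs$metadata)
  zexpr <- z_transform(expr, collapse_technical = TRUE)
  phenos <- unique(zexpr$meta$phenotype)

  flux_fits <- NULL
  if (isTRUE(config$stages$flux)) {
    stage("flux", {
      check_paths(config$inputs, "model")
      model <- read_metabolic_model(config$inputs$model)
      bounds <- run_fva(model, biomass_min = par$biomass_min)
      write.table(bounds, file.path(out, "bounds.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      core <- config$inputs$core_reactions %||%
        model$reactions$id[!model$reactions$exchange &
                             model$reactions$id != model$biomass]
      targets <- build_targets(model, zexpr, bounds, core = unlist(core))
      flux_fits <- lapply(phenos, function(p) {
        ft <- fit_fluxes(model, targets, bounds, phenotype = p,
                         biomass_min = par$biomass_min,
                         support_threshold = par$support_threshold)
        write.table(
          data.frame(id = names(ft$fluxes), flux = unname(ft$fluxes),
                     in_support = names(ft$fluxes) %in% ft$support),
          file.path(out, paste0("flux_", p, ".tsv")), sep = "\t",
          quote = FALSE, row.names = FALSE)
        ft
      })
      names(flux_fits) <- phenos
      jsonlite::write_json(
        lapply(flux_fits, function(f) lapply(f$cuts, function(ct)
          list(reactions = ct$reactions, directions = ct$directions))),
        file.path(out, "cycle_cuts.json"), auto_unbox = TRUE, digits = NA)
      if (all(c("M1", "M2") %in% phenos)) {
        dfp <- differential_flux_percent(flux_fits$M1$fluxes,
                                         flux_fits$M2$fluxes)
        write.table(data.frame(id = names(dfp), diff_percent = unname(dfp)),
                    file.path(out, "diffflux.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      list(phenotypes = phenos,
           cuts = vapply(flux_fits, function(f) length(f$cuts), 0L),
           objectives = vapply(flux_fits, `[[`, 0, "objective"))
    })
  }

  model_fit <- NULL
  boot <- NULL
  if (isTRUE(config$stages$regnet)) {
    stage("regnet", {
      check_paths(config$inputs, c("evidence", "signature"))
      evidence <- read_evidence(config$inputs$evidence)
      signature <- readLines(config$inputs$signature)
      signature <- signature[nzchar(signature)]
      es <- compute_edge_scores(evidence)
      eligible <- filter_eligible_tfs(es, signature,
                                      min_targets = par$min_targets)
      act <- compute_activities(es, zexpr, tfs = eligible)
      write.table(
        data.frame(tf = rownames(es$scores),
                   as.data.frame(es$scores, check.names = FALSE)),
        file.path(out, "edge_scores.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      write.table(
        data.frame(tf = rownames(act$act),
                   as.data.frame(act$act, check.names = FALSE)),
        file.path(out, "activities.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      boot <- bootstrap_selection(signature, zexpr, es, act,
                                   reps = par$reps,
                                   genes_per_rep = par$genes_per_rep,
                                   folds = par$folds,
                                   regulator_cap = par$regulator_cap,
                                   seed = config$seed)
      write.table(boot, file.path(out, "bootstrap.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cand <- top_ranking_tfs(boot, n = par$top_candidates)
      model_fit <- fit_parsimony_model(cand, signature, zexpr, es, act,
                                        regulator_cap = par$regulator_cap,
                                        folds = par$folds,
                                        seed = config$seed)
      jsonlite::write_json(
        list(selected = model_fit$selected,
             beta0 = as.list(model_fit$beta0),
             beta = apply(model_fit$beta, 2, function(col)
               as.list(col[col != 0]), simplify = FALSE),
             cap_search = model_fit$cap_search),
        file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)
      list(eligible = length(eligible), candidates = cand,
           selected = model_fit$selected,
           cv_mae = mean(vapply(model_fit$cv, `[[`, 0, "heldout_mae")))
    })
  }

  if (isTRUE(config$stages$reprogram) && !is.null(model_fit)) {
    stage("reprogram", {
      from <- config$parameters$reprogram_from %||% "M2"
      to <- config$parameters$reprogram_to %||% "M1"
      rp <- reprogram(model_fit, from = from, to = to)
      write.table(rp$genes, file.path(out, "reprogram.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      subsets <- evaluate_subsets(model_fit, from = from, to = to)
      write.table(subsets, file.path(out, "subsets.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(from = from, to = to,
           switched_fraction = rp$switched_fraction,
           best_subset = subsets$subset[1])
    })
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (macrep", x$version, ")\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %6.2fs\n", nm, x$stages[[nm]]$seconds))
  }
  invisible(x)
}

#' Compare reprogramming predictions to a signed differential table
#'
#' Given a reprogramming result (source -> target) and a table assigning each
#' gene a differential-expression sign (+1 if up in the target phenotype
#' relative to the source, -1 otherwise), counts the genes whose predicted
#' reprogramming direction (sign of `prediction - mean_source`) matches the
#' table's sign. Genes absent from the table are excluded and reported
#' separately.
#'
#' @param reprogramming A [reprogram()] result.
#' @param de_table Data frame with columns `gene` and `sign` (+1/-1).
#' @return A list with `n_agree`, `n_evaluated`, `fraction`, `n_missing`.
#' @export
compare_to_signature <- function(reprogramming, de_table) {
  stopifnot(inherits(reprogramming, "reprogramming_result"))
  if (!all(c("gene", "sign") %in% names(de_table)))
    stop("de_table needs columns gene, sign")
  tab <- reprogramming$genes
  idx <- match(tab$gene, de_table$gene)
  missing <- is.na(idx)
  tab <- tab[!missing, , drop = FALSE]
  signs <- de_table$sign[idx[!missing]]
  pred_dir <- sign(tab$prediction - tab$mean_source)
  agree <- pred_dir == signs
  list(n_agree = sum(agree), n_evaluated = nrow(tab),
       fraction = if (nrow(tab)) mean(agree) else NA_real_,
       n_missing = sum(missing))
}
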