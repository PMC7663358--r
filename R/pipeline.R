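# End-to-end orchestration: preprocess -> differential -> concordance ->
# module activation -> MFA constraints -> production scoring -> evaluation ->
# shuffled-gene control, with every stage writing a plain-text artifact.

#' Build and validate a pipeline configuration
#'
#' @param network path to the network JSON.
#' @param genes named character vector of per-condition raw gene table paths
#'   (TSV with group sidecars, see [write_sample_table()]).
#' @param metabolites named character vector of per-condition raw metabolite
#'   table paths; names must match \code{genes}.
#' @param modules path to the module/pathway GMT file.
#' @param fluxes optional path to the MFA flux TSV; \code{NULL} skips the
#'   constraint stage.
#' @param anchor_reaction,anchor_absolute anchor used to absolutize relative
#'   fluxes (required when \code{fluxes} is given).
#' @param q_threshold FDR significance threshold used throughout.
#' @param n_draws permutation draws for module activation.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param outdir output directory for stage artifacts.
#' @param timbr a [timbr_config()].
#' @param mfa_k half-width (in sd) of MFA bound intervals.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(network, genes, metabolites, modules,
                            fluxes = NULL, anchor_reaction = NULL,
                            anchor_absolute = NULL, q_threshold = 0.1,
                            n_draws = 10000L, seed = 1L, outdir,
                            timbr = timbr_config(), mfa_k = 2) {
  stopifnot(length(genes) >= 1, length(genes) == length(metabolites),
            q_threshold > 0)
  if (is.null(names(genes)) || is.null(names(metabolites)) ||
      !identical(names(genes), names(metabolites)))
    stop("genes and metabolites must be named by the same conditions")
  cfg <- structure(list(network = network, genes = genes,
                        metabolites = metabolites, modules = modules,
                        fluxes = fluxes, anchor_reaction = anchor_reaction,
                        anchor_absolute = anchor_absolute,
                        q_threshold = q_threshold,
                        n_draws = as.integer(n_draws), seed = as.integer(seed),
                        outdir = outdir, timbr = timbr, mfa_k = mfa_k),
                   class = "pipeline_config")
  missing_files <- c(network, genes, metabolites, modules, fluxes)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files))
    stop("configured input file(s) not found: ",
         paste(missing_files, collapse = ", "))
  if (!is.null(fluxes) &&
      (is.null(anchor_reaction) || is.null(anchor_absolute)))
    stop("anchor_reaction and anchor_absolute are required with fluxes")
  cfg
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: per-condition preprocessing and differential statistics for genes
#' (log2) and metabolites (natural log); cross-condition Pearson correlation
#' (all-features and significant-only) and average-linkage clustering of gene
#' fold-change profiles; AFC pathway scores and AAFC module activation;
#' conversion and application of MFA flux constraints; TIMBR production
#' scoring per condition; evaluation against the observed metabolite changes;
#' and the shuffled-gene control. Every artifact is written under
#' \code{config$outdir}; the run is fully deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @return list of class \code{run_report}: \code{manifest} (stage -> file),
#'   per-condition tables, the correlation matrices, the evaluation report
#'   pairs, and the config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, paste0(...))
  manifest <- character()
  conds <- names(config$genes)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  net <- stage("read_network", read_network(config$network))
  modules <- stage("read_modules", read_gene_sets(config$modules))

  gene_diff <- list()
  met_diff <- list()
  for (cn in conds) {
    gene_diff[[cn]] <- stage(paste0("differential_genes_", cn), {
      tab <- preprocess(read_sample_table(config$genes[[cn]]), log_base = "2")
      differential(tab, config$q_threshold)
    })
    met_diff[[cn]] <- stage(paste0("differential_metabolites_", cn), {
      tab <- preprocess(read_sample_table(config$metabolites[[cn]]),
                        log_base = "e")
      differential(tab, config$q_threshold)
    })
    manifest[paste0("gene_differential_", cn)] <-
      write_tsv(gene_diff[[cn]], out("gene_differential_", cn, ".tsv"))
    manifest[paste0("metabolite_differential_", cn)] <-
      write_tsv(met_diff[[cn]], out("metabolite_differential_", cn, ".tsv"))
  }

  cor_all <- cor_sig <- tree <- NULL
  if (length(conds) >= 2) {
    cor_all <- stage("correlation", correlation_matrix(gene_diff, "all"))
    cor_sig <- tryCatch(
      correlation_matrix(gene_diff, "significant", config$q_threshold),
      error = function(e) NULL)
    manifest["correlation_all"] <- write_tsv(
      data.frame(condition = rownames(cor_all), cor_all, check.names = FALSE),
      out("correlation_all.tsv"))
    if (!is.null(cor_sig))
      manifest["correlation_significant"] <- write_tsv(
        data.frame(condition = rownames(cor_sig), cor_sig,
                   check.names = FALSE),
        out("correlation_significant.tsv"))
    common <- Reduce(intersect, lapply(gene_diff, `[[`, "feature"))
    profiles <- do.call(rbind, lapply(gene_diff, function(d)
      d$log_fc[match(common, d$feature)]))
    rownames(profiles) <- conds
    tree <- stage("clustering", hier_cluster(profiles))
    manifest["cluster_tree"] <- out("cluster_tree.nwk")
    ape::write.tree(ape::as.phylo(tree), manifest["cluster_tree"])
  }

  afc <- aafc <- list()
  for (i in seq_along(conds)) {
    cn <- conds[i]
    afc[[cn]] <- stage(paste0("afc_", cn),
      afc_pathway_scores(gene_diff[[cn]], modules, n_draws = config$n_draws,
                         seed = config$seed + 100L * i))
    aafc[[cn]] <- stage(paste0("aafc_", cn),
      activate_modules(gene_diff[[cn]], modules,
                       q_threshold = config$q_threshold,
                       n_draws = config$n_draws,
                       seed = config$seed + 100L * i + 50L))
    manifest[paste0("afc_", cn)] <- write_tsv(afc[[cn]], out("afc_", cn, ".tsv"))
    manifest[paste0("aafc_", cn)] <- write_tsv(aafc[[cn]],
                                               out("aafc_", cn, ".tsv"))
  }

  net_used <- net
  if (!is.null(config$fluxes)) {
    cs <- stage("mfa_constraints", {
      est <- read_flux_estimates(config$fluxes)
      est <- relative_to_absolute(est, config$anchor_reaction,
                                  config$anchor_absolute)
      constraints_from_mfa(est, net, k = config$mfa_k)
    })
    manifest["mfa_constraints"] <- write_tsv(as.data.frame(cs),
                                             out("mfa_constraints.tsv"))
    net_used <- stage("mfa_constraints", apply_constraints(net, cs))
  }

  production <- list()
  evaluation <- list()
  for (i in seq_along(conds)) {
    cn <- conds[i]
    gene_fc <- stats::setNames(gene_diff[[cn]]$log_fc,
                               gene_diff[[cn]]$feature)
    production[[cn]] <- stage(paste0("timbr_", cn),
      production_scores(net_used, gene_fc, config = config$timbr))
    manifest[paste0("production_", cn)] <-
      write_tsv(production[[cn]], out("production_", cn, ".tsv"))
    real <- stage(paste0("evaluate_", cn),
      evaluate_predictions(production[[cn]], met_diff[[cn]],
                           q_threshold = config$q_threshold))
    rand <- stage(paste0("randomized_", cn),
      randomized_control(net_used, gene_fc, observed = met_diff[[cn]],
                         seed = config$seed + 7000L + i,
                         q_threshold = config$q_threshold,
                         config = config$timbr))
    evaluation[[cn]] <- list(real = real, randomized = rand)
    jsonlite::write_json(
      list(real = unclass(real[c("n_scored", "n_observed_significant",
                                 "n_correct", "fraction_correct", "mode")]),
           randomized = unclass(rand[c("n_scored", "n_observed_significant",
                                       "n_correct", "fraction_correct",
                                       "mode", "seed")])),
      out("evaluation_", cn, ".json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    manifest[paste0("evaluation_", cn)] <- out("evaluation_", cn, ".json")
  }

  report <- structure(list(manifest = manifest, gene_diff = gene_diff,
                           met_diff = met_diff, correlation_all = cor_all,
                           correlation_significant = cor_sig, tree = tree,
                           afc = afc, aafc = aafc, production = production,
                           evaluation = evaluation,
                           config = config),
                      class = "run_report")
  jsonlite::write_json(
    list(seed = config$seed, q_threshold = config$q_threshold,
         n_draws = config$n_draws,
         timbr = unclass(config$timbr), mfa_k = config$mfa_k,
         inputs = list(network = config$network,
                       genes = as.list(config$genes),
                       metabolites = as.list(config$metabolites),
                       modules = config$modules,
                       fluxes = config$fluxes),
         manifest = as.list(manifest)),
    out("run_report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$manifest["run_report"] <- out("run_report.json")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", length(x$manifest), "artifacts in",
      x$config$outdir, "\n")
  for (cn in names(x$evaluation)) {
    ev <- x$evaluation[[cn]]
    cat(sprintf("  %s: real %.2f vs randomized %.2f fraction correct\n",
                cn, ev$real$fraction_correct,
                ev$randomized$fraction_correct))
  }
  invisible(x)
}
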