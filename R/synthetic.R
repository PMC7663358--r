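# Synthetic study generator: toy metabolic networks and omics/flux datasets
# with known ground truth, shaped like a two-group acute-exposure rodent
# study (control and treated, 8 animals per group, hundreds of genes, tens of
# plasma metabolites, central-carbon flux estimates reported relative to a
# reference reaction fixed at 100).

#' Define a synthetic study scenario
#'
#' The defaults describe the strong-signal benchmark condition: designed
#' log-scale effect size 2 on the genes of perturbed pathways and on their
#' terminal plasma metabolites, residual noise sd 0.25, 8 samples per group,
#' 5% values missing completely at random, and 4 of 12 pathways perturbed
#' (two up, two down).
#'
#' @param n_pathways number of linear pathways in the toy network.
#' @param reactions_per_pathway chain length of each pathway (>= 2).
#' @param genes_per_reaction genes available per reaction GPR.
#' @param perturbations data.frame with columns \code{subsystem}
#'   (\code{"pathway_<i>"}), \code{direction} ("up"/"down"),
#'   \code{effect_size} (log-scale shift, >= 0). \code{NULL} means the default
#'   4-pathway design; use a 0-row data.frame for a null scenario.
#' @param noise_sd residual log-scale noise sd (> 0).
#' @param n_per_group samples per group (>= 3).
#' @param missing_rate fraction of cells missing completely at random,
#'   in [0, 0.3].
#' @param effect_size default effect size used when \code{perturbations} is
#'   built automatically.
#' @param seed integer seed governing every random choice downstream.
#' @return list of class \code{synthetic_scenario}.
#' @export
synthetic_scenario <- function(n_pathways = 12, reactions_per_pathway = 5,
                               genes_per_reaction = 3, perturbations = NULL,
                               noise_sd = 0.25, n_per_group = 8,
                               missing_rate = 0.05, effect_size = 2,
                               seed = 1L) {
  stopifnot(n_pathways >= 1, reactions_per_pathway >= 2,
            genes_per_reaction >= 1, noise_sd > 0, n_per_group >= 3,
            missing_rate >= 0, missing_rate <= 0.3, effect_size >= 0)
  if (is.null(perturbations)) {
    k <- min(4, n_pathways)
    perturbations <- data.frame(
      subsystem = paste0("pathway_", seq_len(k)),
      direction = rep(c("up", "down"), length.out = k),
      effect_size = effect_size,
      stringsAsFactors = FALSE)
  }
  if (nrow(perturbations) > 0) {
    stopifnot(all(c("subsystem", "direction", "effect_size") %in%
                    names(perturbations)),
              all(perturbations$direction %in% c("up", "down")),
              all(perturbations$effect_size >= 0))
  }
  structure(list(n_pathways = n_pathways,
                 reactions_per_pathway = reactions_per_pathway,
                 genes_per_reaction = genes_per_reaction,
                 perturbations = perturbations, noise_sd = noise_sd,
                 n_per_group = n_per_group, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Build a toy metabolic network with ground-truth annotations
#'
#' Constructs \code{n_pathways} linear routes from a shared uptake reaction to
#' distinct extracellular products. Every reaction carries a GPR over fresh
#' gene ids, mixing single genes, AND pairs and OR groups; each pathway also
#' gets one parallel alternative for a middle step so that flux routing is
#' exercised. Deterministic given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with \code{network} (a \code{metabolic_network}) and
#'   \code{truth} (skeleton: pathway -> product, gene -> pathway, anchor
#'   reaction id).
#' @export
make_toy_network <- function(scenario) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(scenario$seed)
  np <- scenario$n_pathways
  k <- scenario$reactions_per_pathway
  gpr_forms <- c("single", "and", "or")

  mets <- data.frame(id = "sub_c", name = "shared substrate",
                     compartment = "c", extracellular = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = "UPT", lower_bound = 0, upper_bound = 10,
                     gpr = "", subsystem = "uptake",
                     stringsAsFactors = FALSE)
  stoich <- list(UPT = c(sub_c = 1))
  gene_counter <- 0L
  gene_pathway <- character()
  product_of <- character()

  new_gpr <- function(ng) {
    ids <- paste0("g", gene_counter + seq_len(ng))
    gene_counter <<- gene_counter + ng
    form <- if (ng == 1) "single" else sample(gpr_forms[-1], 1)
    rule <- switch(form,
      single = ids[1],
      and = paste(ids, collapse = " and "),
      or = paste(ids, collapse = " or "))
    list(rule = rule, genes = ids)
  }

  for (p in seq_len(np)) {
    sys <- paste0("pathway_", p)
    chain_mets <- c("sub_c",
                    if (k > 1) paste0("m_", p, "_", seq_len(k - 1)),
                    paste0("prod_", p, "_e"))
    for (s in seq_len(k - 1)) {
      mets <- rbind(mets, data.frame(id = paste0("m_", p, "_", s),
                                     name = paste0("intermediate ", p, ".", s),
                                     compartment = "c", extracellular = FALSE,
                                     stringsAsFactors = FALSE))
    }
    mets <- rbind(mets, data.frame(id = paste0("prod_", p, "_e"),
                                   name = paste0("product ", p),
                                   compartment = "e", extracellular = TRUE,
                                   stringsAsFactors = FALSE))
    for (s in seq_len(k)) {
      g <- new_gpr(sample(seq_len(scenario$genes_per_reaction), 1))
      rid <- paste0("r_", p, "_", s)
      rxns <- rbind(rxns, data.frame(id = rid, lower_bound = 0,
                                     upper_bound = 10, gpr = g$rule,
                                     subsystem = sys, stringsAsFactors = FALSE))
      stoich[[rid]] <- stats::setNames(c(-1, 1),
                                       c(chain_mets[s], chain_mets[s + 1]))
      gene_pathway[g$genes] <- sys
    }
    # parallel alternative for a middle step: same stoichiometry, own genes
    alt_step <- if (k >= 3) sample(2:(k - 1), 1) else 1L
    g <- new_gpr(sample(seq_len(scenario$genes_per_reaction), 1))
    aid <- paste0("r_", p, "_", alt_step, "alt")
    rxns <- rbind(rxns, data.frame(id = aid, lower_bound = 0,
                                   upper_bound = 10, gpr = g$rule,
                                   subsystem = sys, stringsAsFactors = FALSE))
    stoich[[aid]] <- stats::setNames(c(-1, 1),
                                     c(chain_mets[alt_step],
                                       chain_mets[alt_step + 1]))
    gene_pathway[g$genes] <- sys
    product_of[sys] <- paste0("prod_", p, "_e")
    # secretion exchange so the product can leave the system at steady state
    # even when another metabolite's demand is being scored
    eid <- paste0("EX_prod_", p)
    rxns <- rbind(rxns, data.frame(id = eid, lower_bound = 0,
                                   upper_bound = 10, gpr = "",
                                   subsystem = "exchange",
                                   stringsAsFactors = FALSE))
    stoich[[eid]] <- stats::setNames(-1, paste0("prod_", p, "_e"))
  }
  net <- metabolic_network(mets, rxns, stoich)
  list(network = net,
       truth = list(product_of = product_of, gene_pathway = gene_pathway,
                    anchor_reaction = "UPT"))
}

#' Simulate two-group gene and metabolite abundance tables
#'
#' Gene abundances are log-normal: the control log2-mean of each gene is drawn
#' from Normal(5, 1); genes on a perturbed pathway are shifted by the designed
#' effect in the treated group; per-sample noise has the scenario sd. The
#' terminal metabolite of each perturbed pathway is shifted in the designed
#' direction on the natural-log scale. Cells go missing completely at random
#' at the scenario rate (never an entire feature). The completed truth maps
#' each gene to its designed log2 effect, each perturbed product to its
#' expected direction, and each pathway to an active/inactive flag; the
#' per-pathway gene sets double as injury-module definitions.
#'
#' @param network,truth output of [make_toy_network()].
#' @param scenario the generating [synthetic_scenario()].
#' @return list with \code{genes} and \code{metabolites} (raw-scale
#'   \code{sample_table}s), \code{modules} (per-pathway gene sets), and the
#'   completed \code{truth}.
#' @export
simulate_omics <- function(network, truth, scenario) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(scenario$seed + 1L)
  n <- scenario$n_per_group
  samples <- c(paste0("ctrl_", seq_len(n)), paste0("trt_", seq_len(n)))
  group <- stats::setNames(rep(c("control", "treated"), each = n), samples)

  pert <- scenario$perturbations
  gene_effect <- stats::setNames(rep(0, length(truth$gene_pathway)),
                                 names(truth$gene_pathway))
  met_dir <- character()
  if (nrow(pert) > 0) {
    for (i in seq_len(nrow(pert))) {
      sys <- pert$subsystem[i]
      sgn <- if (pert$direction[i] == "up") 1 else -1
      gene_effect[names(truth$gene_pathway)[truth$gene_pathway == sys]] <-
        sgn * pert$effect_size[i]
      met_dir[truth$product_of[[sys]]] <- pert$direction[i]
    }
  }

  genes <- names(gene_effect)
  mu_g <- stats::rnorm(length(genes), 5, 1)
  gvals <- matrix(NA_real_, length(genes), 2 * n,
                  dimnames = list(genes, samples))
  for (i in seq_along(genes)) {
    gvals[i, ] <- 2^(stats::rnorm(2 * n, mu_g[i], scenario$noise_sd) +
                       c(rep(0, n), rep(gene_effect[i], n)))
  }

  products <- unname(truth$product_of)
  mu_m <- stats::rnorm(length(products), 5, 1)
  met_effect <- stats::setNames(rep(0, length(products)), products)
  if (length(met_dir) > 0) {
    sgn <- ifelse(met_dir == "up", 1, -1)
    eff <- pert$effect_size[match(names(truth$product_of)[
      match(names(met_dir), truth$product_of)], pert$subsystem)]
    met_effect[names(met_dir)] <- sgn * eff
  }
  mvals <- matrix(NA_real_, length(products), 2 * n,
                  dimnames = list(products, samples))
  for (i in seq_along(products)) {
    mvals[i, ] <- exp(stats::rnorm(2 * n, mu_m[i], scenario$noise_sd) +
                        c(rep(0, n), rep(met_effect[i], n)))
  }

  if (scenario$missing_rate > 0) {
    gvals <- punch_missing(gvals, scenario$missing_rate)
    mvals <- punch_missing(mvals, scenario$missing_rate)
  }

  modules <- lapply(unique(truth$gene_pathway), function(sys) {
    list(name = sys, description = paste("genes of", sys),
         genes = names(truth$gene_pathway)[truth$gene_pathway == sys])
  })
  modules <- stats::setNames(modules,
                             vapply(modules, `[[`, "", "name"))
  active <- stats::setNames(
    unique(truth$gene_pathway) %in% pert$subsystem,
    unique(truth$gene_pathway))

  truth$gene_effect <- gene_effect
  truth$metabolite_direction <- met_dir
  truth$module_active <- active
  list(genes = sample_table(gvals, group),
       metabolites = sample_table(mvals, group),
       modules = modules, truth = truth)
}

# MCAR missingness that never blanks out an entire feature row
punch_missing <- function(m, rate) {
  mask <- matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m))
  full <- rowSums(!mask) == 0
  mask[full, 1] <- FALSE
  m[mask] <- NA_real_
  m
}

#' Simulate MFA-style relative flux estimates
#'
#' Samples one feasible steady-state flux vector by maximizing a randomly
#' weighted combination of product demands, rescales it so the anchor
#' reaction reads exactly 100 (the reference-reaction convention), and
#' attaches relative standard deviations of 5-15%. Reactions carrying no flux
#' in the sampled state are not reported, mirroring a measured subset.
#'
#' @param network,truth output of [make_toy_network()].
#' @param scenario the generating [synthetic_scenario()].
#' @return data.frame with columns \code{reaction}, \code{relative_value},
#'   \code{sd_relative}; attribute \code{flux_vector} carries the exact
#'   pre-noise steady-state vector (named, full network).
#' @export
simulate_fluxes <- function(network, truth, scenario) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(scenario$seed + 2L)
  net <- network
  S <- stoich_matrix(net)
  lb <- pmax(net$reactions$lower_bound, -LP_INF)
  ub <- pmin(net$reactions$upper_bound, LP_INF)
  obj <- stats::runif(ncol(S), 0.5, 1.5) *
    as.numeric(net$reactions$subsystem == "exchange")
  sol <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
  if (sol$status != "optimal") stop("synthetic network is infeasible")
  v <- stats::setNames(sol$x, net$reactions$id)
  anchor <- truth$anchor_reaction
  if (abs(v[anchor]) < 1e-9) stop("anchor reaction carries no flux")
  keep <- names(v)[abs(v) > 1e-9 & net$reactions$subsystem != "exchange"]
  rel <- 100 * v[keep] / v[anchor]
  out <- data.frame(reaction = keep, relative_value = unname(rel),
                    sd_relative = unname(abs(rel)) *
                      stats::runif(length(keep), 0.05, 0.15),
                    stringsAsFactors = FALSE)
  attr(out, "flux_vector") <- v
  out
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits every file the pipeline consumes: the network (JSON), one raw gene
#' and one raw metabolite abundance table per condition (TSV, features x
#' samples, with a sidecar group table), the per-pathway module definitions
#' (GMT), the relative flux estimates (TSV), and the ground truth (JSON).
#' Conditions are independent noise realizations of the same designed
#' perturbations (condition seeds are \code{seed}, \code{seed + 1000}, ...),
#' emulating several exposures sharing one injury signature.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @param n_conditions number of exposure conditions to emit (>= 1).
#' @return invisible list: the file manifest plus the generated objects.
#' @export
simulate_dataset <- function(scenario, dir, n_conditions = 2) {
  stopifnot(n_conditions >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_network(scenario)
  net_path <- file.path(dir, "network.json")
  write_network(toy$network, net_path)

  conds <- paste0("cond", seq_len(n_conditions))
  omics <- list()
  manifest <- c(network = net_path)
  for (i in seq_len(n_conditions)) {
    sc <- scenario
    sc$seed <- scenario$seed + (i - 1L) * 1000L
    om <- simulate_omics(toy$network, toy$truth, sc)
    omics[[conds[i]]] <- om
    for (what in c("genes", "metabolites")) {
      p <- file.path(dir, paste0(what, "_", conds[i], ".tsv"))
      write_sample_table(om[[what]], p)
      manifest[paste0(what, "_", conds[i])] <- p
    }
  }
  gmt_path <- file.path(dir, "modules.gmt")
  write_gene_sets(omics[[1]]$modules, gmt_path)
  flux <- simulate_fluxes(toy$network, toy$truth, scenario)
  flux_path <- file.path(dir, "fluxes.tsv")
  utils::write.table(flux, flux_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(anchor_reaction = toy$truth$anchor_reaction,
         product_of = as.list(toy$truth$product_of),
         gene_effect = as.list(omics[[1]]$truth$gene_effect),
         metabolite_direction = as.list(omics[[1]]$truth$metabolite_direction),
         module_active = as.list(omics[[1]]$truth$module_active)),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- c(manifest, modules = gmt_path, fluxes = flux_path,
                truth = truth_path)
  invisible(list(manifest = manifest, network = toy$network,
                 truth = omics[[1]]$truth, omics = omics, flux = flux))
}

#' Write a sample table as TSV plus sidecar group file
#'
#' @param table a \code{sample_table}.
#' @param path output TSV path; the group sidecar is \code{<path>.groups.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_sample_table <- function(table, path) {
  df <- data.frame(feature = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  grp <- data.frame(sample = names(table$group), group = unname(table$group),
                    stringsAsFactors = FALSE)
  utils::write.table(grp, paste0(path, ".groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table written by [write_sample_table()]
#'
#' @param path TSV path with sidecar \code{<path>.groups.tsv}.
#' @return a \code{sample_table}.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  gpath <- paste0(path, ".groups.tsv")
  if (!file.exists(gpath)) stop("group sidecar not found: ", gpath)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(d[, -1, drop = FALSE])
  rownames(v) <- d$feature
  g <- utils::read.delim(gpath, stringsAsFactors = FALSE)
  sample_table(v, stats::setNames(g$group, g$sample))
}
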