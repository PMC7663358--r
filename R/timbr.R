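# Transcriptionally inferred metabolic biomarker response (TIMBR) scoring.
#
# Gene log2 fold changes are mapped through GPR rules to per-reaction fold
# changes, converted into condition-specific reaction weights, and each
# scoreable (extracellular) metabolite is scored by comparing the minimal
# weighted flux ("network demand") needed to sustain a fixed fraction of its
# maximal production under control weights versus treatment weights. A
# metabolite whose production becomes cheaper under treatment weights is
# predicted to increase in plasma.

#' TIMBR configuration
#'
#' @param fraction fraction f of the maximal demand flux enforced in the
#'   demand LP, in (0, 1]. f = 1 leaves no routing freedom; the default 0.9
#'   keeps the network near capacity while allowing alternate routes.
#' @param score_threshold classification cut-off: score > threshold is
#'   "increased", score < -threshold "decreased", otherwise "unchanged"
#'   (strict inequalities; the conventional cut-off is 0.1).
#' @param fc_clip clip limit L for gene-derived reaction fold changes; weights
#'   are computed from clip(fc, -L, L).
#' @param standardize standardize raw scores across feasible metabolites
#'   (z-score) before classification.
#' @param infinity sentinel magnitude replacing infinite bounds in LP form.
#' @param tol LP tolerance.
#' @return list of class \code{timbr_config}.
#' @export
timbr_config <- function(fraction = 0.9, score_threshold = 0.1,
                         fc_clip = 4, standardize = TRUE,
                         infinity = LP_INF, tol = 1e-9) {
  stopifnot(fraction > 0, fraction <= 1, score_threshold > 0, fc_clip > 0)
  structure(list(fraction = fraction, score_threshold = score_threshold,
                 fc_clip = fc_clip, standardize = standardize,
                 infinity = infinity, tol = tol),
            class = "timbr_config")
}

#' Map gene fold changes onto reactions through GPR rules
#'
#' Each reaction's GPR is evaluated over the gene log2 fold changes with
#' AND = min, OR = max; genes without a measured fold change default to 0
#' (unchanged), and reactions without a GPR get 0.
#'
#' @param net a \code{metabolic_network}.
#' @param gene_fc named numeric vector, gene id -> log2 fold change.
#' @return named numeric vector, reaction id -> fold change.
#' @export
reaction_fold_changes <- function(net, gene_fc) {
  out <- vapply(net$reactions$id, function(rid) {
    rule <- net$reactions$gpr[net$reactions$id == rid]
    expr <- tryCatch(parse_gpr(rule), error = function(e)
      stop("GPR of reaction '", rid, "': ", conditionMessage(e)))
    evaluate_gpr(expr, gene_fc, default = 0)
  }, 0)
  stats::setNames(out, net$reactions$id)
}

#' Condition-specific reaction weights
#'
#' With c = clip(fc, -L, L), the treated weight is \eqn{2^{-c/2}} and the
#' control weight \eqn{2^{+c/2}}: an upregulated reaction becomes cheap to
#' use under treatment and expensive under control, symmetrically, so that
#' negating all fold changes exactly swaps the two conditions. fc = 0 gives
#' weight 1 in both conditions.
#'
#' @param reaction_fc named numeric vector from [reaction_fold_changes()].
#' @param condition \code{"control"} or \code{"treated"}.
#' @param config a [timbr_config()].
#' @return list of class \code{condition_weights} with \code{condition} and
#'   a named positive \code{weights} vector.
#' @export
condition_weights <- function(reaction_fc,
                              condition = c("control", "treated"),
                              config = timbr_config()) {
  condition <- match.arg(condition)
  cc <- pmin(pmax(reaction_fc, -config$fc_clip), config$fc_clip)
  w <- if (condition == "treated") 2^(-cc / 2) else 2^(cc / 2)
  structure(list(condition = condition, weights = w),
            class = "condition_weights")
}

lp_bounds <- function(net, config) {
  lb <- pmax(net$reactions$lower_bound, -config$infinity)
  ub <- pmin(net$reactions$upper_bound, config$infinity)
  list(lb = lb, ub = ub)
}

#' Maximal production capacity of a metabolite
#'
#' Maximizes the flux of the metabolite's demand reaction subject to
#' steady-state mass balance (S v = 0) and the reaction bounds.
#'
#' @param net a \code{metabolic_network} already containing the demand
#'   reaction (see [add_demand_reaction()]).
#' @param metabolite_id the demanded metabolite.
#' @param config a [timbr_config()].
#' @return list with \code{v_max} and \code{feasible}.
#' @export
max_production <- function(net, metabolite_id, config = timbr_config()) {
  did <- paste0("DM_", metabolite_id)
  j <- match(did, net$reactions$id)
  if (is.na(j)) stop("demand reaction '", did, "' not present; ",
                     "call add_demand_reaction() first")
  S <- stoich_matrix(net)
  b <- lp_bounds(net, config)
  obj <- rep(0, ncol(S)); obj[j] <- 1
  sol <- solve_lp(obj, S, rep(0, nrow(S)), b$lb, b$ub, maximize = TRUE,
                  tol = config$tol)
  if (sol$status != "optimal")
    return(list(v_max = NA_real_, feasible = FALSE))
  list(v_max = max(sol$objval, 0), feasible = TRUE)
}

#' Minimal weighted network demand for producing a metabolite
#'
#' Minimizes the weighted sum of absolute fluxes subject to steady state,
#' the reaction bounds, and a demand flux of at least
#' \code{fraction * v_max}. Reversible reactions are split into non-negative
#' forward/backward components so the absolute-value objective is linear.
#'
#' @param net network containing the demand reaction.
#' @param weights a [condition_weights()] object (or named numeric vector);
#'   reactions without an entry get weight 1.
#' @param metabolite_id the demanded metabolite.
#' @param v_max maximal demand flux from [max_production()].
#' @param config a [timbr_config()].
#' @return list with \code{D} (objective value) and \code{feasible}.
#' @export
network_demand <- function(net, weights, metabolite_id, v_max,
                           config = timbr_config()) {
  if (inherits(weights, "condition_weights")) weights <- weights$weights
  if (is.na(v_max) || v_max <= 0) return(list(D = NA_real_, feasible = FALSE))
  did <- paste0("DM_", metabolite_id)
  j <- match(did, net$reactions$id)
  if (is.na(j)) stop("demand reaction '", did, "' not present")
  S <- stoich_matrix(net)
  b <- lp_bounds(net, config)
  lb <- b$lb; ub <- b$ub
  lb[j] <- max(lb[j], config$fraction * v_max)
  if (lb[j] > ub[j]) return(list(D = NA_real_, feasible = FALSE))
  w <- rep(1, ncol(S))
  hit <- match(net$reactions$id, names(weights))
  w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
  if (any(w <= 0) || any(!is.finite(w)))
    stop("reaction weights must be positive and finite")
  # split: v = v_plus - v_minus, v_plus, v_minus >= 0
  n <- ncol(S)
  A <- cbind(S, -S)
  lbs <- c(pmax(lb, 0), pmax(-ub, 0))
  ubs <- c(pmax(ub, 0), pmax(-lb, 0))
  sol <- solve_lp(c(w, w), A, rep(0, nrow(S)), lbs, ubs, tol = config$tol)
  if (sol$status != "optimal") {
    if (sol$status == "infeasible") return(list(D = NA_real_, feasible = FALSE))
    stop("network_demand LP failed with status: ", sol$status)
  }
  list(D = sol$objval, feasible = TRUE)
}

#' TIMBR production scores for scoreable metabolites
#'
#' For each metabolite: the maximal demand flux v_max, the minimal weighted
#' demands under control and treatment weights, the raw score
#' \eqn{\log_2(D_{control} / D_{treatment})} (positive when production is
#' cheaper under treatment, i.e. predicted to increase), the optionally
#' standardized score used for classification, and the three-way class by the
#' \code{score_threshold} cut-off. Metabolites whose production is infeasible
#' (v_max = 0) are reported with \code{feasible = FALSE} and no class.
#'
#' @param net a \code{metabolic_network} (without demand reactions).
#' @param gene_fc named numeric vector of gene log2 fold changes.
#' @param metabolites metabolite ids to score; default all extracellular.
#' @param config a [timbr_config()].
#' @return data.frame with columns \code{metabolite}, \code{v_max},
#'   \code{D_control}, \code{D_treatment}, \code{raw_score}, \code{score},
#'   \code{class}, \code{feasible}.
#' @export
production_scores <- function(net, gene_fc, metabolites = NULL,
                              config = timbr_config()) {
  if (is.null(metabolites))
    metabolites <- net$metabolites$id[net$metabolites$extracellular]
  if (length(metabolites) == 0) stop("no scoreable metabolites")
  # Each condition evaluates the GPRs from its own perspective: the treated
  # side aggregates the fold changes as given, the control side aggregates
  # their negation (control is "up" exactly where treatment is down). For
  # single-gene rules this reduces to the plain 2^(+c/2) control weight, and
  # it makes gene-level negation swap the two conditions exactly even through
  # min/max aggregation, which is not an odd function.
  rfc_trt <- reaction_fold_changes(net, gene_fc)
  rfc_ctl <- -reaction_fold_changes(net, -gene_fc)
  w_ctl <- condition_weights(rfc_ctl, "control", config)
  w_trt <- condition_weights(rfc_trt, "treated", config)
  rows <- lapply(metabolites, function(mid) {
    netd <- add_demand_reaction(net, mid, allow_internal = TRUE)
    mp <- max_production(netd, mid, config)
    if (!mp$feasible || mp$v_max <= config$tol * 1e3)
      return(data.frame(metabolite = mid, v_max = if (mp$feasible) 0 else NA,
                        D_control = NA_real_, D_treatment = NA_real_,
                        raw_score = NA_real_, score = NA_real_,
                        class = NA_character_, feasible = FALSE,
                        stringsAsFactors = FALSE))
    dc <- network_demand(netd, w_ctl, mid, mp$v_max, config)
    dt <- network_demand(netd, w_trt, mid, mp$v_max, config)
    if (!dc$feasible || !dt$feasible)
      return(data.frame(metabolite = mid, v_max = mp$v_max,
                        D_control = NA_real_, D_treatment = NA_real_,
                        raw_score = NA_real_, score = NA_real_,
                        class = NA_character_, feasible = FALSE,
                        stringsAsFactors = FALSE))
    data.frame(metabolite = mid, v_max = mp$v_max, D_control = dc$D,
               D_treatment = dt$D, raw_score = log2(dc$D / dt$D),
               score = NA_real_, class = NA_character_, feasible = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$feasible)) stop("all metabolites infeasible")
  ok <- out$feasible
  raw <- out$raw_score[ok]
  if (config$standardize && length(raw) > 1) {
    mu <- mean(raw)
    sdv <- stats::sd(raw)
    out$score[ok] <- if (sdv > config$tol) (raw - mu) / sdv else raw - mu
  } else {
    out$score[ok] <- raw
  }
  thr <- config$score_threshold
  out$class[ok] <- ifelse(out$score[ok] > thr, "increased",
                   ifelse(out$score[ok] < -thr, "decreased", "unchanged"))
  out
}

#' Compare production-score classes with observed metabolite changes
#'
#' Over observed-significant metabolites that were feasibly scored: a
#' prediction is correct iff the class is "increased" and the observed log
#' fold change is positive, or "decreased" and negative. "unchanged"
#' predictions are never counted correct; the reported fraction is therefore
#' conservative.
#'
#' @param results data.frame from [production_scores()].
#' @param observed data.frame with columns \code{feature}, \code{log_fc},
#'   \code{q} (metabolite differential result; ids must match the network's
#'   metabolite ids).
#' @param q_threshold significance filter on the observed changes.
#' @param mode label recorded in the report (\code{"real"} or
#'   \code{"randomized"}).
#' @param seed seed recorded for randomized-mode reports.
#' @return list of class \code{evaluation_report}: \code{n_scored},
#'   \code{n_observed_significant}, \code{n_correct},
#'   \code{fraction_correct}, \code{mode}, \code{seed}.
#' @export
evaluate_predictions <- function(results, observed, q_threshold = 0.1,
                                 mode = "real", seed = NA_integer_) {
  sig <- observed[!is.na(observed$q) & observed$q < q_threshold, , drop = FALSE]
  joined <- merge(results[results$feasible, , drop = FALSE], sig,
                  by.x = "metabolite", by.y = "feature")
  if (nrow(joined) == 0)
    stop("no observed-significant metabolite is scoreable on the network")
  correct <- (joined$class == "increased" & joined$log_fc > 0) |
             (joined$class == "decreased" & joined$log_fc < 0)
  structure(list(n_scored = sum(results$feasible),
                 n_observed_significant = nrow(joined),
                 n_correct = sum(correct),
                 fraction_correct = mean(correct),
                 mode = mode, seed = seed,
                 detail = data.frame(metabolite = joined$metabolite,
                                     class = joined$class,
                                     observed_log_fc = joined$log_fc,
                                     correct = correct,
                                     stringsAsFactors = FALSE)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation_report (%s): %d/%d observed-significant ",
                     "metabolites predicted in the right direction (%.1f%%)\n"),
              x$mode, x$n_correct, x$n_observed_significant,
              100 * x$fraction_correct))
  invisible(x)
}

#' Shuffled-gene robustness control
#'
#' Randomly permutes the gene-id to fold-change assignment, reruns production
#' scoring and evaluation, and reports the fraction correct under this
#' no-information input. Comparing it with the real-data report measures how
#' much of the prediction accuracy is attributable to the actual expression
#' pattern.
#'
#' @inheritParams production_scores
#' @param observed as in [evaluate_predictions()].
#' @param seed integer seed for the permutation.
#' @param q_threshold passed to [evaluate_predictions()].
#' @return an \code{evaluation_report} with \code{mode = "randomized"}.
#' @export
randomized_control <- function(net, gene_fc, metabolites = NULL, observed,
                               seed, q_threshold = 0.1,
                               config = timbr_config()) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  shuffled <- stats::setNames(unname(gene_fc),
                              sample(names(gene_fc), length(gene_fc)))
  res <- production_scores(net, shuffled, metabolites, config)
  evaluate_predictions(res, observed, q_threshold = q_threshold,
                       mode = "randomized", seed = seed)
}
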