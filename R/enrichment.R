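# Gene-set scoring by aggregated fold change. AFC (signed sum of member-gene
# log fold changes) scores pathway direction; AAFC (sum of absolute values)
# scores injury-module activation magnitude. Significance comes from a
# permutation null of size-matched random draws from the fold-change pool.

#' Aggregated fold-change score of a gene set
#'
#' \code{afc}: the signed sum of member-gene log fold changes; the sign gives
#' the pathway's direction of regulation. \code{aafc}: the sum of absolute
#' values; a magnitude-only activation score. Set genes absent from the
#' fold-change table are skipped.
#'
#' @param fc named numeric vector, gene id -> log fold change.
#' @param genes character vector of set gene ids, or a gene set from
#'   [read_gene_sets()].
#' @param mode \code{"afc"} or \code{"aafc"}.
#' @param set_name used in the error message when no set gene is present.
#' @return numeric score, with attribute \code{n_genes_used}.
#' @export
set_score <- function(fc, genes, mode = c("afc", "aafc"),
                      set_name = NULL) {
  mode <- match.arg(mode)
  if (is.list(genes)) {
    if (is.null(set_name)) set_name <- genes$name
    genes <- genes$genes
  }
  present <- intersect(genes, names(fc))
  if (length(present) == 0)
    stop("no genes of set '", if (is.null(set_name)) "?" else set_name,
         "' are present in the fold-change table")
  x <- fc[present]
  s <- if (mode == "afc") sum(x) else sum(abs(x))
  attr(s, "n_genes_used") <- length(present)
  s
}

#' Permutation null for a set score
#'
#' Draws \code{n_draws} random gene sets of the same size (without
#' replacement, by default) from the fold-change pool, scores each under the
#' given mode, and reports
#' \deqn{p = (1 + \#\{random \ge actual\}) / (n_{draws} + 1)}
#' (upper tail, ties counted as extreme, add-one smoothed so p is never 0) and
#' \deqn{z = (actual - mean(random)) / sd(random).}
#' When the null is degenerate (\code{sd = 0}), \code{z} is 0 if the actual
#' score equals the null mean and signed \code{Inf} otherwise.
#'
#' @param fc_pool numeric vector of fold changes to draw from.
#' @param set_size number of genes per random draw.
#' @param actual_score the observed set score.
#' @param mode \code{"afc"} or \code{"aafc"}.
#' @param n_draws number of random draws (>= 100).
#' @param seed integer seed; required for reproducibility.
#' @param replace draw with replacement instead.
#' @return list with \code{z}, \code{p}, \code{n_draws}, \code{seed}.
#' @export
permutation_test <- function(fc_pool, set_size, actual_score,
                             mode = c("afc", "aafc"), n_draws = 10000L,
                             seed, replace = FALSE) {
  mode <- match.arg(mode)
  n_draws <- as.integer(n_draws)
  if (n_draws < 100L) stop("n_draws must be at least 100")
  np <- length(fc_pool)
  if (set_size < 1 || (!replace && set_size > np))
    stop("set_size must lie in [1, length(fc_pool)]")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  pool <- if (mode == "aafc") abs(fc_pool) else fc_pool
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  if (set_size == np && !replace) {
    draws <- rep(sum(pool), n_draws)
  } else {
    draws <- vapply(seq_len(n_draws), function(i)
      sum(pool[sample.int(np, set_size, replace = replace)]), 0)
  }
  mu <- mean(draws)
  sdv <- stats::sd(draws)
  z <- if (sdv > 0) (actual_score - mu) / sdv
       else if (isTRUE(all.equal(actual_score, mu))) 0
       else sign(actual_score - mu) * Inf
  p <- (1 + sum(draws >= actual_score - 1e-12)) / (n_draws + 1)
  list(z = unname(z), p = unname(p), n_draws = n_draws, seed = seed)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Score gene sets against a differential result
#'
#' Generic driver behind [activate_modules()] and [afc_pathway_scores()].
#' Optionally restricts the gene universe (and hence the permutation pool) to
#' significant genes. Sets with no gene present in the universe are reported
#' with \code{null_result = TRUE} rather than dropped.
#'
#' @param diff data.frame from [differential()] (columns \code{feature},
#'   \code{log_fc}, \code{q}).
#' @param sets list of gene sets (see [read_gene_sets()]).
#' @param mode \code{"afc"} or \code{"aafc"}.
#' @param filter_significant restrict to genes with \code{q < q_threshold}.
#' @param q_threshold FDR threshold for the filter.
#' @param n_draws,seed,replace passed to [permutation_test()]; per-set seeds
#'   are derived deterministically from \code{seed}.
#' @return data.frame with one row per set: \code{set}, \code{mode},
#'   \code{n_genes_used}, \code{score}, \code{z}, \code{p},
#'   \code{null_result}, \code{seed}, \code{n_draws}.
#' @export
score_gene_sets <- function(diff, sets, mode = c("afc", "aafc"),
                            filter_significant = FALSE, q_threshold = 0.1,
                            n_draws = 10000L, seed, replace = FALSE) {
  mode <- match.arg(mode)
  if (nrow(diff) == 0) stop("empty differential result")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  use <- diff
  if (filter_significant) {
    use <- diff[diff$q < q_threshold, , drop = FALSE]
    if (nrow(use) == 0)
      stop("no genes pass q < ", q_threshold,
           "; consider relaxing the threshold")
  }
  fc <- stats::setNames(use$log_fc, use$feature)
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    present <- intersect(s$genes, names(fc))
    if (length(present) == 0)
      return(data.frame(set = s$name, mode = mode, n_genes_used = 0L,
                        score = NA_real_, z = NA_real_, p = NA_real_,
                        null_result = TRUE, seed = seed, n_draws = n_draws,
                        stringsAsFactors = FALSE))
    sc <- set_score(fc, present, mode = mode, set_name = s$name)
    pt <- permutation_test(fc, length(present), as.numeric(sc), mode = mode,
                           n_draws = n_draws, seed = seed + i,
                           replace = replace)
    data.frame(set = s$name, mode = mode, n_genes_used = length(present),
               score = as.numeric(sc), z = pt$z, p = pt$p,
               null_result = FALSE, seed = seed, n_draws = n_draws,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Injury-module activation scores (AAFC)
#'
#' Restricts the differential result to significantly changed genes
#' (q below threshold), then scores each module by the sum of absolute log
#' fold changes with a size-matched permutation null drawn from the filtered
#' fold-change pool. The module with the largest z is the most strongly
#' activated injury phenotype.
#'
#' @inheritParams score_gene_sets
#' @param modules list of gene sets defining the injury modules.
#' @return data.frame as in [score_gene_sets()].
#' @export
activate_modules <- function(diff, modules, q_threshold = 0.1,
                             n_draws = 10000L, seed, replace = FALSE) {
  score_gene_sets(diff, modules, mode = "aafc", filter_significant = TRUE,
                  q_threshold = q_threshold, n_draws = n_draws, seed = seed,
                  replace = replace)
}

#' Pathway direction scores (AFC)
#'
#' Signed aggregated fold-change scores with permutation z and p per pathway;
#' by default all measured genes form the universe and the pool.
#'
#' @inheritParams score_gene_sets
#' @param pathways list of gene sets defining the pathways.
#' @return data.frame as in [score_gene_sets()].
#' @export
afc_pathway_scores <- function(diff, pathways, filter_significant = FALSE,
                               q_threshold = 0.1, n_draws = 10000L, seed,
                               replace = FALSE) {
  score_gene_sets(diff, pathways, mode = "afc",
                  filter_significant = filter_significant,
                  q_threshold = q_threshold, n_draws = n_draws, seed = seed,
                  replace = replace)
}
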