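#' Construct a metabolic network
#'
#' A metabolic network holds metabolites, reactions with flux bounds and
#' gene-protein-reaction (GPR) rules, and the reaction stoichiometries that
#' imply the stoichiometric matrix S (one row per metabolite, one column per
#' reaction). Steady-state flux analysis on the network requires S v = 0
#' within the per-reaction bounds.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{extracellular} (logical). Extracellular
#'   metabolites form the scoreable set for production scoring: they are the
#'   species that can appear in blood plasma.
#' @param reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound}, \code{gpr} (rule text, may be empty), \code{subsystem}.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite id -> signed coefficient (negative =
#'   consumed, positive = produced).
#' @return object of class \code{metabolic_network}.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        stoichiometry = stoichiometry),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks id uniqueness, bound ordering, and that every stoichiometry entry
#' is non-empty, has non-zero coefficients, and references only metabolites
#' present in the network.
#'
#' @param net a \code{metabolic_network}.
#' @return the network, invisibly; errors describe the offending record.
#' @export
validate_network <- function(net) {
  mets <- net$metabolites
  rxns <- net$reactions
  req_m <- c("id", "name", "compartment", "extracellular")
  req_r <- c("id", "lower_bound", "upper_bound", "gpr", "subsystem")
  if (!all(req_m %in% names(mets)))
    stop("metabolites table must have columns: ", paste(req_m, collapse = ", "))
  if (!all(req_r %in% names(rxns)))
    stop("reactions table must have columns: ", paste(req_r, collapse = ", "))
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (any(!nzchar(mets$compartment)))
    stop("metabolite with empty compartment: ",
         paste(mets$id[!nzchar(mets$compartment)], collapse = ", "))
  if (any(rxns$lower_bound > rxns$upper_bound))
    stop("lower_bound > upper_bound for reaction: ",
         paste(rxns$id[rxns$lower_bound > rxns$upper_bound], collapse = ", "))
  if (!setequal(names(net$stoichiometry), rxns$id))
    stop("stoichiometry entries must match reaction ids exactly")
  for (rid in rxns$id) {
    s <- net$stoichiometry[[rid]]
    if (length(s) == 0)
      stop("reaction '", rid, "' has empty stoichiometry")
    if (any(s == 0))
      stop("reaction '", rid, "' has zero stoichiometric coefficient")
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      stop("reaction '", rid, "' references unknown metabolite '",
           unknown[1], "'")
  }
  invisible(net)
}

#' Stoichiometric matrix of a network
#'
#' @param net a \code{metabolic_network}.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(net) {
  m <- nrow(net$metabolites)
  n <- nrow(net$reactions)
  S <- matrix(0, m, n, dimnames = list(net$metabolites$id, net$reactions$id))
  for (rid in net$reactions$id) {
    s <- net$stoichiometry[[rid]]
    S[names(s), rid] <- s
  }
  S
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions (",
      sum(x$metabolites$extracellular), "extracellular )\n")
  invisible(x)
}

bound_to_json <- function(b) {
  ifelse(is.infinite(b), ifelse(b > 0, "inf", "-inf"), b)
}

bound_from_json <- function(b) {
  if (is.character(b)) {
    out <- suppressWarnings(as.numeric(b))
    out[b %in% c("inf", "Inf", "+inf")] <- Inf
    out[b %in% c("-inf", "-Inf")] <- -Inf
    out
  } else as.numeric(b)
}

#' Read a metabolic network from disk
#'
#' Two serializations are supported. \code{"json"}: a single file with
#' top-level arrays \code{metabolites} and \code{reactions}; each reaction
#' carries its stoichiometry as an object of metabolite id -> coefficient, and
#' unbounded fluxes are written as the tokens \code{"inf"} / \code{"-inf"}.
#' \code{"tsv-pair"}: \code{path} is a prefix; \code{<path>_reactions.tsv}
#' holds the reaction table, \code{<path>_stoichiometry.tsv} holds
#' (reaction, metabolite, coefficient) triplets and
#' \code{<path>_metabolites.tsv} the metabolite table.
#'
#' @param path file path (json) or path prefix (tsv-pair).
#' @param format \code{"json"} or \code{"tsv-pair"}.
#' @return a validated \code{metabolic_network}.
#' @export
read_network <- function(path, format = c("json", "tsv-pair")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) stop("network file not found: ", path)
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$metabolites) || is.null(doc$reactions))
      stop("malformed network file: missing 'metabolites' or 'reactions'")
    mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
      for (f in c("id", "compartment"))
        if (is.null(m[[f]]) || !nzchar(m[[f]]))
          stop("malformed metabolite record (missing ", f, "): ",
               jsonlite::toJSON(m, auto_unbox = TRUE))
      data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
                 compartment = m$compartment,
                 extracellular = isTRUE(m$extracellular),
                 stringsAsFactors = FALSE)
    }))
    stoich <- list()
    rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
      if (is.null(r$id) || !nzchar(r$id))
        stop("malformed reaction record (missing id)")
      if (is.null(r$stoichiometry) || length(r$stoichiometry) == 0)
        stop("malformed reaction record '", r$id, "': empty stoichiometry")
      stoich[[r$id]] <<- vapply(r$stoichiometry, as.numeric, 0)
      data.frame(id = r$id,
                 lower_bound = bound_from_json(r$lower_bound),
                 upper_bound = bound_from_json(r$upper_bound),
                 gpr = if (is.null(r$gpr)) "" else r$gpr,
                 subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
                 stringsAsFactors = FALSE)
    }))
    metabolic_network(mets, rxns, stoich)
  } else {
    rfile <- paste0(path, "_reactions.tsv")
    sfile <- paste0(path, "_stoichiometry.tsv")
    mfile <- paste0(path, "_metabolites.tsv")
    for (f in c(rfile, sfile, mfile))
      if (!file.exists(f)) stop("network file not found: ", f)
    mets <- utils::read.delim(mfile, stringsAsFactors = FALSE)
    mets$extracellular <- as.logical(mets$extracellular)
    rxns <- utils::read.delim(rfile, stringsAsFactors = FALSE,
                              colClasses = c(gpr = "character",
                                             subsystem = "character"))
    rxns$gpr[is.na(rxns$gpr)] <- ""
    trip <- utils::read.delim(sfile, stringsAsFactors = FALSE)
    stoich <- lapply(split(trip, factor(trip$reaction, levels = rxns$id)),
                     function(d) stats::setNames(d$coefficient, d$metabolite))
    metabolic_network(mets, rxns, stoich[rxns$id])
  }
}

#' Write a metabolic network to disk
#'
#' Inverse of [read_network()]; \code{read_network(write_network(net, p), f)}
#' returns a network structurally equal to \code{net}.
#'
#' @param net a \code{metabolic_network}.
#' @param path file path (json) or path prefix (tsv-pair).
#' @param format \code{"json"} or \code{"tsv-pair"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "tsv-pair")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "json") {
    mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
      m <- net$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           extracellular = m$extracellular)
    })
    rxns <- lapply(seq_len(nrow(net$reactions)), function(i) {
      r <- net$reactions[i, ]
      list(id = r$id,
           lower_bound = bound_to_json(r$lower_bound),
           upper_bound = bound_to_json(r$upper_bound),
           gpr = r$gpr, subsystem = r$subsystem,
           stoichiometry = as.list(net$stoichiometry[[r$id]]))
    })
    jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(net$metabolites, paste0(path, "_metabolites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$reactions, paste0(path, "_reactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trip <- do.call(rbind, lapply(net$reactions$id, function(rid) {
      s <- net$stoichiometry[[rid]]
      data.frame(reaction = rid, metabolite = names(s), coefficient = unname(s),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(trip, paste0(path, "_stoichiometry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Add a demand reaction for a metabolite
#'
#' Appends an irreversible sink reaction consuming exactly one unit of the
#' metabolite, bounds [0, Inf). Demand reactions quantify the network's
#' capacity to produce a species; production scoring adds one per scoreable
#' (extracellular) metabolite. The input network is not modified.
#'
#' @param net a \code{metabolic_network}.
#' @param metabolite_id id of an extracellular metabolite.
#' @param allow_internal permit demands on intracellular metabolites.
#' @return a new network with one added reaction \code{DM_<metabolite_id>}.
#' @export
add_demand_reaction <- function(net, metabolite_id, allow_internal = FALSE) {
  idx <- match(metabolite_id, net$metabolites$id)
  if (is.na(idx)) stop("unknown metabolite: ", metabolite_id)
  if (!net$metabolites$extracellular[idx] && !allow_internal)
    stop("metabolite '", metabolite_id, "' is not extracellular; ",
         "set allow_internal = TRUE to add a demand anyway")
  rid <- paste0("DM_", metabolite_id)
  if (rid %in% net$reactions$id)
    stop("reaction id '", rid, "' already present")
  out <- net
  out$reactions <- rbind(out$reactions,
                         data.frame(id = rid, lower_bound = 0,
                                    upper_bound = Inf, gpr = "",
                                    subsystem = "demand",
                                    stringsAsFactors = FALSE))
  out$stoichiometry[[rid]] <- stats::setNames(-1, metabolite_id)
  validate_network(out)
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then one gene id per
#' field. Duplicate genes within a line are removed with a warning.
#'
#' @param path GMT file path.
#' @return list of gene sets, each a list with \code{name}, \code{description},
#'   \code{genes}; named by set name.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    list(name = f[1], description = f[2], genes = genes)
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets list of gene sets as returned by [read_gene_sets()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
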