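# Independent oracles used to validate the package's own implementations.

# Literal Benjamini-Hochberg step-up reference: for each p-value, the minimum
# over all larger-or-equal ranks j of m * p_(j) / j, capped at 1. Written as
# an explicit double loop so it shares no code path with the implementation.
bh_reference <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q_sorted[i] <- min(best, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force LP minimizer: enumerates every basic solution of
# {A x = b, lb <= x <= ub} (basic columns + nonbasic variables pinned at a
# bound), keeps the feasible ones, and returns the minimal objective. The
# optimum of an LP over equalities and a box is attained at such a point.
lp_brute_force <- function(obj, mat, rhs, lb, ub) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  # reduce to an independent row set (rhs is consistent by construction)
  qt <- qr(t(mat))
  r <- qt$rank
  keep <- qt$pivot[seq_len(r)]
  A <- mat[keep, , drop = FALSE]
  b <- rhs[keep]
  best <- Inf
  feasible <- FALSE
  combs <- utils::combn(n, r)
  for (ci in seq_len(ncol(combs))) {
    B <- combs[, ci]
    AB <- A[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    Nset <- setdiff(seq_len(n), B)
    k <- length(Nset)
    for (bits in seq_len(2^k) - 1L) {
      xN <- numeric(k)
      if (k > 0) {
        sel <- bitwAnd(bits, bitwShiftL(1L, seq_len(k) - 1L)) != 0L
        xN <- ifelse(sel, ub[Nset], lb[Nset])
      }
      rhs2 <- b - if (k > 0) as.vector(A[, Nset, drop = FALSE] %*% xN) else 0
      xB <- tryCatch(solve(AB, rhs2), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n)
      x[B] <- xB
      if (k > 0) x[Nset] <- xN
      if (max(abs(mat %*% x - rhs)) > 1e-7) next
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      feasible <- TRUE
      best <- min(best, sum(obj * x))
    }
  }
  list(feasible = feasible, objval = best)
}

# Random small irreversible network for LP oracle checks: a chain from a
# source to an extracellular product, with a few random parallel/skip
# reactions, integer stoichiometry and finite integer bounds.
random_oracle_network <- function(seed) {
  set.seed(seed)
  p <- sample(3:4, 1)               # metabolites on the chain
  mets <- data.frame(
    id = c(paste0("M", seq_len(p - 1)), "P_e"),
    name = paste0("met", seq_len(p)),
    compartment = c(rep("c", p - 1), "e"),
    extracellular = c(rep(FALSE, p - 1), TRUE),
    stringsAsFactors = FALSE)
  ids <- mets$id
  rxns <- data.frame(id = "SRC", lower_bound = 0,
                     upper_bound = sample(3:10, 1), gpr = "", subsystem = "",
                     stringsAsFactors = FALSE)
  stoich <- list(SRC = c(M1 = 1))
  for (i in seq_len(p - 1)) {
    rid <- paste0("C", i)
    rxns <- rbind(rxns, data.frame(id = rid, lower_bound = 0,
                                   upper_bound = sample(3:10, 1), gpr = "",
                                   subsystem = "", stringsAsFactors = FALSE))
    stoich[[rid]] <- stats::setNames(c(-sample(1:2, 1), sample(1:2, 1)),
                                     c(ids[i], ids[i + 1]))
  }
  n_extra <- sample(0:2, 1)
  for (e in seq_len(n_extra)) {
    from <- sample(seq_len(p - 1), 1)
    to <- sample((from + 1):p, 1)
    rid <- paste0("X", e)
    rxns <- rbind(rxns, data.frame(id = rid, lower_bound = 0,
                                   upper_bound = sample(2:8, 1), gpr = "",
                                   subsystem = "", stringsAsFactors = FALSE))
    stoich[[rid]] <- stats::setNames(c(-sample(1:2, 1), sample(1:2, 1)),
                                     c(ids[from], ids[to]))
  }
  net <- metabolic_network(mets, rxns, stoich)
  weights <- stats::setNames(round(stats::runif(nrow(rxns), 0.2, 3), 2),
                             rxns$id)
  list(net = net, weights = weights, product = "P_e")
}

# Standard-form LP data (min w'v, S v = 0, bounds with the demand lower bound
# enforced) for a network + demand, matching network_demand's program but
# without flux splitting (valid for irreversible networks).
demand_lp_data <- function(netd, weights, metabolite_id, v_max, fraction) {
  S <- stoich_matrix(netd)
  lb <- pmax(netd$reactions$lower_bound, -1e6)
  ub <- pmin(netd$reactions$upper_bound, 1e6)
  j <- match(paste0("DM_", metabolite_id), netd$reactions$id)
  lb[j] <- fraction * v_max
  w <- rep(1, ncol(S))
  hit <- match(netd$reactions$id, names(weights))
  w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
  list(obj = w, mat = S, rhs = rep(0, nrow(S)), lb = lb, ub = ub, j = j)
}

# Three-reaction chain fixture: SRC (ub 10) -> A, A -> B, demand on B.
# With unit weights, fraction 1 and v_max 10 the unique flux is 10 on every
# reaction, so the minimal weighted demand is 30.
chain3_network <- function(mid_ub = 10) {
  metabolic_network(
    metabolites = data.frame(
      id = c("A", "B_e"), name = c("A", "B"),
      compartment = c("c", "e"), extracellular = c(FALSE, TRUE),
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("SRC", "CONV"), lower_bound = 0,
      upper_bound = c(10, mid_ub), gpr = c("", "gA"),
      subsystem = c("uptake", "core"), stringsAsFactors = FALSE),
    stoichiometry = list(SRC = c(A = 1), CONV = c(A = -1, B_e = 1)))
}

# Same chain with a parallel alternative for the conversion step.
chain3_parallel_network <- function() {
  net <- chain3_network()
  net$reactions <- rbind(net$reactions, data.frame(
    id = "CONV2", lower_bound = 0, upper_bound = 10, gpr = "gB",
    subsystem = "core", stringsAsFactors = FALSE))
  net$stoichiometry$CONV2 <- c(A = -1, B_e = 1)
  validate_network(net)
  net
}
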