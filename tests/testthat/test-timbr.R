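test_that("gene fold changes map onto reactions through GPRs", {
  net <- chain3_parallel_network()
  net$reactions$gpr <- c("", "g1 or g2", "g1 and g2")
  rfc <- reaction_fold_changes(net, c(g1 = 1.2, g2 = 0.3))
  expect_equal(unname(rfc), c(0, 1.2, 0.3))
  rfc2 <- reaction_fold_changes(net, c(g1 = 1.2))
  expect_equal(unname(rfc2[3]), 0)   # g2 defaults to 0, AND takes the min
  net$reactions$gpr[2] <- "g1 and and g2"
  expect_error(reaction_fold_changes(net, c(g1 = 1)), "CONV")
})

test_that("condition weights follow the symmetric 2^(±fc/2) form with clipping", {
  cfg <- timbr_config()
  w_t <- condition_weights(c(r = 1), "treated", cfg)$weights
  w_c <- condition_weights(c(r = 1), "control", cfg)$weights
  expect_equal(unname(w_t), 2^-0.5, tolerance = 1e-12)
  expect_equal(unname(w_c), 2^0.5, tolerance = 1e-12)
  expect_equal(unname(condition_weights(c(r = 0), "treated", cfg)$weights), 1)
  expect_equal(unname(condition_weights(c(r = 0), "control", cfg)$weights), 1)
  expect_equal(unname(condition_weights(c(r = 10), "treated", cfg)$weights),
               0.25)   # clipped at fc_clip = 4
  expect_equal(unname(condition_weights(c(r = -10), "control", cfg)$weights),
               0.25)
})

test_that("maximal production propagates bottleneck bounds along a chain", {
  net <- add_demand_reaction(chain3_network(), "B_e")
  expect_equal(max_production(net, "B_e")$v_max, 10, tolerance = 1e-8)
  net4 <- add_demand_reaction(chain3_network(mid_ub = 4), "B_e")
  expect_equal(max_production(net4, "B_e")$v_max, 4, tolerance = 1e-8)
})

test_that("a metabolite with no producing route has zero capacity", {
  net <- chain3_network()
  net$reactions$upper_bound[net$reactions$id == "CONV"] <- 0
  net <- add_demand_reaction(net, "B_e")
  expect_equal(max_production(net, "B_e")$v_max, 0, tolerance = 1e-8)
})

test_that("network demand on the chain matches hand and oracle computation", {
  cfg1 <- timbr_config(fraction = 1)
  net <- add_demand_reaction(chain3_network(), "B_e")
  w1 <- stats::setNames(rep(1, 3), net$reactions$id)
  expect_equal(network_demand(net, w1, "B_e", 10, cfg1)$D, 30,
               tolerance = 1e-8)
  # fraction scales the unique route linearly
  expect_equal(network_demand(net, w1, "B_e", 10,
                              timbr_config(fraction = 0.5))$D, 15,
               tolerance = 1e-8)
  # parallel cheaper route takes the whole flux
  netp <- add_demand_reaction(chain3_parallel_network(), "B_e")
  wp <- c(SRC = 1, CONV = 1, CONV2 = 0.5, DM_B_e = 1)
  expect_equal(network_demand(netp, wp, "B_e", 10, cfg1)$D, 25,
               tolerance = 1e-8)
  dat <- demand_lp_data(netp, wp, "B_e", 10, 1)
  ref <- lp_brute_force(dat$obj, dat$mat, dat$rhs, dat$lb, dat$ub)
  expect_equal(ref$objval, 25, tolerance = 1e-8)
})

test_that("raw production score is log2 of the demand ratio", {
  # D_control = 30 (unit weights), D_treatment = 25 (cheap parallel route)
  expect_equal(log2(30 / 25), 0.2630344, tolerance = 1e-6)
  net <- chain3_parallel_network()
  net$reactions$gpr <- c("", "", "gB")
  cfg <- timbr_config(fraction = 1, standardize = FALSE, fc_clip = 4)
  # fc = 2 on the parallel route: w_treated = 0.5, w_control = 2
  res <- production_scores(net, c(gB = 2), config = cfg)
  expect_equal(res$D_treatment, 25, tolerance = 1e-6)
  expect_equal(res$D_control, 30, tolerance = 1e-6)
  expect_equal(res$raw_score, log2(30 / 25), tolerance = 1e-6)
  expect_equal(res$class, "increased")
})

test_that("all-zero gene fold changes give zero scores and 'unchanged'", {
  sc <- synthetic_scenario(n_pathways = 3, seed = 4)
  net <- make_toy_network(sc)$network
  genes <- unique(unlist(lapply(net$reactions$gpr, function(g)
    gpr_genes(parse_gpr(g)))))
  res <- production_scores(net, stats::setNames(rep(0, length(genes)), genes))
  expect_true(all(res$feasible))
  expect_equal(res$raw_score, rep(0, nrow(res)), tolerance = 1e-9)
  expect_true(all(res$class == "unchanged"))
})

test_that("negating all gene fold changes negates every raw score", {
  sc <- synthetic_scenario(n_pathways = 3, seed = 5)
  net <- make_toy_network(sc)$network
  genes <- unique(unlist(lapply(net$reactions$gpr, function(g)
    gpr_genes(parse_gpr(g)))))
  set.seed(81)
  fc <- stats::setNames(stats::rnorm(length(genes), 0, 1.5), genes)
  cfg <- timbr_config(standardize = FALSE)
  up <- production_scores(net, fc, config = cfg)
  dn <- production_scores(net, -fc, config = cfg)
  expect_equal(up$D_control, dn$D_treatment, tolerance = 1e-7)
  expect_equal(up$D_treatment, dn$D_control, tolerance = 1e-7)
  expect_equal(up$raw_score, -dn$raw_score, tolerance = 1e-7)
})

test_that("raising fold changes on the unique producing route never lowers the score", {
  net <- chain3_network()
  net$reactions$gpr <- c("gU", "gA")
  cfg <- timbr_config(standardize = FALSE)
  deltas <- c(-2, -1, 0, 0.5, 1, 2, 3)
  scores <- vapply(deltas, function(d)
    production_scores(net, c(gU = d, gA = d), config = cfg)$raw_score, 0)
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("doubling all weights leaves the raw score unchanged", {
  netp <- add_demand_reaction(chain3_parallel_network(), "B_e")
  cfg <- timbr_config(fraction = 1)
  w <- c(SRC = 1.3, CONV = 0.8, CONV2 = 0.5, DM_B_e = 1)
  d1 <- network_demand(netp, w, "B_e", 10, cfg)$D
  d2 <- network_demand(netp, 2 * w, "B_e", 10, cfg)$D
  expect_equal(d2, 2 * d1, tolerance = 1e-8)
  expect_equal(log2(d1 / d1), log2(d2 / d2))
})

test_that("standardized scores classify by the strict ±0.1 rule", {
  res <- data.frame(metabolite = letters[1:4], v_max = 1,
                    D_control = 1, D_treatment = 1,
                    raw_score = c(0.05, -0.2, 0.3, 0.1),
                    score = c(0.05, -0.2, 0.3, 0.1),
                    class = NA_character_, feasible = TRUE,
                    stringsAsFactors = FALSE)
  thr <- 0.1
  cls <- ifelse(res$score > thr, "increased",
                ifelse(res$score < -thr, "decreased", "unchanged"))
  expect_equal(cls, c("unchanged", "decreased", "increased", "unchanged"))
})

test_that("prediction evaluation counts direction matches only", {
  res <- data.frame(metabolite = c("m1", "m2", "m3"), v_max = 1,
                    D_control = 1, D_treatment = 1, raw_score = 0,
                    score = 0,
                    class = c("increased", "unchanged", "decreased"),
                    feasible = TRUE, stringsAsFactors = FALSE)
  obs <- data.frame(feature = c("m1", "m2", "m3"),
                    log_fc = c(1, -1, 1), q = 0.01)
  ev <- evaluate_predictions(res, obs)
  expect_equal(ev$fraction_correct, 1 / 3)
  expect_equal(ev$n_observed_significant, 3)
  # perfect agreement
  res$class <- c("increased", "decreased", "increased")
  expect_equal(evaluate_predictions(res, obs)$fraction_correct, 1)
  expect_error(evaluate_predictions(res, data.frame(feature = "zz",
                                                    log_fc = 1, q = 0.01)),
               "scoreable")
})

test_that("randomized control is deterministic given its seed", {
  sc <- synthetic_scenario(n_pathways = 3, seed = 6)
  toy <- make_toy_network(sc)
  om <- simulate_omics(toy$network, toy$truth, sc)
  gd <- differential(preprocess(om$genes, "2"))
  md <- differential(preprocess(om$metabolites, "e"))
  fc <- stats::setNames(gd$log_fc, gd$feature)
  r1 <- randomized_control(toy$network, fc, observed = md, seed = 42)
  r2 <- randomized_control(toy$network, fc, observed = md, seed = 42)
  expect_identical(r1$fraction_correct, r2$fraction_correct)
  expect_equal(r1$mode, "randomized")
})
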