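make_fixture_network <- function() {
  metabolic_network(
    metabolites = data.frame(
      id = c("A_c", "B_c", "C_e"),
      name = c("alpha", "beta", "gamma"),
      compartment = c("c", "c", "e"),
      extracellular = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("R1", "R2", "EX_C"),
      lower_bound = c(0, -5, -Inf), upper_bound = c(10, 5, Inf),
      gpr = c("g1", "(g1 and g2) or g3", ""),
      subsystem = c("s1", "s1", "exchange"),
      stringsAsFactors = FALSE),
    stoichiometry = list(R1 = c(A_c = -1, B_c = 1),
                         R2 = c(B_c = -1, C_e = 1),
                         EX_C = c(C_e = -1)))
}

test_that("JSON round-trip preserves the network, including infinite bounds", {
  net <- make_fixture_network()
  expect_equal(nrow(net$metabolites), 3)
  expect_equal(nrow(net$reactions), 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  # infinity survives as a token, not as a mangled number
  expect_match(paste(readLines(path), collapse = ""), '"-inf"')
  back <- read_network(path)
  expect_equal(back$metabolites, net$metabolites)
  expect_equal(back$reactions, net$reactions)
  expect_equal(back$stoichiometry[net$reactions$id],
               net$stoichiometry[net$reactions$id])
})

test_that("TSV-pair round-trip preserves the network", {
  net <- make_fixture_network()
  net$reactions$lower_bound[3] <- -100   # tsv keeps numerics plain
  net$reactions$upper_bound[3] <- 100
  prefix <- file.path(withr::local_tempdir(), "net")
  write_network(net, prefix, format = "tsv-pair")
  back <- read_network(prefix, format = "tsv-pair")
  expect_equal(back$metabolites, net$metabolites)
  expect_equal(back$reactions, net$reactions)
  expect_equal(back$stoichiometry[net$reactions$id],
               net$stoichiometry[net$reactions$id])
})

test_that("validation names the offending record", {
  net <- make_fixture_network()
  net$stoichiometry$R2 <- c(B_c = -1, X = 1)
  expect_error(validate_network(net), "unknown metabolite 'X'")
  net2 <- make_fixture_network()
  net2$metabolites$id[2] <- "A_c"
  net2$stoichiometry$R1 <- c(A_c = -1)
  net2$stoichiometry$R2 <- c(A_c = -1, C_e = 1)
  expect_error(validate_network(net2), "duplicate metabolite id: A_c")
  net3 <- make_fixture_network()
  net3$reactions$lower_bound[1] <- 11
  expect_error(validate_network(net3), "lower_bound > upper_bound.*R1")
})

test_that("stoichiometric matrix has one row per metabolite, one column per reaction", {
  net <- make_fixture_network()
  S <- stoich_matrix(net)
  expect_equal(dim(S), c(3, 3))
  expect_equal(S["A_c", "R1"], -1)
  expect_equal(S["C_e", "EX_C"], -1)
  expect_equal(S["A_c", "EX_C"], 0)
})

test_that("GPR parsing honors precedence and parenthesization", {
  expect_equal(parse_gpr("g1"), list(op = "gene", gene = "g1"))
  tree <- parse_gpr("(g1 and g2) or g3")
  expect_equal(tree$op, "or")
  expect_equal(tree$children[[1]]$op, "and")
  expect_equal(tree$children[[2]]$gene, "g3")
  # unparenthesized: and binds tighter than or
  tree2 <- parse_gpr("g1 or g2 and g3")
  expect_equal(tree2$op, "or")
  expect_equal(tree2$children[[2]]$op, "and")
  # keywords are case-insensitive
  expect_equal(parse_gpr("g1 AND g2")$op, "and")
  expect_null(parse_gpr(""))
  expect_null(parse_gpr(NA))
})

test_that("malformed GPR rules raise positioned parse errors", {
  expect_error(parse_gpr("g1 and or g2"), "operand expected")
  expect_error(parse_gpr("(g1 and g2"), "unbalanced")
  expect_error(parse_gpr("g1 and"), "operand expected")
  expect_error(parse_gpr(")g1"), "position 1")
})

test_that("GPR evaluation: AND = min, OR = max, missing genes take default", {
  expect_equal(evaluate_gpr(parse_gpr("g1"), c(g1 = 0.7)), 0.7)
  expect_equal(evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 2, g2 = -1)), -1)
  expect_equal(
    evaluate_gpr(parse_gpr("(g1 and g2) or g3"),
                 c(g1 = 2, g2 = -1, g3 = 0.5)), 0.5)
  expect_equal(evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 1.2)), 0)
  expect_equal(evaluate_gpr(parse_gpr("g1 or g2"), c(g1 = 1.2, g2 = 0.3)), 1.2)
  expect_equal(evaluate_gpr(NULL, c(g1 = 5)), 0)
  expect_equal(evaluate_gpr(NULL, c(g1 = 5), default = 9), 9)
})

test_that("GPR evaluation is monotone and collapses on constant inputs", {
  set.seed(11)
  rules <- c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or (g3 and g4)",
             "g1 or (g2 and (g3 or g4))", "(g1 or g2) and (g3 or g4)")
  genes <- paste0("g", 1:4)
  for (rule in rules) {
    expr <- parse_gpr(rule)
    for (rep in 1:20) {
      v <- stats::setNames(stats::rnorm(4), genes)
      base <- evaluate_gpr(expr, v)
      g <- sample(genes, 1)
      v2 <- v
      v2[g] <- v2[g] + abs(stats::rnorm(1))
      expect_gte(evaluate_gpr(expr, v2), base)
    }
    cval <- stats::rnorm(1)
    expect_equal(evaluate_gpr(expr, stats::setNames(rep(cval, 4), genes)),
                 cval)
  }
})

test_that("add_demand_reaction copies, validates, and errors as specified", {
  net <- make_fixture_network()
  before <- net
  out <- add_demand_reaction(net, "C_e")
  expect_equal(nrow(out$reactions), nrow(net$reactions) + 1)
  expect_equal(out$stoichiometry$DM_C_e, c(C_e = -1))
  expect_equal(out$reactions$lower_bound[out$reactions$id == "DM_C_e"], 0)
  expect_equal(ncol(stoich_matrix(out)), ncol(stoich_matrix(net)) + 1)
  expect_identical(net, before)  # input untouched
  expect_error(add_demand_reaction(net, "Q"), "unknown metabolite: Q")
  expect_error(add_demand_reaction(net, "A_c"), "not extracellular")
  expect_silent(add_demand_reaction(net, "A_c", allow_internal = TRUE))
})

test_that("GMT parsing handles dedup, short lines, and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("mod1\tdesc\tg1\tg2", "mod2\tother\tg3\tg3\tg4"), path)
  expect_warning(sets <- read_gene_sets(path), "mod2")
  expect_equal(sets$mod1$genes, c("g1", "g2"))
  expect_equal(sets$mod2$genes, c("g3", "g4"))
  writeLines("mod1\tdesc", path)
  expect_error(read_gene_sets(path), "line 1")
  sets2 <- list(a = list(name = "a", description = "d", genes = c("x", "y")))
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets2, p2)
  expect_equal(read_gene_sets(p2), sets2)
})
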