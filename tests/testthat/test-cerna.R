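# small deterministic expression fixture with known correlation structure:
# mi1 negatively tracks g1/g2 and l1; g1, g2, l1 positively co-move; x*
# features are independent noise
cerna_fixture <- function(n = 60, seed = 2) {
  set.seed(seed)
  z <- rnorm(n)
  expr <- rbind(
    g1 = z + rnorm(n, sd = 0.3),
    g2 = z + rnorm(n, sd = 0.3),
    g3 = rnorm(n),
    mi1 = -z + rnorm(n, sd = 0.3),
    mi2 = rnorm(n),
    l1 = z + rnorm(n, sd = 0.3),
    l2 = -z + rnorm(n, sd = 0.3))
  de <- data.frame(
    feature_id = rownames(expr),
    class = c("mrna", "mrna", "mrna", "mirna", "mirna", "lncrna", "lncrna"),
    log2fc = c(2, 2, 2, -2, 2, 2, -2),
    pvalue = 1e-8, fdr = 1e-7,
    direction = c("up", "up", "up", "down", "up", "up", "down"),
    stable = TRUE, stringsAsFactors = FALSE)
  list(expr = expr, de = de)
}

test_that("candidate selection applies both strict cuts", {
  shap <- c(a = 1e-3, b = 1e-3, c = 1e-5, d = 0, e = 1e-4)
  mcc <- c(a = 9, b = 8, c = 100, d = 100)   # e missing -> 0
  got <- select_candidate_mrnas(shap, mcc)
  expect_equal(got, "a")   # b fails MCC > 8, c/e fail shap, d fails shap
  # brute-force set comprehension over the two tables
  brute <- sort(names(shap)[shap > 1e-4 &
                              ifelse(is.na(mcc[names(shap)]), 0,
                                     mcc[names(shap)]) > 8])
  expect_equal(got, brute)
  expect_warning(select_candidate_mrnas(c(x = 0), c(x = 1)), "no mRNA")
})

test_that("the triplet screen enforces target and sign gates", {
  fx <- cerna_fixture()
  tm <- data.frame(mirna_id = c("mi1", "mi1", "mi2"),
                   target_id = c("g1", "g2", "g3"))
  tl <- data.frame(mirna_id = c("mi1", "mi1", "mi2"),
                   target_id = c("l1", "l2", "l1"))
  tr <- screen_triplets(fx$expr, fx$de, tm, tl,
                        candidate_mrnas = c("g1", "g2", "g3"))
  # mi1 pairs with g1/g2 and l1 only: l2 fails the miRNA-lncRNA sign
  # (both negative in z, positively correlated); mi2 uncorrelated with g3
  expect_equal(nrow(tr), 2L)
  expect_setequal(tr$mrna_id, c("g1", "g2"))
  expect_equal(unique(tr$lncrna_id), "l1")
  expect_true(all(tr$r_mm < 0 & tr$r_ml < 0 & tr$r_gl > 0))
  expect_true(all(tr[, c("p_mm", "p_ml", "p_gl")] < 0.05))

  # a correlated pair absent from the target tables never forms a triplet
  tr2 <- screen_triplets(fx$expr, fx$de, tm[-1, , drop = FALSE], tl,
                         candidate_mrnas = c("g1", "g2", "g3"))
  expect_false("g1" %in% tr2$mrna_id)

  expect_warning(
    tr3 <- screen_triplets(fx$expr, fx$de, tm[0, ], tl, "g1"),
    "empty target")
  expect_equal(nrow(tr3), 0L)
})

test_that("the triplet screen is invariant to input row order", {
  fx <- cerna_fixture()
  tm <- data.frame(mirna_id = c("mi1", "mi1"), target_id = c("g1", "g2"))
  tl <- data.frame(mirna_id = "mi1", target_id = "l1")
  a <- screen_triplets(fx$expr, fx$de, tm, tl, c("g1", "g2"))
  b <- screen_triplets(fx$expr[sample(nrow(fx$expr)), ],
                       fx$de[sample(nrow(fx$de)), ],
                       tm[2:1, ], tl, c("g2", "g1"))
  expect_equal(a, b)
})

test_that("ceRNA network assembly counts nodes, edges and degrees", {
  expect_equal(nrow(build_cerna_network(empty_triplets())$nodes), 0L)

  fx <- cerna_fixture()
  one <- data.frame(mrna_id = "g1", mirna_id = "mi1", lncrna_id = "l1",
                    r_mm = -0.9, p_mm = 0, r_ml = -0.9, p_ml = 0,
                    r_gl = 0.9, p_gl = 0, stringsAsFactors = FALSE)
  net1 <- build_cerna_network(one, de_table = fx$de)
  expect_equal(nrow(net1$nodes), 3L)
  expect_equal(nrow(net1$edges), 3L)
  expect_equal(net1$nodes$direction[net1$nodes$id == "mi1"], "down")

  two <- rbind(one, transform(one, mrna_id = "g2"))
  net2 <- build_cerna_network(two, de_table = fx$de)
  deg_mi1 <- sum(net2$edges$from == "mi1" | net2$edges$to == "mi1")
  # degree of the miRNA = its distinct targets over retained triplets
  expect_equal(deg_mi1, length(unique(c(two$mrna_id, two$lncrna_id))))

  # interaction edges between included mRNAs are carried over
  ig <- list(edges = data.frame(node_a = "g1", node_b = "g2",
                                confidence = 900, r = 0.9, p = 0),
             nodes = c("g1", "g2"))
  class(ig) <- "interaction_graph"
  net3 <- build_cerna_network(two, ig, fx$de)
  expect_true(any(net3$edges$type == "interaction"))
})

test_that("potential-ceRNA selection filters by contribution threshold", {
  fx <- cerna_fixture()
  two <- data.frame(mrna_id = c("g1", "g2"), mirna_id = "mi1",
                    lncrna_id = "l1", r_mm = -0.9, p_mm = 0, r_ml = -0.9,
                    p_ml = 0, r_gl = 0.9, p_gl = 0, stringsAsFactors = FALSE)
  net <- build_cerna_network(two, de_table = fx$de)
  shap <- c(g1 = 0.2, g2 = 1e-5, mi1 = 0.1, l1 = 0.05)
  sub <- select_potential_cernas(shap, net)
  expect_setequal(sub$nodes$id, c("g1", "mi1", "l1"))   # g2 below cut
  expect_equal(sub$nodes$shap_value[sub$nodes$id == "g1"], 0.2)
  # membership equals the brute-force filter (plus isolation pruning)
  expect_setequal(sub$nodes$id,
                  intersect(names(shap)[shap > 1e-4], net$nodes$id))

  expect_warning(sel0 <- select_potential_cernas(shap * 0, net), "empty")
  expect_equal(nrow(sel0$nodes), 0L)

  # threshold 0 keeps every node with a nonzero contribution
  sub0 <- select_potential_cernas(shap, net, threshold = 0)
  expect_setequal(sub0$nodes$id, names(shap)[shap > 0])
})

test_that("module extraction groups targets by direction per miRNA", {
  # one miRNA with 3 up mRNAs, 1 up lncRNA, 1 down mRNA -> two modules
  nodes <- data.frame(
    id = c("mi1", "g1", "g2", "g3", "g4", "l1"),
    class = c("mirna", rep("mrna", 4), "lncrna"),
    direction = c("down", "up", "up", "up", "down", "up"),
    shap_value = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = "mi1", to = c("g1", "g2", "g3", "g4", "l1"),
                      type = "ceRNA", stringsAsFactors = FALSE)
  sub <- structure(list(nodes = nodes, edges = edges),
                   class = "cerna_network")
  de <- data.frame(feature_id = nodes$id, class = nodes$class,
                   direction = nodes$direction, stable = TRUE,
                   stringsAsFactors = FALSE)
  mods <- extract_modules(sub, de)
  expect_length(mods, 2L)
  up <- mods[[which(vapply(mods, `[[`, "", "direction") == "up")]]
  down <- mods[[which(vapply(mods, `[[`, "", "direction") == "down")]]
  expect_setequal(up$mrna_ids, c("g1", "g2", "g3"))
  expect_equal(up$lncrna_ids, "l1")
  expect_true(up$primary)
  expect_equal(down$mrna_ids, "g4")
  expect_false(down$primary)
  expect_false(down$has_lncrna)

  # purity: same inputs, same output
  expect_identical(mods, extract_modules(sub, de))

  # a miRNA with no surviving targets yields no module
  sub2 <- sub
  sub2$edges <- sub2$edges[0, ]
  expect_length(extract_modules(sub2, de), 0L)

  # a direction group with only lncRNAs yields no module
  nodes3 <- nodes
  nodes3$direction[nodes3$id %in% c("g1", "g2", "g3")] <- "down"
  sub3 <- structure(list(nodes = nodes3, edges = edges),
                    class = "cerna_network")
  de3 <- transform(de, direction = nodes3$direction)
  mods3 <- extract_modules(sub3, de3)
  expect_length(mods3, 1L)
  expect_equal(mods3[[1]]$direction, "down")
})
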