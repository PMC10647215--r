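# Driver calls, the 20/20-rule baseline, concordance and rule
# comparison.

fixed_proba_forest <- function(probs) {
  # single-leaf trees reproducing a fixed probability vector
  df <- data.frame(id = 1L, leaf = TRUE, feature = NA_integer_,
                   threshold = NA_real_, left = NA_integer_,
                   right = NA_integer_, n = 10L,
                   p_OG = probs[1], p_TSG = probs[2], p_PG = probs[3])
  tree <- structure(list(nodes = df, variant = "T_prune",
                         classes = c("OG", "TSG", "PG")),
                    class = "selforest_tree")
  structure(list(trees = list(tree), kind = "RF_mouse",
                 classes = c("OG", "TSG", "PG"), config = NULL,
                 standardization = NULL, feature_names = "f"),
            class = "selforest_forest")
}

test_that("driver calls require both the maximum and the cutoff", {
  x <- matrix(0, 1, 1, dimnames = list("g1", "f"))
  call_for <- function(p) classify(fixed_proba_forest(p), x)
  high_og <- call_for(c(0.995, 0.001, 0.004))
  expect_equal(high_og$class_label, "OG")
  expect_equal(high_og$probability, 0.995)
  # no driver class above the cutoff -> passenger
  expect_equal(call_for(c(0.45, 0.15, 0.40))$class_label, "PG")
  # passenger maximum -> passenger regardless of cutoff
  expect_equal(call_for(c(0.2, 0.2, 0.6))$class_label, "PG")
  expect_equal(call_for(c(0.1, 0.6, 0.3))$class_label, "TSG")
  expect_error(classify(fixed_proba_forest(c(1, 0, 0)), x, cutoff = 1.2),
               "cutoff")
})

test_that("driver calls never carry probability at or below the cutoff", {
  set.seed(31)
  d <- blob_data(25)
  forest <- train_forest(d$X, d$y, forest_config(n_trees = 30, seed = 6))
  adapted <- build_rf_mouse(forest, d$X, min_target = 10)
  calls <- classify(adapted, d$X)
  drivers <- calls[calls$class_label %in% c("OG", "TSG"), ]
  expect_true(all(drivers$probability > 0.5))
})

test_that("the 20/20 rule reproduces its worked examples", {
  # 3 truncating of 10 coding mutations: 30% > 20% -> TSG
  tsg <- make_records(1:10, c(rep("nonsense", 3), rep("missense", 7)))
  expect_equal(rule_20_20(tsg), "TSG")
  # 3 missense at one recurrent position, none truncating -> OG
  og <- make_records(c(50, 50, 50, 1:7),
                     c(rep("missense", 3), rep("synonymous", 7)))
  expect_equal(rule_20_20(og), "OG")
  # 1 truncating + 9 scattered singleton missense -> PG
  pg <- make_records(1:10, c("nonsense", rep("missense", 9)))
  expect_equal(rule_20_20(pg), "PG")
  # dual-threshold conflict resolves to TSG by default
  both <- make_records(c(10, 10, 10, 1, 2, 3, 4, 5, 6, 7),
                       c(rep("missense", 3), rep("nonsense", 3),
                         rep("synonymous", 4)))
  expect_equal(rule_20_20(both), "TSG")
  expect_equal(rule_20_20(both, tsg_precedence = FALSE), "OG")
})

test_that("concordance reproduces the ortholog-surrogate arithmetic", {
  # 45 ortholog pairs, 39 concordant; B calls 7 OGs of which 4 are
  # OGs in the reference, and 36 PGs of which 34 are reference PGs
  ref <- data.frame(
    gene = paste0("g", 1:45),
    class_label = c(rep("OG", 4), rep("PG", 3),
                    rep("TSG", 1), rep("PG", 1),
                    rep("PG", 34), "TSG", "TSG"),
    stringsAsFactors = FALSE)
  prd <- data.frame(
    gene = paste0("g", 1:45),
    class_label = c(rep("OG", 7), rep("TSG", 2), rep("PG", 36)),
    stringsAsFactors = FALSE)
  cs <- concordance(ref, prd)
  expect_equal(cs$n, 45)
  expect_equal(cs$accuracy, 39 / 45)
  expect_equal(round(100 * cs$accuracy, 1), 86.7)
  pc <- cs$per_class
  expect_equal(pc$ppv[pc$class == "OG"], 4 / 7)
  expect_equal(round(100 * pc$ppv[pc$class == "OG"], 1), 57.1)
  expect_equal(pc$ppv[pc$class == "PG"], 34 / 36)
  expect_equal(round(100 * pc$ppv[pc$class == "PG"], 1), 94.4)
  expect_equal(sum(cs$confusion), cs$n)

  # ortholog mapping between namespaces
  map <- data.frame(gene_a = paste0("g", 1:45),
                    gene_b = paste0("m", 1:45),
                    stringsAsFactors = FALSE)
  prd_m <- transform(prd, gene = paste0("m", 1:45))
  cs2 <- concordance(ref, prd_m, map)
  expect_equal(cs2$accuracy, cs$accuracy)
  expect_error(concordance(ref, transform(prd, gene = paste0("x", 1:45))),
               "no overlapping")
})

test_that("rule comparison counts shared and exclusive calls", {
  a <- data.frame(gene = paste0("g", 1:6),
                  class_label = c("OG", "OG", "TSG", "PG", "PG", "PG"))
  same <- compare_rules(a, a)
  expect_equal(sum(same$per_class$model_only), 0)
  expect_equal(sum(same$per_class$rule_only), 0)

  b <- data.frame(gene = paste0("g", 1:6),
                  class_label = c("PG", "PG", "TSG", "OG", "OG", "OG"))
  cmp <- compare_rules(a, b)
  og <- cmp$per_class[cmp$per_class$class == "OG", ]
  expect_equal(og$shared, 0)
  expect_equal(og$model_only, 2)
  expect_equal(og$rule_only, 3)
  expect_setequal(cmp$exclusive$OG_model_only, c("g1", "g2"))
  expect_error(compare_rules(a, b[1:3, ]), "different genes")
})

test_that("neutral hotspots fool the 20/20 rule but not the estimator", {
  # passengers with a mutation hotspot sampled under omega = 1:
  # recurrent missense exceed 20% so the 20/20 rule calls OG, while the
  # selection estimate stays near neutral
  set.seed(33)
  fooled <- 0
  neutral_logs <- numeric(0)
  for (i in 1:12) {
    cds <- gen_cds(300)
    e <- enumerate_saturated_mutations(cds)
    rec <- gen_mutations(cds, e, log_omega = 0, log_phi = 0, h = 0.5,
                         n_mutations = 40)
    if (rule_20_20(rec) == "OG") fooled <- fooled + 1
    est <- estimate_selection(
      c(n_syn = sum(rec$consequence == "synonymous"),
        n_mis = sum(rec$consequence == "missense"),
        n_trunc = sum(rec$consequence %in% c("nonsense", "frameshift"))),
      e)
    neutral_logs <- c(neutral_logs, est$log_omega)
  }
  expect_gte(fooled, 8)                   # the rule's false positives
  expect_lt(mean(abs(neutral_logs)), 1)   # selection stays near neutral
})
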