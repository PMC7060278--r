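test_that("is_expressed applies the replicate-fraction rule", {
  st <- toy_study(rbind(c(0, 0, 0), c(5.0, 4.2, 6.1), c(0.05, 1.2, 3.0)),
                  matrix(1, 3, 3))
  expect_false(is_expressed(st, "g1", "a", min_fpkm = 0))
  expect_false(is_expressed(st, "g1", "a", min_fpkm = 2))
  expect_true(is_expressed(st, "g2", "a", min_fpkm = 0.1,
                           min_replicate_fraction = 1.0))
  # 2 of 3 replicates above 0.1: passes at 2/3, fails at 1.0
  expect_true(is_expressed(st, "g3", "a", min_fpkm = 0.1,
                           min_replicate_fraction = 2 / 3))
  expect_false(is_expressed(st, "g3", "a", min_fpkm = 0.1,
                            min_replicate_fraction = 1.0))
  expect_error(is_expressed(st, "nope", "a"), class = "emtnet_input_error")
  expect_error(is_expressed(st, "g1", "c"), class = "emtnet_input_error")
  expect_error(is_expressed(st, "g1", "a", min_replicate_fraction = 0),
               class = "emtnet_config_error")
})

test_that("venn_partition classifies a hand-enumerated 6-gene study", {
  a <- rbind(c(5, 5, 5), c(3, 4, 3), c(2, 2, 2), c(0, 0, 0),
             c(0, 0, 0), c(0, 0, 0))
  b <- rbind(c(6, 6, 6), c(2, 2, 2), c(0, 0, 0), c(7, 7, 7),
             c(0, 0, 0), c(0, 0, 0))
  vp <- venn_partition(toy_study(a, b))
  expect_setequal(vp$common, c("g1", "g2"))
  expect_equal(vp$specific_a, "g3")
  expect_equal(vp$specific_b, "g4")
  expect_setequal(vp$excluded, c("g5", "g6"))
})

test_that("venn partition conserves the universe on random studies", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    m <- matrix(runif(n * 6, 0, 5) * rbinom(n * 6, 1, 0.7), n, 6)
    rownames(m) <- sprintf("g%03d", seq_len(n))
    st <- expression_study(m, rep(c("a", "b"), each = 3))
    vp <- venn_partition(st, min_fpkm = 0.1,
                         min_replicate_fraction = sample(c(1 / 3, 2 / 3, 1), 1))
    parts <- c(vp$common, vp$specific_a, vp$specific_b, vp$excluded)
    expect_setequal(parts, st$genes)
    expect_length(parts, n) # pairwise disjoint
  }
})

test_that("simple_de_test handles identities and arithmetic", {
  same <- rbind(c(4, 7, 5))
  st <- toy_study(same, same)
  det <- simple_de_test(st)
  expect_equal(det$log2fc, 0)
  expect_equal(det$p_value, 1)
  expect_false(det$inf_fc)

  st2 <- toy_study(rbind(c(10, 10, 10)), rbind(c(40, 40, 40)))
  det2 <- simple_de_test(st2, pseudocount = 0)
  expect_equal(det2$log2fc, 2.0)
  expect_equal(det2$p_value, 0) # zero variance, different means

  # infinite-fold-change flag iff exactly one raw mean is zero
  st3 <- toy_study(rbind(c(0, 0, 0), c(0, 0, 0), c(3, 4, 5)),
                   rbind(c(9, 8, 10), c(0, 0, 0), c(6, 7, 8)))
  det3 <- simple_de_test(st3)
  expect_equal(det3$inf_fc, c(TRUE, FALSE, FALSE))
  expect_true(all(det3$p_value >= 0 & det3$p_value <= 1))
  expect_true(all(is.finite(det3$log2fc)))
})

test_that("q-values are the BH transform of the p-values", {
  set.seed(7)
  g <- generate_expression(synth_config(n_genes = 150, de_fraction = 0.2,
                                        effect_log2fc = 2, seed = 7))
  det <- simple_de_test(g$study)
  expect_equal(det$q_value, oracle_bh(det$p_value))
})

test_that("call_degs applies thresholds with boundary retention", {
  det <- hand_de_table(c("x", "y", "z"), log2fc = c(1.2, 3.0, 1.0),
                       q_value = c(0.04, 0.06, 0.05))
  degs <- call_degs(det)
  expect_true(degs$is_deg[1])
  expect_equal(degs$direction[1], "up_in_b")
  expect_false(degs$is_deg[2]) # q too high despite large fold change
  expect_true(degs$is_deg[3])  # both thresholds exactly at the boundary
  expect_error(call_degs(det, q_max = 0), class = "emtnet_config_error")
  expect_error(call_degs(det, q_max = 1.5), class = "emtnet_config_error")
})

test_that("call_degs equals a brute-force filter pass on a hand table", {
  set.seed(3)
  det <- hand_de_table(sprintf("g%02d", 1:10),
                       log2fc = round(runif(10, -3, 3), 2),
                       q_value = round(runif(10), 3))
  degs <- call_degs(det, q_max = 0.3, fc_min = 1.5)
  brute <- det$gene_id[det$q_value <= 0.3 & abs(det$log2fc) >= 1.5]
  expect_setequal(degs$gene_id[degs$is_deg], brute)
})

test_that("exclusive (infinite-flagged) genes are always DEGs of their condition", {
  det <- hand_de_table(c("e1", "e2"), log2fc = c(3, -3), q_value = c(0.9, 0.9),
                       mean_a = c(0, 5), mean_b = c(5, 0),
                       inf_fc = c(TRUE, TRUE))
  degs <- call_degs(det)
  expect_true(all(degs$is_deg))
  expect_equal(degs$direction, c("up_in_b", "up_in_a"))
  expect_equal(degs$exclusive_condition, c("b", "a"))
})

test_that("DEG calling is idempotent and threshold-monotone", {
  set.seed(9)
  det <- hand_de_table(sprintf("g%03d", 1:100),
                       log2fc = runif(100, -4, 4), q_value = runif(100))
  base <- call_degs(det, q_max = 0.2, fc_min = 1)
  again <- call_degs(base, q_max = 0.2, fc_min = 1)
  expect_equal(again$is_deg, base$is_deg)
  for (qm in c(0.1, 0.05, 0.01)) {
    tighter <- call_degs(det, q_max = qm, fc_min = 1)
    expect_true(all(base$gene_id[tighter$is_deg] %in%
                      base$gene_id[base$is_deg]))
  }
  for (fc in c(1.5, 2, 3)) {
    tighter <- call_degs(det, q_max = 0.2, fc_min = fc)
    expect_true(all(base$gene_id[tighter$is_deg] %in%
                      base$gene_id[base$is_deg]))
  }
})

test_that("deg_summary totals equal the per-direction sums", {
  set.seed(13)
  det <- hand_de_table(sprintf("g%03d", 1:80), log2fc = runif(80, -3, 3),
                       q_value = runif(80))
  ds <- deg_summary(call_degs(det, q_max = 0.4))
  expect_equal(ds$total, ds$up_in_a + ds$up_in_b)
})

test_that("study construction rejects invalid designs", {
  m <- matrix(1, 2, 4, dimnames = list(c("g1", "g2"), NULL))
  expect_error(expression_study(m, c("a", "a", "a", "b")),
               class = "emtnet_input_error") # 1 replicate in b
  expect_error(expression_study(m, rep("a", 4)), class = "emtnet_input_error")
  expect_error(expression_study(m, c("a", "a", "b", "c")),
               class = "emtnet_input_error")
  m2 <- m; m2[1, 1] <- -1
  expect_error(expression_study(m2, c("a", "a", "b", "b")),
               class = "emtnet_input_error")
  expect_error(simple_de_test(toy_study(rbind(c(1, 1)), rbind(c(1, 1)))),
               NA) # 2+2 replicates is the minimum valid design
})
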