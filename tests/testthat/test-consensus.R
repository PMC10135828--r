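chains_df <- function(...) {
  d <- data.frame(...)
  names(d) <- c("ligand", "receptor", "tf", "target", "weight")[seq_along(d)]
  d
}

four_chains <- function() {
  chains_df(c("L1", "L1", "L2", "L2"), c("R1", "R1", "R2", "R2"),
            c("T1", "T1", "T2", "T2"), c("G1", "G2", "G3", "G4"),
            c(0.5, 0.4, 0.3, 0.2))
}

scores_tab <- function(lig, rec, retained = TRUE) {
  s <- data.frame(ligand = lig, receptor = rec, sender = "tumor",
                  receiver = "macrophage", mean = as.numeric(retained),
                  retained = retained)
  class(s) <- c("InteractionScores", "data.frame")
  s
}

deg_tab <- function(genes, dirs = "up", p = 1e-6) {
  n <- length(genes)
  dirs <- rep_len(dirs, n)
  d <- data.frame(gene = genes, log2fc = ifelse(dirs == "up", 1, -1),
                  p = rep(p, n), p_adj = rep(p, n), pct_in = rep(1, n),
                  pct_ref = rep(1, n), direction = dirs)
  class(d) <- c("DEGTable", "data.frame")
  d
}

test_that("build_network1 deduplicates and validates", {
  ch <- chains_df(c("L1", "L1", "L2"), c("R1", "R1", "R2"),
                  c("T1", "T1", "T2"), c("G1", "G1", "G2"),
                  c(0.5, 0.3, 0.7))
  net <- build_network1(ch, "nLung", "tLung")
  expect_equal(nrow(net$chains), 2L)
  expect_equal(net$version, "1.0")
  # highest-weight duplicate kept
  expect_equal(net$chains$weight[net$chains$ligand == "L1"], 0.5)
  expect_false(any(net$chains$lr_verified))
  expect_error(build_network1(ch[0, ], "nLung", "tLung"), "empty")
})

test_that("quad networks round-trip losslessly through JSON", {
  net <- build_network1(four_chains(), "nLung", "tLung")
  net2 <- verify_lr(net, scores_tab(c("L1", "L2"), c("R1", "R2")))
  f <- tempfile(fileext = ".json")
  write_quad_network(net2, f)
  back <- read_quad_network(f)
  expect_equal(back$chains, net2$chains)
  expect_equal(back$version, net2$version)
  expect_equal(back$condition_oi, net2$condition_oi)

  # empty network round-trips too
  e <- quad_network(four_chains()[0, ], "4.0", "nLung", "tLung")
  write_quad_network(e, f)
  expect_equal(nrow(read_quad_network(f)$chains), 0L)
})

test_that("verify_lr keeps exactly the retained pairs' chains", {
  net1 <- build_network1(four_chains(), "nLung", "tLung")
  expect_warning(none <- verify_lr(net1, scores_tab("LX", "RX")), "empty")
  expect_equal(nrow(none$chains), 0L)
  expect_equal(none$version, "2.0")

  one <- verify_lr(net1, scores_tab("L1", "R1"))
  # oracle: brute-force set recomputation
  want <- four_chains()[paste(four_chains()$ligand,
                              four_chains()$receptor) %in% "L1 R1", ]
  expect_setequal(chain_keys(one$chains), chain_keys(want))
  expect_true(all(one$chains$lr_verified))
  expect_lte(nrow(one$chains), nrow(net1$chains))
})

test_that("verify_tf keeps regulon-supported chains and is idempotent", {
  net1 <- build_network1(four_chains(), "nLung", "tLung")
  net2 <- verify_lr(net1, scores_tab(c("L1", "L2"), c("R1", "R2")))
  regs <- structure(list(T1 = c(G1 = 0.9, G2 = 0.8)), class = "Regulons")
  net3 <- verify_tf(net2, regs)
  expect_setequal(net3$chains$target, c("G1", "G2"))
  expect_true(all(net3$chains$tf_verified))

  again <- verify_tf(net3, regs)
  expect_equal(again$chains[, 1:5], net3$chains[, 1:5])

  empty <- verify_tf(net2, structure(list(), class = "Regulons"))
  expect_equal(nrow(empty$chains), 0L)
})

test_that("deg_filter implements ligand-AND-downstream with direction", {
  net1 <- build_network1(four_chains(), "nLung", "tLung")
  net2 <- verify_lr(net1, scores_tab(c("L1", "L2"), c("R1", "R2")))
  regs <- structure(list(T1 = c(G1 = 0.9, G2 = 0.8),
                         T2 = c(G3 = 0.7, G4 = 0.6)), class = "Regulons")
  net3 <- verify_tf(net2, regs)

  # no DE at all -> empty 4.0
  none <- deg_filter(net3, deg_tab(character(0)), deg_tab(character(0)))
  expect_equal(nrow(none$chains), 0L)

  # ligand L1 DE + target G1 DE(down): only the (L1, G1) chain survives
  net4 <- deg_filter(net3, deg_tab("L1"), deg_tab("G1", "down"))
  expect_equal(chain_keys(net4$chains), "L1 R1 T1 G1")
  expect_equal(net4$chains$direction, "down")
  expect_true(all(net4$chains$deg_passed))
  expect_true(all(chain_keys(net4$chains) %in% chain_keys(net3$chains)))

  # downstream DE without ligand DE is not enough
  no_lig <- deg_filter(net3, deg_tab("LX"), deg_tab("G1"))
  expect_equal(nrow(no_lig$chains), 0L)
  expect_error(deg_filter(net3, NULL, deg_tab("G1")), "required")
})

test_that("count_signals counts distinct receptor/TF/target genes", {
  one <- quad_network(chains_df("L", "R", "T", "G", 1), "4.0",
                      "nLung", "tLung")
  expect_equal(count_signals(one), 3L)

  shared_tf <- quad_network(chains_df(c("L", "L"), c("R1", "R2"),
                                      c("T", "T"), c("G1", "G2"),
                                      c(1, 1)), "4.0", "nLung", "tLung")
  expect_equal(count_signals(shared_tf), 5L)   # set union, not 6

  empty <- quad_network(chains_df(character(0), character(0), character(0),
                                  character(0), numeric(0)),
                        "4.0", "nLung", "tLung")
  expect_equal(count_signals(empty), 0L)
  expect_error(count_signals(one$chains))
})

test_that("compare_stage_networks partitions the chain union exactly", {
  a <- quad_network(four_chains()[1:3, ], "4.0", "nLung", "tLung")
  b <- quad_network(four_chains()[2:4, ], "4.0", "tLung", "tL/B")
  cmp <- compare_stage_networks(a, b)
  expect_equal(nrow(cmp$shared), 2L)
  expect_equal(nrow(cmp$a_specific), 1L)
  expect_equal(nrow(cmp$b_specific), 1L)
  union_n <- length(union(chain_keys(a$chains), chain_keys(b$chains)))
  expect_equal(nrow(cmp$shared) + nrow(cmp$a_specific) +
               nrow(cmp$b_specific), union_n)

  same <- compare_stage_networks(a, a)
  expect_equal(nrow(same$a_specific), 0L)
  expect_equal(nrow(same$b_specific), 0L)

  disjoint <- compare_stage_networks(
    quad_network(four_chains()[1:2, ], "4.0", "nLung", "tLung"),
    quad_network(four_chains()[3:4, ], "4.0", "tLung", "tL/B"))
  expect_equal(nrow(disjoint$shared), 0L)

  other <- quad_network(four_chains(), "4.0", "nLung", "tLung",
                        sender = "tumor", receiver = "Tcell")
  expect_error(compare_stage_networks(a, other), "mismatched")
})

test_that("the filter cascade is monotone on a real pipeline run", {
  run <- small_pipeline_run()
  for (tag in c("nLung_tLung", "tLung_tLB")) {
    nets <- lapply(c("1.0", "2.0", "3.0", "4.0"), function(v) {
      read_quad_network(file.path(run$out, tag,
                                  sprintf("network_%s.json", v)))
    })
    keys <- lapply(nets, function(n) chain_keys(n$chains))
    for (i in 2:4) expect_true(all(keys[[i]] %in% keys[[i - 1]]))
    expect_true(all(nets[[4]]$chains$lr_verified &
                    nets[[4]]$chains$tf_verified &
                    nets[[4]]$chains$deg_passed))
  }
})
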