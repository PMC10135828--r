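# independent oracle: personalized PageRank by dense linear solve, then
# TF out-weight spreading — mirrors the documented model, not the code
oracle_potential <- function(prior, ligand, damping = 0.85) {
  walk <- prior$nodes$gene[prior$nodes$role %in%
                           c("ligand", "receptor", "signaling", "tf")]
  e <- prior$edges[prior$edges$layer %in% c("lr", "signaling"), ]
  n <- length(walk)
  P <- matrix(0, n, n, dimnames = list(walk, walk))
  P[cbind(match(e$from, walk), match(e$to, walk))] <- e$weight
  rs <- rowSums(P)
  restart <- as.numeric(walk == ligand)
  for (i in seq_len(n)) {
    if (rs[i] > 0) P[i, ] <- P[i, ] / rs[i]   # dangling rows absorb
  }
  # pi = (1-d) e (I - dP')^{-1}  <=>  (I - d t(P')) pi^T = (1-d) e^T
  pi <- solve(diag(n) - damping * t(P), (1 - damping) * restart)
  names(pi) <- walk
  gr <- prior$edges[prior$edges$layer == "gene_regulatory", ]
  genes <- prior$nodes$gene[prior$nodes$role == "target"]
  out <- setNames(numeric(length(genes)), genes)
  for (tf in unique(gr$from)) {
    sub <- gr[gr$from == tf, ]
    out[sub$to] <- out[sub$to] + pi[[tf]] * sub$weight / sum(sub$weight)
  }
  out
}

test_that("regulatory_potential matches a dense linear solve", {
  p <- toy_prior()
  for (d in c(0.85, 0.5)) {
    got <- regulatory_potential(p, "LIG1", damping = d)
    want <- oracle_potential(p, "LIG1", damping = d)
    expect_equal(as.numeric(got[names(want)]), as.numeric(want),
                 tolerance = 1e-8)
  }
  # and on random layered graphs up to 10 walk nodes
  for (s in 1:5) {
    rp <- suppressMessages(generate_prior_network(2, 3, 2, 3, 6, 0.4,
                                                  seed = s))
    got <- regulatory_potential(rp, "LIG1")
    want <- oracle_potential(rp, "LIG1")
    expect_equal(as.numeric(got[names(want)]), as.numeric(want),
                 tolerance = 1e-8)
  }
})

test_that("regulatory_potential handles degenerate ligands and bad input", {
  nodes <- data.frame(gene = c("L1", "L2", "R1", "TF1", "G1"),
                      role = c("ligand", "ligand", "receptor", "tf",
                               "target"))
  edges <- data.frame(from = c("L1", "R1", "TF1"), to = c("R1", "TF1", "G1"),
                      weight = 0.5, layer = c("lr", "signaling",
                                              "gene_regulatory"))
  p <- prior_network(nodes, edges)
  # L2 has no outgoing edges: all-zero potential
  expect_true(all(regulatory_potential(p, "L2") == 0))
  expect_gt(regulatory_potential(p, "L1")[["G1"]], 0)
  expect_error(regulatory_potential(p, "R1"), "not a ligand")
  expect_error(regulatory_potential(p, "NOPE"), "not a ligand")
})

test_that("potentials are monotone in path weight and bounded", {
  # two parallel routes to distinct genes; the heavier route scores higher
  nodes <- data.frame(
    gene = c("L", "Ra", "Rb", "TFa", "TFb", "Ga", "Gb"),
    role = c("ligand", "receptor", "receptor", "tf", "tf",
             "target", "target"))
  edges <- data.frame(
    from = c("L", "L", "Ra", "Rb", "TFa", "TFb"),
    to = c("Ra", "Rb", "TFa", "TFb", "Ga", "Gb"),
    weight = c(0.9, 0.3, 0.9, 0.3, 0.9, 0.9),
    layer = c("lr", "lr", "signaling", "signaling",
              "gene_regulatory", "gene_regulatory"))
  p <- prior_network(nodes, edges)
  pv <- regulatory_potential(p, "L")
  expect_gt(pv[["Ga"]], pv[["Gb"]])
  expect_true(all(pv >= 0) && sum(pv) <= 1)
  # deleting the heavy edge never increases any score
  p2 <- prior_network(nodes, edges[edges$from != "Ra", ])
  pv2 <- regulatory_potential(p2, "L")
  expect_true(all(pv2 <= pv + 1e-12))
})

test_that("rank_ligands orders by activity with deterministic ties", {
  universe <- sprintf("G%d", 1:10)
  degs <- universe[1:3]
  ind_pot <- setNames(as.numeric(universe %in% degs) * 0.2, universe)
  flat_pot <- setNames(rep(0.1, 10), universe)
  ranked <- rank_ligands(list(B_perfect = ind_pot, A_flat = flat_pot),
                         degs, universe)
  expect_equal(ranked$ligand[1], "B_perfect")
  expect_equal(ranked$activity[1], 1)
  expect_equal(ranked$activity[2], 0)   # zero-variance potential
  expect_equal(formals(rank_ligands)$top_n, 30)

  ties <- rank_ligands(list(b = ind_pot, a = ind_pot), degs, universe)
  expect_equal(ties$ligand, c("a", "b"))
  expect_equal(nrow(rank_ligands(rep(list(ind_pot), 40) |>
                                   setNames(sprintf("L%02d", 1:40)),
                                 degs, universe)), 30)
  expect_error(rank_ligands(list(x = ind_pot), character(0), universe),
               "no receiver signal")
})

test_that("true ligands rank above decoys across simulated worlds", {
  hits <- vapply(1:20, function(s) {
    ds <- simulate_dataset(n_cells = 60, n_patients = 0, seed = 400 + s)
    nm <- normalize_log1p(qc_filter(ds$counts, ds$cells)$counts)
    cells <- ds$cells[match(colnames(nm), ds$cells$cell_id), ]
    rcv_oi <- cells$cell_id[cells$cell_type == "macrophage" &
                            cells$condition == "tLung"]
    rcv_ref <- cells$cell_id[cells$cell_type == "macrophage" &
                             cells$condition == "nLung"]
    degs <- rank_sum_deg(nm, rcv_oi, rcv_ref)
    universe <- ds$prior$nodes$gene[ds$prior$nodes$role == "target"]
    de <- intersect(degs$gene[degs$p_adj < 0.05], universe)
    if (length(de) == 0) return(NA)
    ligs <- ds$prior$nodes$gene[ds$prior$nodes$role == "ligand"]
    pots <- lapply(setNames(nm = ligs),
                   function(l) regulatory_potential(ds$prior, l))
    ranked <- rank_ligands(pots, de, universe)
    # cascades active in tLung (vs nLung): cascades 1 and 3
    true_ligs <- vapply(ds$truth$cascades[c(1, 3)], `[[`, "", "ligand")
    all(match(true_ligs, ranked$ligand) <= 2)
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("extract_paths returns exactly the brute-force best paths", {
  p <- toy_prior()
  quads <- oracle_enumerate_quads(p)
  # single best path per target
  got <- extract_paths(p, "LIG1", c("REC1", "REC2"), c("TGT1", "TGT2"))
  for (g in c("TGT1", "TGT2")) {
    best <- quads[quads$target == g, ]
    best <- best[which.max(best$weight), ]
    row <- got[got$target == g, ]
    expect_equal(row$receptor, best$receptor)
    expect_equal(row$tf, best$tf)
    expect_equal(row$weight, best$weight, tolerance = 1e-12)
  }
  # k = 2: second-best must match enumeration too
  two <- extract_paths(p, "LIG1", c("REC1", "REC2"), "TGT2",
                       k_per_target = 2)
  want <- quads[quads$target == "TGT2", ]
  want <- want[order(-want$weight), ]
  expect_equal(two$weight, want$weight[1:2], tolerance = 1e-12)
  expect_equal(two$tf, want$tf[1:2])

  # unreachable target dropped with a warning, never fabricated
  expect_warning(none <- extract_paths(p, "LIG1", "REC1", "NOPE"),
                 "no path")
  expect_equal(nrow(none), 0L)

  # randomized cross-check including signaling intermediates
  for (s in 1:5) {
    rp <- suppressMessages(generate_prior_network(2, 3, 3, 3, 8, 0.35,
                                                  seed = 50 + s))
    q <- oracle_enumerate_quads(rp)
    if (is.null(q)) next
    q1 <- q[q$ligand == "LIG1", ]
    if (nrow(q1) == 0) next
    got <- extract_paths(rp, "LIG1",
                         rp$nodes$gene[rp$nodes$role == "receptor"],
                         unique(q1$target))
    for (g in unique(q1$target)) {
      expect_equal(got$weight[got$target == g], max(q1$weight[q1$target == g]),
                   tolerance = 1e-12)
    }
  }
})
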