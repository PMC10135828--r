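test_that("generate_prior_network builds the minimal layered graph", {
  p <- generate_prior_network(1, 1, 0, 1, 1, edge_density = 1, seed = 1)
  expect_equal(nrow(p$edges), 3L)
  expect_setequal(p$edges$layer, c("lr", "signaling", "gene_regulatory"))
  expect_equal(p$edges$from[p$edges$layer == "lr"], "LIG1")
  expect_equal(p$edges$to[p$edges$layer == "gene_regulatory"], "TGT1")
})

test_that("generate_prior_network is deterministic and repairs connectivity", {
  a <- suppressMessages(generate_prior_network(5, 5, 10, 5, 50, 0.2, seed = 7))
  b <- suppressMessages(generate_prior_network(5, 5, 10, 5, 50, 0.2, seed = 7))
  expect_identical(a$edges, b$edges)
  # oracle: brute-force reachability for every ligand
  for (l in a$nodes$gene[a$nodes$role == "ligand"]) {
    expect_true(oracle_ligand_reaches(a, l))
  }
  # invariants hold across seeds and densities
  for (s in 1:5) {
    p <- suppressMessages(generate_prior_network(4, 4, 3, 4, 10, 0.15,
                                                 seed = s))
    expect_true(all(p$edges$weight > 0 & p$edges$weight <= 1))
    expect_false(any(p$edges$from == p$edges$to))
    for (l in p$nodes$gene[p$nodes$role == "ligand"]) {
      expect_true(oracle_ligand_reaches(p, l))
    }
  }
})

test_that("prior_network rejects invalid structures", {
  nodes <- data.frame(gene = c("L", "R", "G"),
                      role = c("ligand", "receptor", "target"))
  expect_error(prior_network(nodes, data.frame(
    from = "R", to = "L", weight = 0.5, layer = "lr")), "ligand")
  expect_error(prior_network(nodes, data.frame(
    from = "L", to = "R", weight = 0, layer = "lr")), "weight")
  expect_error(prior_network(nodes, data.frame(
    from = "L", to = "L", weight = 0.5, layer = "lr")), "self-loops")
})

test_that("prior network round-trips through edge-list TSV", {
  p <- suppressMessages(generate_prior_network(3, 3, 2, 3, 8, 0.3, seed = 2))
  ep <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  write_prior_network(p, ep, np)
  q <- read_prior_network(ep, np)
  expect_equal(p$nodes, q$nodes)
  expect_equal(p$edges, q$edges, tolerance = 1e-12)
})

test_that("generate_truth samples valid distinct paths", {
  p <- suppressMessages(generate_prior_network(5, 5, 4, 5, 20, 0.2, seed = 11))
  empty <- generate_truth(p, 0, seed = 1)
  expect_length(empty$cascades, 0L)
  expect_error(generate_truth(p, 3, effect_log2fc = 0), "positive")

  tr <- generate_truth(p, 3, effect_log2fc = 2, seed = 3)
  expect_length(tr$cascades, 3L)
  quads <- oracle_enumerate_quads(p)
  for (cs in tr$cascades) {
    # membership oracle: the (L, R, TF) path and every target must appear
    # in the exhaustive enumeration
    hit <- quads[quads$ligand == cs$ligand & quads$receptor == cs$receptor &
                 quads$tf == cs$tf, ]
    expect_true(nrow(hit) > 0)
    expect_setequal(cs$targets, unique(hit$target))
  }
  # sampled without replacement: distinct (L, R, TF)
  keys <- vapply(tr$cascades, function(cs) paste(cs$ligand, cs$receptor,
                                                 cs$tf), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("generate_truth errors when asked for more cascades than paths", {
  p <- generate_prior_network(1, 1, 0, 1, 2, edge_density = 1, seed = 1)
  expect_error(generate_truth(p, 5, seed = 1), "deficit")
})

test_that("identifiable truth yields gene-disjoint, uniquely-routed cascades", {
  ds <- simulate_dataset(n_cells = 20, n_patients = 0, seed = 3)
  tr <- ds$truth
  genes <- unlist(lapply(tr$cascades, function(cs)
    c(cs$ligand, cs$receptor, cs$tf)))
  expect_equal(anyDuplicated(genes), 0L)
  quads <- oracle_enumerate_quads(ds$prior)
  for (cs in tr$cascades) {
    routes <- unique(quads[quads$tf == cs$tf, c("ligand", "receptor")])
    expect_equal(nrow(routes), 1L)
    expect_equal(routes$ligand, cs$ligand)
    expect_equal(routes$receptor, cs$receptor)
  }
})

test_that("simulate_counts matches its negative-binomial law under the null", {
  p <- generate_prior_network(2, 2, 0, 2, 4, edge_density = 1, seed = 5)
  tr <- generate_truth(p, 0, seed = 1)
  des <- simulation_design(cell_types = c("tumor", "macrophage"),
                           conditions = "tLung", n_cells = 250,
                           patients_per_condition = 1)
  sim <- simulate_counts(p, tr, des, baseline_mean = 1, dispersion = 2,
                         n_background_genes = 20, seed = 9)
  # depth factor is lognormal(0, 0.25): E[count] = baseline * exp(0.25^2/2)
  mu_eff <- 1 * exp(0.25^2 / 2)
  non_mt <- !startsWith(rownames(sim$counts), "MT-")
  for (ty in c("tumor", "macrophage")) {
    cols <- sim$cells$cell_id[sim$cells$cell_type == ty]
    gm <- Matrix::rowMeans(sim$counts[non_mt, cols])
    # 3 MC standard errors of the stratum mean (var = mu + mu^2/size, plus
    # depth-factor variance), n = 250 cells
    se <- sqrt((mu_eff + mu_eff^2 / 2 + 0.1) / length(cols))
    expect_true(all(abs(gm - mu_eff) < 3.5 * se))
  }
})

test_that("simulate_counts realizes the planted effect size", {
  p <- generate_prior_network(2, 2, 0, 2, 4, edge_density = 1, seed = 5)
  tr <- generate_truth(p, 1, effect_log2fc = 2, active_map = "tLung",
                       seed = 2)
  des <- simulation_design(conditions = c("nLung", "tLung"), n_cells = 300,
                           patients_per_condition = 1)
  sim <- simulate_counts(p, tr, des, seed = 4)
  lig <- tr$cascades[[1]]$ligand
  m <- function(cond) {
    cols <- sim$cells$cell_id[sim$cells$cell_type == "tumor" &
                              sim$cells$condition == cond]
    mean(sim$counts[lig, cols])
  }
  expect_lt(abs(log2(m("tLung") / m("nLung")) - 2), 0.3)
  # receiver-side co-elevation of receptor/TF/targets
  cs <- tr$cascades[[1]]
  rc <- function(g, cond) {
    cols <- sim$cells$cell_id[sim$cells$cell_type == "macrophage" &
                              sim$cells$condition == cond]
    mean(sim$counts[g, cols])
  }
  for (g in c(cs$receptor, cs$tf, cs$targets)) {
    expect_lt(abs(log2(rc(g, "tLung") / rc(g, "nLung")) - 2), 0.45)
  }
})

test_that("simulate_counts is reproducible and validates its design", {
  p <- generate_prior_network(1, 1, 0, 1, 1, edge_density = 1, seed = 1)
  tr <- generate_truth(p, 0, seed = 1)
  des <- simulation_design(n_cells = 30, patients_per_condition = 1)
  a <- simulate_counts(p, tr, des, seed = 8)
  b <- simulate_counts(p, tr, des, seed = 8)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cells, b$cells)

  bad <- des; bad$condition[1] <- "kidney"
  expect_error(simulate_counts(p, tr, bad, seed = 1), "condition")
  solo <- des[des$cell_type == "tumor", ]
  expect_error(simulate_counts(p, tr, solo, seed = 1), "receiver")
})

test_that("default QC passes at least 95% of simulated cells", {
  ds <- simulate_dataset(n_cells = 100, n_patients = 0, seed = 12)
  qc <- qc_filter(ds$counts, ds$cells)
  expect_gte(qc$report$n_retained / qc$report$n_input, 0.95)
})

test_that("simulate_survival obeys its censoring contract", {
  s0 <- simulate_survival(50, beta = 0, censor_rate = 0, seed = 1)
  expect_true(all(s0$event == 1L))
  expect_true(all(s0$time > 0))

  s3 <- simulate_survival(400, beta = 0, censor_rate = 0.3, seed = 2)
  expect_lt(abs(mean(s3$event == 0) - 0.3), 0.08)

  # protective biomarker: high group lives longer (closed-form hazard order)
  sp <- simulate_survival(400, beta = -1, censor_rate = 0, seed = 3)
  hi <- sp$biomarker > stats::median(sp$biomarker)
  expect_gt(stats::median(sp$time[hi]), stats::median(sp$time[!hi]))

  expect_error(simulate_survival(5, seed = 1))
  expect_error(simulate_survival(20, censor_rate = 1, seed = 1))
})

test_that("type-I error of median-split log-rank on null cohorts is ~5%", {
  # beta = 0: biomarker carries no hazard information
  rej <- vapply(1:200, function(s) {
    sv <- simulate_survival(60, beta = 0, censor_rate = 0.2, seed = s)
    g <- setNames(ifelse(sv$biomarker > stats::median(sv$biomarker),
                         "high", "low"), sv$patient_id)
    km_logrank(sv, g)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})
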