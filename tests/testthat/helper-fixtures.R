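# Shared fixtures, built in code. Everything is deterministic.

# tiny hand-specified prior: LIG1 -> REC1 -> TF1 -> {TGT1, TGT2}
#                            LIG1 -> REC2 -> TF2 -> {TGT2}
toy_prior <- function() {
  nodes <- data.frame(
    gene = c("LIG1", "REC1", "REC2", "TF1", "TF2", "TGT1", "TGT2"),
    role = c("ligand", "receptor", "receptor", "tf", "tf",
             "target", "target"))
  edges <- data.frame(
    from = c("LIG1", "LIG1", "REC1", "REC2", "TF1", "TF1", "TF2"),
    to = c("REC1", "REC2", "TF1", "TF2", "TGT1", "TGT2", "TGT2"),
    weight = c(0.9, 0.4, 0.8, 0.5, 0.7, 0.6, 0.9),
    layer = c("lr", "lr", "signaling", "signaling",
              "gene_regulatory", "gene_regulatory", "gene_regulatory"))
  prior_network(nodes, edges)
}

# normalized matrix with exact cluster means, for interaction-score tests
cluster_mean_matrix <- function(ligand_sender, receptor_receiver,
                                n_snd = 3, n_rcv = 3) {
  m <- rbind(LIGX = c(ligand_sender, rep(0, n_rcv)),
             RECX = c(rep(0, n_snd), receptor_receiver))
  colnames(m) <- c(sprintf("s%d", seq_len(n_snd)),
                   sprintf("r%d", seq_len(n_rcv)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

toy_cells <- function(n_snd = 3, n_rcv = 3) {
  data.frame(cell_id = c(sprintf("s%d", seq_len(n_snd)),
                         sprintf("r%d", seq_len(n_rcv))),
             cell_type = rep(c("tumor", "macrophage"), c(n_snd, n_rcv)),
             condition = "tLung",
             patient = "P1")
}

# small count matrix with chosen per-cell mito/umi/gene structure
counts_from_dense <- function(m, genes, cells) {
  dimnames(m) <- list(genes, cells)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# independent brute-force reachability used as oracle against the
# generator's connectivity guarantee
oracle_ligand_reaches <- function(prior, ligand) {
  e <- prior$edges
  tgt <- prior$nodes$gene[prior$nodes$role == "target"]
  frontier <- ligand
  seen <- character(0)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(e$to[e$from %in% frontier], seen)
  }
  any(tgt %in% seen)
}

# independent full path enumeration: all L->R->(S)->TF->G paths with
# weight products (oracle for extract_paths and truth membership)
oracle_enumerate_quads <- function(prior) {
  e <- prior$edges
  role <- setNames(prior$nodes$role, prior$nodes$gene)
  lr <- e[e$layer == "lr", ]
  sg <- e[e$layer == "signaling", ]
  gr <- e[e$layer == "gene_regulatory", ]
  out <- list()
  for (i in seq_len(nrow(lr))) {
    r <- lr$to[i]
    hop1 <- sg[sg$from == r, ]
    for (j in seq_len(nrow(hop1))) {
      mid <- hop1$to[j]
      legs <- if (role[[mid]] == "tf") {
        data.frame(tf = mid, w = lr$weight[i] * hop1$weight[j],
                   sig = NA_character_)
      } else {
        hop2 <- sg[sg$from == mid & role[sg$to] == "tf", ]
        if (nrow(hop2) == 0) next
        data.frame(tf = hop2$to,
                   w = lr$weight[i] * hop1$weight[j] * hop2$weight,
                   sig = mid)
      }
      for (k in seq_len(nrow(legs))) {
        ge <- gr[gr$from == legs$tf[k], ]
        for (m in seq_len(nrow(ge))) {
          out[[length(out) + 1L]] <- data.frame(
            ligand = lr$from[i], receptor = r, signaling = legs$sig[k],
            tf = legs$tf[k], target = ge$to[m],
            weight = legs$w[k] * ge$weight[m])
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

chain_keys <- function(d) paste(d$ligand, d$receptor, d$tf, d$target)

# cells along a 1-D expression gradient; nLung occupies the low end
gradient_world <- function(n = 150, n_genes = 6, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    pos <- sort(runif(n, 0, 4))
    loadings <- runif(n_genes, 0.5, 1.5)
    m <- outer(loadings, pos) + if (noise > 0)
      matrix(rnorm(n_genes * n, sd = noise), n_genes, n) else 0
    m <- pmax(m, 0)
    genes <- sprintf("SIG%d", seq_len(n_genes))
    cells <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n)),
      cell_type = "macrophage",
      condition = ifelse(pos < quantile(pos, 1 / 3), "nLung",
                         ifelse(pos < quantile(pos, 2 / 3), "tLung", "tL/B")),
      patient = "P1")
    list(normed = counts_from_dense(m, genes, cells$cell_id),
         cells = cells, pos = pos)
  })
}

# one small end-to-end pipeline run on the benchmark world, reused by
# several structural tests (built once per test session)
small_pipeline_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    td <- file.path(tempdir(), "quadnet-small-run")
    ds <- simulate_dataset(td, n_cells = 120, n_patients = 0, seed = 7)
    out <- file.path(td, "out")
    suppressMessages(run_pipeline(ds$config_path, out))
    cache <<- list(dataset = ds, out = out, dir = td)
    cache
  }
})
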