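#' Run the full consensus-network pipeline
#'
#' Executes, for each configured (reference, interest) condition pair:
#' QC filtering, log-normalization, sender and receiver differential
#' expression, permutation-verified ligand-receptor scoring, diffusion
#' ligand ranking, signaling-path extraction, co-expression regulons and
#' the Network 1.0 -> 4.0 consensus filters; then compares the stage
#' networks, orders receiver cells in pseudotime on the union of
#' Network-4.0 signal genes, and (when a survival table is configured)
#' runs the optimal-cutpoint Kaplan-Meier analysis.  Every intermediate is
#' written under `out_dir` together with a manifest recording input
#' hashes, the seed and per-stage outputs.  All randomized stages derive
#' their stream from the config seed via [stage_seed()].
#'
#' @param config a [read_pipeline_config()] object (or a path to one).
#' @param out_dir artifact directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("quadnet")),
                   inputs = lapply(config$paths, function(p) {
                     list(path = p, md5 = unname(tools::md5sum(p)))
                   }),
                   stages = list())
  log_info <- function(...) message("[INFO] ", sprintf(...))
  emit <- function(stage, files) {
    manifest$stages[[stage]] <<- files
    log_info("%s: %s", stage, paste(basename(unlist(files)), collapse = ", "))
  }
  fail <- function(stage, err) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  # ---- load ----
  counts <- run_stage("load", read_counts(config$paths$counts_mtx,
                                          config$paths$genes,
                                          config$paths$barcodes))
  cells <- run_stage("load", read_cell_table(config$paths$cells))
  prior <- run_stage("load", read_prior_network(config$paths$prior_edges,
                                                config$paths$prior_nodes))
  run_stage("load", assert_that(all(colnames(counts) %in% cells$cell_id),
                                "count matrix cells missing from cell table"))
  cells <- cells[match(colnames(counts), cells$cell_id), , drop = FALSE]
  log_info("loaded %d genes x %d cells, prior with %d edges",
           nrow(counts), ncol(counts), nrow(prior$edges))

  # ---- qc + normalize ----
  qc <- run_stage("qc", qc_filter(counts, cells, config$thresholds$qc))
  jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("qc", file.path(out_dir, "qc_report.json"))
  normed <- run_stage("normalize", normalize_log1p(qc$counts))
  cells <- qc$cells

  th <- config$thresholds
  sender <- config$sender; receiver <- config$receiver
  pair_tag <- function(pr) paste(gsub("[^A-Za-z]", "", pr[1]),
                                 gsub("[^A-Za-z]", "", pr[2]), sep = "_")
  nets4 <- list()

  for (pr in config$condition_pairs) {
    ref <- pr[[1]]; oi <- pr[[2]]
    tag <- pair_tag(pr)
    pdir <- file.path(out_dir, tag)
    dir.create(pdir, showWarnings = FALSE)
    in_pair <- cells$condition %in% c(ref, oi)

    # differential expression, interest vs reference, per population
    degs <- run_stage(paste0("deg:", tag), {
      grab <- function(type, cond) {
        cells$cell_id[cells$cell_type == type & cells$condition == cond]
      }
      list(sender = rank_sum_deg(normed, grab(sender, oi), grab(sender, ref)),
           receiver = rank_sum_deg(normed, grab(receiver, oi),
                                   grab(receiver, ref)))
    })
    write.table(degs$sender, file.path(pdir, "degs_sender.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(degs$receiver, file.path(pdir, "degs_receiver.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit(paste0("deg:", tag),
         file.path(pdir, c("degs_sender.tsv", "degs_receiver.tsv")))

    # permutation-verified L-R scoring on the pair's cells
    lr_pairs <- prior$edges[prior$edges$layer == "lr", c("from", "to")]
    names(lr_pairs) <- c("ligand", "receptor")
    scores <- run_stage(paste0("lrtest:", tag),
      permutation_test(normed[, cells$cell_id[in_pair], drop = FALSE],
                       cells[in_pair, , drop = FALSE],
                       unique(lr_pairs), sender, receiver,
                       n_perm = th$n_perm,
                       seed = stage_seed(config$seed, paste0("lrtest:", tag))))
    write.table(scores, file.path(pdir, "lr_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit(paste0("lrtest:", tag), file.path(pdir, "lr_scores.tsv"))

    # diffusion potentials and ligand ranking against receiver DEGs
    universe <- prior_genes_by_role(prior, "target")
    receiver_de <- intersect(degs$receiver$gene[degs$receiver$p_adj < th$alpha],
                             universe)
    ranked <- run_stage(paste0("ligands:", tag), {
      pots <- lapply(setNames(nm = prior_genes_by_role(prior, "ligand")),
                     function(l) regulatory_potential(prior, l))
      rank_ligands(pots, receiver_de, universe,
                   top_n = th$top_n_ligands)
    })
    write.table(ranked, file.path(pdir, "ligand_activities.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit(paste0("ligands:", tag), file.path(pdir, "ligand_activities.tsv"))

    # chains for the top ligands over all structurally possible receptors
    net1 <- run_stage(paste0("network:", tag), {
      all_receptors <- prior_genes_by_role(prior, "receptor")
      chains <- do.call(rbind, lapply(ranked$ligand, function(l) {
        pv <- regulatory_potential(prior, l)
        tg <- names(pv)[pv > 0]
        if (length(tg) == 0L) return(NULL)
        extract_paths(prior, l, all_receptors, tg)
      }))
      build_network1(chains, ref, oi, sender, receiver)
    })
    net2 <- run_stage(paste0("network:", tag), verify_lr(net1, scores))
    regs <- run_stage(paste0("regulons:", tag), {
      rcv_cells <- cells$cell_id[in_pair & cells$cell_type == receiver]
      imp <- coexpression_importance(
        normed[, rcv_cells, drop = FALSE],
        tfs = prior_genes_by_role(prior, "tf"),
        targets = universe, method = "correlation",
        seed = stage_seed(config$seed, paste0("regulons:", tag)))
      build_regulons(imp, top_k = th$top_k,
                     min_importance = th$min_importance)
    })
    write_regulons(regs, file.path(pdir, "regulons.json"))
    emit(paste0("regulons:", tag), file.path(pdir, "regulons.json"))
    net3 <- run_stage(paste0("network:", tag), verify_tf(net2, regs))
    net4 <- run_stage(paste0("network:", tag),
                      deg_filter(net3, degs$sender, degs$receiver,
                                 alpha = th$alpha))
    for (v in list(net1, net2, net3, net4)) {
      write_quad_network(v, file.path(pdir, sprintf("network_%s.json",
                                                    v$version)))
      write_quad_network_tsv(v, file.path(pdir, sprintf("network_%s.tsv",
                                                        v$version)))
    }
    emit(paste0("network:", tag),
         file.path(pdir, sprintf("network_%s.json",
                                 c("1.0", "2.0", "3.0", "4.0"))))
    log_info("pair %s -> %s: chains %d/%d/%d/%d, %d signal(s)", ref, oi,
             nrow(net1$chains), nrow(net2$chains), nrow(net3$chains),
             nrow(net4$chains), count_signals(net4))
    nets4[[tag]] <- net4
  }

  # ---- stage comparison ----
  if (length(nets4) >= 2L) {
    cmp <- run_stage("compare",
                     compare_stage_networks(nets4[[1]], nets4[[2]]))
    jsonlite::write_json(cmp, file.path(out_dir, "network_comparison.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
    emit("compare", file.path(out_dir, "network_comparison.json"))
  }

  # ---- trajectory on union of signal genes ----
  sig <- sort(unique(unlist(lapply(nets4, signal_genes))))
  rcv_all <- cells$cell_id[cells$cell_type == receiver]
  if (length(sig) >= 2L && length(rcv_all) >= 10L &&
      length(intersect(sig, rownames(normed))) >= 2L) {
    traj <- run_stage("trajectory", {
      feats <- signal_features(normed, rcv_all, sig)
      pseudotime_order(feats, cells[match(rcv_all, cells$cell_id), ,
                                    drop = FALSE],
                       root_condition = config$condition_pairs[[1]][1],
                       n_states = min(config$n_states, length(rcv_all)),
                       seed = stage_seed(config$seed, "trajectory"))
    })
    write.table(traj, file.path(out_dir, "pseudotime.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    comp <- state_composition(traj, cells)
    write.table(as.data.frame.matrix(comp),
                file.path(out_dir, "state_composition.tsv"),
                sep = "\t", quote = FALSE)
    emit("trajectory",
         file.path(out_dir, c("pseudotime.tsv", "state_composition.tsv")))
  } else {
    log_info("trajectory skipped: fewer than 2 signal genes in Network 4.0")
  }

  # ---- survival (optional) ----
  if (!is.null(config$paths$survival)) {
    surv_res <- run_stage("survival", {
      surv <- read.delim(config$paths$survival, stringsAsFactors = FALSE)
      cp <- optimal_cutpoint(surv, minprop = th$minprop)
      grp <- setNames(ifelse(surv$biomarker > cp$cutoff, "high", "low"),
                      surv$patient_id)
      km <- km_logrank(surv, grp)
      list(cutoff = cp$cutoff, cutpoint_chi2 = cp$chi2,
           selection_biased = cp$selection_biased,
           logrank_chi2 = km$logrank_chi2, p = km$p)
    })
    jsonlite::write_json(surv_res, file.path(out_dir, "survival.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("survival", file.path(out_dir, "survival.json"))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_info("pipeline complete; manifest at %s",
           file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
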