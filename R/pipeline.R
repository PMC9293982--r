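# End-to-end orchestration: QC -> structure -> selection scans -> candidate
# sets -> SEGS -> association, with a manifest recording every parameter
# decision so a run can be reproduced from its own output.

default_pipeline_config <- function() {
  list(
    vcf = NULL, pop_map = NULL, gff = NULL,
    expression = NULL,                    # list(fpkm=, stages=) or NULL
    focal_pops = NULL,                    # populations scanned by iHS
    comparisons = NULL,                   # list(list(name=, a=, b=))
    qc = list(min_call_rate = 0.90, min_maf = 0.05, min_hwe_p = 1e-6),
    ld = list(window_snps = 50, step_snps = 10, r2_max = 0.1,
              decay_max_bp = 5e5, decay_bin_bp = 1e3),
    sweep = list(ehh_cutoff = 0.05, core_maf_min = 0.05, freq_bins = 20,
                 edge_policy = "discard"),
    anc_policy = "major_allele",
    fractions = c(0.01, 0.05),
    tails = list(ihs = "two_sided", fst = "upper", xpehh = "two_sided",
                 rsb = "two_sided"),
    flank_bp = 50000,
    cgs_rule = "union", cgs_fraction = 0.01,
    segs_fraction = 0.07,
    n_components = 2,
    seed = 1)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(
    config, simplifyVector = TRUE)
  if (!is.null(config$config)) config <- config$config  # manifest re-feed
  out <- utils::modifyList(default_pipeline_config(), config)
  for (f in c("vcf", "pop_map")) {
    if (is.null(out[[f]])) stop("pipeline config error: '", f, "' missing")
    if (!file.exists(out[[f]]))
      stop("pipeline config error: file not found: ", out[[f]])
  }
  if (is.null(out$comparisons)) stop("pipeline config error: no comparisons")
  # comparisons may arrive as a data.frame-ish structure from JSON
  if (is.data.frame(out$comparisons))
    out$comparisons <- lapply(seq_len(nrow(out$comparisons)), function(i)
      as.list(out$comparisons[i, ]))
  out
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes QC, population structure (PCA, p-distance/NJ, LD pruning and
#' decay), the four selection scans (iHS within the focal populations;
#' FST/xp-EHH/Rsb for every configured pairing), candidate gene sets at the
#' 1% and 5% thresholds with UpSet intersections, the CGS, and -- when
#' expression input is present -- SEGS construction and the CGS-SEGS
#' association. All products are plain TSV/JSON files under `out_dir`, and
#' `manifest.json` records the fully resolved configuration (every default
#' made explicit) so that feeding the manifest back as the config
#' reproduces the run.
#'
#' @param config a config list, or path to a JSON config/manifest. Required
#'   fields: `vcf`, `pop_map`, `comparisons` (list of `list(name, a, b)`),
#'   `focal_pops`; everything else defaults as in the manifest.
#' @param out_dir output directory.
#' @return invisibly, a list with the key in-memory results.
#' @export
run_all <- function(config, out_dir) {
  cfg <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  set.seed(cfg$seed)
  msg <- function(...) message("[desertsweep] ", ...)

  g <- stage_run("input", {
    pm <- utils::read.table(cfg$pop_map, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    read_vcf(cfg$vcf, pm)
  })

  msg("qc: ", ncol(g$calls), " SNPs in")
  qc_res <- stage_run("qc", apply_qc(g, qc_thresholds(
    cfg$qc$min_call_rate, cfg$qc$min_maf, cfg$qc$min_hwe_p)))
  g <- qc_res$genotypes
  jsonlite::write_json(qc_res$report[c("n_input", "n_fail_callrate",
                                       "n_fail_maf", "n_fail_hwe",
                                       "n_retained")],
                       fp("qc_report.json"), auto_unbox = TRUE)
  data.table::fwrite(qc_res$report$snp_report, fp("qc_snps.tsv"), sep = "\t")
  msg("qc: ", ncol(g$calls), " SNPs retained")

  stage_run("structure", {
    pc <- pca(g, cfg$n_components)
    data.table::fwrite(data.frame(sample = g$samples, pop = g$pops,
                                  pc$coords), fp("pca_scores.tsv"),
                       sep = "\t")
    dm <- p_distance_matrix(g)
    utils::write.table(dm$d, fp("p_distance.tsv"), sep = "\t", quote = FALSE)
    write_newick(neighbor_joining(dm), fp("nj_tree.nwk"))
    kept <- ld_prune(g, cfg$ld$window_snps, cfg$ld$step_snps, cfg$ld$r2_max)
    data.table::fwrite(data.frame(id = g$snps$id[kept]),
                       fp("pruned_snps.tsv"), sep = "\t")
    decay <- ld_decay(g, cfg$ld$decay_max_bp, cfg$ld$decay_bin_bp)
    data.table::fwrite(decay, fp("ld_decay.tsv"), sep = "\t")
  })

  haps <- stage_run("phasing", to_haplotypes(g, cfg$anc_policy))
  swc <- sweep_config(cfg$sweep$ehh_cutoff, cfg$sweep$core_maf_min,
                      cfg$sweep$freq_bins, cfg$sweep$edge_policy)

  scans <- list()
  scans[["ihs.focal"]] <- stage_run("scan_ihs", {
    focal <- hap_subset(haps, cfg$focal_pops)
    st <- flag_significance(ihs(focal, swc), cfg$tails$ihs)
    write_score_table(st, fp("score_ihs_focal.tsv"))
    st
  })
  for (cmp in cfg$comparisons) {
    nm <- cmp$name
    pair <- stage_run(paste0("scan_", nm), {
      ha <- hap_subset(haps, unlist(cmp$a))
      hb <- hap_subset(haps, unlist(cmp$b))
      ga <- which(g$pops %in% unlist(cmp$a))
      gb <- which(g$pops %in% unlist(cmp$b))
      out <- list()
      for (stat in c("fst", "xpehh", "rsb")) {
        st <- switch(stat,
                     fst = wc_fst(g, ga, gb),
                     xpehh = xpehh(ha, hb, swc),
                     rsb = rsb(ha, hb, swc))
        st <- flag_significance(st, cfg$tails[[stat]])
        write_score_table(st, fp(sprintf("score_%s_%s.tsv", stat, nm)))
        out[[paste(stat, nm, sep = ".")]] <- st
        if (stat == "fst")
          msg("mean FST ", nm, ": ", signif(attr(st, "mean_fst"), 4))
      }
      out
    })
    scans <- c(scans, pair)
  }

  ann <- if (!is.null(cfg$gff)) stage_run("annotation", read_gff(cfg$gff))
         else NULL
  sets <- list()
  if (!is.null(ann)) sets <- stage_run("candidates", {
    for (key in names(scans)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      for (frac in cfg$fractions) {
        idx <- select_top(scans[[key]], frac, cfg$tails[[parts[1]]])
        gs <- annotate_genes(scans[[key]][idx, ], ann, cfg$flank_bp,
                             name = sprintf("%s_%s_%g", parts[1], parts[2],
                                            frac),
                             statistic = parts[1], comparison = parts[2],
                             threshold = frac)
        sets[[gs$name]] <- gs
      }
    }
    per_set <- data.frame(
      set = names(sets),
      n_genes = vapply(sets, function(s) length(s$gene_ids), integer(1)))
    data.table::fwrite(per_set, fp("gene_set_sizes.tsv"), sep = "\t")
    long <- do.call(rbind, lapply(sets, function(s) if (length(s$gene_ids))
      data.frame(set = s$name, gene_id = s$gene_ids,
                 statistic = s$provenance$statistic,
                 comparison = s$provenance$comparison,
                 threshold = s$provenance$threshold)))
    data.table::fwrite(long, fp("gene_sets.tsv"), sep = "\t")
    at_cgs <- Filter(function(s)
      s$provenance$threshold == cfg$cgs_fraction, sets)
    up <- intersect_sets(at_cgs)
    data.table::fwrite(up, fp("upset.tsv"), sep = "\t")
    cg <- cgs(at_cgs, cfg$cgs_rule)
    data.table::fwrite(data.frame(gene_id = cg$gene_ids), fp("cgs.tsv"),
                       sep = "\t")
    sets[["CGS"]] <- cg
    sets
  })

  assoc <- NULL
  if (!is.null(cfg$expression) && !is.null(sets[["CGS"]]) &&
      file.exists(cfg$expression$fpkm %||% "")) {
    assoc <- stage_run("association", {
      vals <- as.data.frame(data.table::fread(cfg$expression$fpkm))
      rownames(vals) <- vals$gene_id
      vals$gene_id <- NULL
      stages <- utils::read.table(cfg$expression$stages, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
      expr <- expression_matrix(as.matrix(vals), rownames(vals),
                                colnames(vals),
                                stages$stage[match(colnames(vals),
                                                   stages$sample)])
      segs <- build_segs(expr, cfg$segs_fraction)
      data.table::fwrite(
        data.frame(gene_id = rownames(segs$membership), segs$membership,
                   check.names = FALSE),
        fp("segs_membership.tsv"), sep = "\t")
      res <- associate(sets[["CGS"]], segs)
      jsonlite::write_json(
        list(intersections = res$intersections,
             contribution = as.list(res$contribution),
             union_size = res$union_size),
        fp("association.json"), auto_unbox = TRUE)
      res
    })
  } else if (!is.null(sets[["CGS"]])) {
    msg("association stage skipped: no expression input")
  }

  manifest <- list(config = cfg,
                   package_version =
                     as.character(utils::packageVersion("desertsweep")),
                   n_snps_input = qc_res$report$n_input,
                   n_snps_retained = qc_res$report$n_retained,
                   statistics = names(scans))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(genotypes = g, scans = scans, sets = sets,
                 association = assoc, qc_report = qc_res$report,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
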