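#' Pipeline configuration
#'
#' Bundles the synthetic-data (or input-file) configuration, every module
#' threshold and the step toggles of [run_pipeline()]. Defaults are the
#' study-wide thresholds: fold change >= 1.5, p < 0.05, |r| >= 0.9,
#' alignment score >= 140, energy <= -20 kcal/mol, k_min = 1.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [simulation_config()]; used by the `simulate` step and the
#'   source of the run seed.
#' @param fc_threshold,alpha DE filter thresholds.
#' @param r_min,coexpr_alpha Coexpression thresholds.
#' @param score_min,energy_max MRE prediction thresholds.
#' @param k_min,cerna_alpha ceRNA candidate thresholds.
#' @param steps Stages to execute, in dependency order. A disabled stage's
#'   outputs must already exist in `out_dir` (from a previous run) or the
#'   first stage needing them fails with a dependency error.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(),
                            fc_threshold = 1.5, alpha = 0.05,
                            r_min = 0.9, coexpr_alpha = 0.05,
                            score_min = 140, energy_max = -20,
                            k_min = 1, cerna_alpha = 0.05,
                            steps = c("simulate", "de", "mre", "coexpr",
                                      "build", "enrich")) {
  steps <- match.arg(steps, several.ok = TRUE)
  structure(list(out_dir = out_dir, sim = sim, fc_threshold = fc_threshold,
                 alpha = alpha, r_min = r_min, coexpr_alpha = coexpr_alpha,
                 score_min = score_min, energy_max = energy_max,
                 k_min = k_min, cerna_alpha = cerna_alpha, steps = steps),
            class = "pipeline_config")
}

pipeline_paths <- function(out_dir) {
  f <- function(x) file.path(out_dir, x)
  list(circ = f("circ_counts.tsv"), mrna = f("mrna_counts.tsv"),
       mirna = f("mirna_intensity.tsv"), design = f("design.tsv"),
       mirna_fa = f("mirna.fa"), target_fa = f("targets.fa"),
       target_classes = f("target_classes.tsv"),
       gmt = f("annotation.gmt"),
       truth_de = f("truth_de_features.tsv"),
       truth_circuits = f("truth_circuits.tsv"),
       truth_sites = f("truth_planted_sites.tsv"),
       de_circ = f("de_circRNA.tsv"), de_mirna = f("de_miRNA.tsv"),
       de_mrna = f("de_mRNA.tsv"),
       mre_circ = f("mre_circ.tsv"), mre_mrna = f("mre_mrna.tsv"),
       pairs_circ = f("pairs_circ.tsv"), pairs_mrna = f("pairs_mrna.tsv"),
       edges_mir_circ = f("edges_mir_circ.tsv"),
       edges_mir_mrna = f("edges_mir_mrna.tsv"),
       edges_circ_mrna = f("edges_circ_mrna.tsv"),
       validated_circ = f("validated_mir_circ.tsv"),
       validated_mrna = f("validated_mir_mrna.tsv"),
       candidates = f("candidates.tsv"), triplets = f("triplets.tsv"),
       sif = f("network.sif"), graphml = f("network.graphml"),
       enrichment = f("enrichment.tsv"), manifest = f("manifest.json"))
}

require_stage_files <- function(stage, files) {
  missing <- files[!file.exists(unlist(files))]
  if (length(missing))
    stop(sprintf("[%s] missing input file(s) from a disabled earlier stage: %s",
                 stage, paste(basename(unlist(missing)), collapse = ", ")),
         call. = FALSE)
}

read_de_tables <- function(p, fc, alpha) {
  de <- lapply(c(circRNA = p$de_circ, miRNA = p$de_mirna, mRNA = p$de_mrna),
               read_tsv)
  kept <- lapply(de, function(d) filter_de(d, fc, alpha)$kept)
  list(all = de, kept = kept, combined = do.call(rbind, kept))
}

#' In-memory ceRNA inference on a simulated or assembled dataset
#'
#' Runs DE filtering, MRE prediction (restricted to DE features), signed
#' coexpression, validated-pair intersection and network assembly on the
#' in-memory dataset structure returned by [simulate_dataset()], without
#' touching the filesystem. Used for Monte-Carlo evaluation; [run_pipeline()]
#' is the file-based equivalent.
#'
#' @param ds Dataset list as returned by [simulate_dataset()].
#' @param fc_threshold,alpha DE filter thresholds.
#' @param r_min,coexpr_alpha Coexpression thresholds.
#' @param score_min,energy_max MRE thresholds.
#' @param k_min,cerna_alpha ceRNA candidate thresholds.
#' @return List with `de` (kept records per class), `mres`, `pairs`,
#'   `edges` (list `mir_circ`, `mir_mrna`, `circ_mrna`), `validated`
#'   (list `circ`, `mrna`), `candidates`, `triplets`.
#' @export
infer_network <- function(ds, fc_threshold = 1.5, alpha = 0.05,
                          r_min = 0.9, coexpr_alpha = 0.05,
                          score_min = 140, energy_max = -20,
                          k_min = 1, cerna_alpha = 0.05) {
  de_circ <- filter_de(de_test_counts(ds$circ, "circRNA"), fc_threshold, alpha)$kept
  de_mrna <- filter_de(de_test_counts(ds$mrna, "mRNA"), fc_threshold, alpha)$kept
  de_mirna <- filter_de(de_test_intensity(ds$mirna), fc_threshold, alpha)$kept

  tclass <- attr(ds$target_fa, "target_class")
  keep_m <- intersect(names(ds$mirna_fa), de_mirna$feature_id)
  keep_t <- intersect(names(ds$target_fa),
                      c(de_circ$feature_id, de_mrna$feature_id))
  mirnas <- structure(unclass(ds$mirna_fa)[keep_m], moltype = "miRNA",
                      class = "rna_seqs")
  targets <- structure(unclass(ds$target_fa)[keep_t], moltype = "mRNA_target",
                       target_class = tclass[keep_t], class = "rna_seqs")
  mres <- if (length(keep_m) && length(keep_t))
    predict_mres(mirnas, targets, score_min, energy_max)
  else empty_mre_df()

  pairs <- collapse_to_pairs(mres)
  circ_norm <- normalize_counts(ds$circ)
  mrna_norm <- normalize_counts(ds$mrna)
  sub <- function(em, ids) subset_features(em, ids)
  edges <- list(mir_circ = NULL, mir_mrna = NULL, circ_mrna = NULL)
  if (nrow(de_mirna) && nrow(de_circ))
    edges$mir_circ <- coexpression_edges(sub(ds$mirna, de_mirna$feature_id),
                                         sub(circ_norm, de_circ$feature_id),
                                         "miRNA", "circRNA", "negative",
                                         r_min, coexpr_alpha)
  if (nrow(de_mirna) && nrow(de_mrna))
    edges$mir_mrna <- coexpression_edges(sub(ds$mirna, de_mirna$feature_id),
                                         sub(mrna_norm, de_mrna$feature_id),
                                         "miRNA", "mRNA", "negative",
                                         r_min, coexpr_alpha)
  if (nrow(de_circ) && nrow(de_mrna))
    edges$circ_mrna <- coexpression_edges(sub(circ_norm, de_circ$feature_id),
                                          sub(mrna_norm, de_mrna$feature_id),
                                          "circRNA", "mRNA", "positive",
                                          r_min, coexpr_alpha)
  empty_edges <- data.frame(a_id = character(0), a_class = character(0),
                            b_id = character(0), b_class = character(0),
                            r = numeric(0), p_value = numeric(0),
                            required_sign = character(0),
                            stringsAsFactors = FALSE)
  for (nm in names(edges)) if (is.null(edges[[nm]])) edges[[nm]] <- empty_edges
  vc <- filter_targets_by_coexpression(
    pairs[pairs$target_class == "circRNA", , drop = FALSE], edges$mir_circ)
  vm <- filter_targets_by_coexpression(
    pairs[pairs$target_class == "mRNA", , drop = FALSE], edges$mir_mrna)
  de_all <- rbind(de_circ, de_mirna, de_mrna)
  net <- build_cerna_network(vc, vm, edges$circ_mrna, de_all,
                             cerna_alpha, k_min)
  list(de = list(circRNA = de_circ, miRNA = de_mirna, mRNA = de_mrna),
       mres = mres, pairs = pairs, edges = edges,
       validated = list(circ = vc, mrna = vm),
       candidates = net$candidates, triplets = net$triplets)
}

#' Run the ceRNA inference pipeline end to end
#'
#' Executes the enabled stages in dependency order
#' (simulate -> de -> mre -> coexpr -> build -> enrich), writing every
#' intermediate table under `config$out_dir`, logging row counts per filter,
#' and writing a JSON manifest with the resolved configuration, per-file row
#' counts and MD5 checksums. Identical configuration (including the
#' simulation seed) gives identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(out_dir)
  log_stage <- function(stage, ...) message(sprintf("[%s] ", stage), ...)

  if ("simulate" %in% config$steps) {
    log_stage("simulate", "seed ", config$sim$seed)
    ds <- simulate_dataset(config$sim)
    write_expression(ds$circ, p$circ, p$design)
    write_expression(ds$mrna, p$mrna)
    write_expression(ds$mirna, p$mirna)
    write_fasta(ds$mirna_fa, p$mirna_fa)
    write_fasta(ds$target_fa, p$target_fa)
    tc <- attr(ds$target_fa, "target_class")
    write_tsv(data.frame(target_id = names(tc), target_class = unname(tc),
                         stringsAsFactors = FALSE), p$target_classes)
    write_gmt(ds$annotation, p$gmt)
    write_tsv(ds$truth$de_features, p$truth_de)
    write_tsv(ds$truth$circuits, p$truth_circuits)
    write_tsv(ds$truth$planted_sites, p$truth_sites)
  }

  if ("de" %in% config$steps) {
    require_stage_files("de", p[c("circ", "mrna", "mirna", "design")])
    circ <- read_expression(p$circ, "counts", p$design)
    mrna <- read_expression(p$mrna, "counts", p$design)
    mirna <- read_expression(p$mirna, "log_intensity", p$design)
    de_circ <- de_test_counts(circ, "circRNA")
    de_mrna <- de_test_counts(mrna, "mRNA")
    de_mirna <- de_test_intensity(mirna)
    write_tsv(de_circ, p$de_circ)
    write_tsv(de_mrna, p$de_mrna)
    write_tsv(de_mirna, p$de_mirna)
    for (d in list(de_circ, de_mirna, de_mrna)) {
      f <- filter_de(d, config$fc_threshold, config$alpha)
      log_stage("de", sprintf("%s: %d kept (%d up, %d down) of %d",
                              d$class[1], nrow(f$kept), f$summary["up"],
                              f$summary["down"], nrow(d)))
    }
  }

  if ("mre" %in% config$steps) {
    require_stage_files("mre", p[c("de_circ", "de_mirna", "de_mrna",
                                   "mirna_fa", "target_fa", "target_classes")])
    de <- read_de_tables(p, config$fc_threshold, config$alpha)
    mirnas <- read_fasta(p$mirna_fa, "miRNA")
    targets <- read_fasta(p$target_fa, "mRNA_target")
    tc <- read_tsv(p$target_classes)
    attr(targets, "target_class") <- structure(tc$target_class,
                                               names = tc$target_id)
    keep_m <- intersect(names(mirnas), de$kept$miRNA$feature_id)
    keep_t <- intersect(names(targets),
                        c(de$kept$circRNA$feature_id, de$kept$mRNA$feature_id))
    mirnas_de <- structure(mirnas[keep_m], moltype = "miRNA", class = "rna_seqs")
    targets_de <- structure(targets[keep_t], moltype = "mRNA_target",
                            target_class = attr(targets, "target_class")[keep_t],
                            class = "rna_seqs")
    mres <- predict_mres(mirnas_de, targets_de, config$score_min,
                         config$energy_max)
    for (cl in c("circRNA", "mRNA")) {
      sub <- mres[mres$target_class == cl, , drop = FALSE]
      pairs <- collapse_to_pairs(sub)
      log_stage("mre", sprintf("%s: %d MREs -> %d target pairs",
                               cl, nrow(sub), nrow(pairs)))
      write_tsv(sub, if (cl == "circRNA") p$mre_circ else p$mre_mrna)
      write_tsv(pairs, if (cl == "circRNA") p$pairs_circ else p$pairs_mrna)
    }
  }

  if ("coexpr" %in% config$steps) {
    require_stage_files("coexpr", p[c("circ", "mrna", "mirna", "design",
                                      "de_circ", "de_mirna", "de_mrna")])
    de <- read_de_tables(p, config$fc_threshold, config$alpha)
    circ <- normalize_counts(read_expression(p$circ, "counts", p$design))
    mrna <- normalize_counts(read_expression(p$mrna, "counts", p$design))
    mirna <- read_expression(p$mirna, "log_intensity", p$design)
    circ_de <- subset_features(circ, de$kept$circRNA$feature_id)
    mrna_de <- subset_features(mrna, de$kept$mRNA$feature_id)
    mirna_de <- subset_features(mirna, de$kept$miRNA$feature_id)
    e1 <- coexpression_edges(mirna_de, circ_de, "miRNA", "circRNA",
                             "negative", config$r_min, config$coexpr_alpha)
    e2 <- coexpression_edges(mirna_de, mrna_de, "miRNA", "mRNA",
                             "negative", config$r_min, config$coexpr_alpha)
    e3 <- coexpression_edges(circ_de, mrna_de, "circRNA", "mRNA",
                             "positive", config$r_min, config$coexpr_alpha)
    log_stage("coexpr", sprintf("edges: %d miR-circ, %d miR-mRNA, %d circ-mRNA",
                                nrow(e1), nrow(e2), nrow(e3)))
    write_tsv(e1, p$edges_mir_circ)
    write_tsv(e2, p$edges_mir_mrna)
    write_tsv(e3, p$edges_circ_mrna)
  }

  if ("build" %in% config$steps) {
    require_stage_files("build", p[c("pairs_circ", "pairs_mrna",
                                     "edges_mir_circ", "edges_mir_mrna",
                                     "edges_circ_mrna",
                                     "de_circ", "de_mirna", "de_mrna")])
    de <- read_de_tables(p, config$fc_threshold, config$alpha)
    vc <- filter_targets_by_coexpression(read_tsv(p$pairs_circ),
                                         read_tsv(p$edges_mir_circ))
    vm <- filter_targets_by_coexpression(read_tsv(p$pairs_mrna),
                                         read_tsv(p$edges_mir_mrna))
    log_stage("build", sprintf("validated pairs: %d miR-circ, %d miR-mRNA",
                               nrow(vc), nrow(vm)))
    net <- build_cerna_network(vc, vm, read_tsv(p$edges_circ_mrna),
                               de$combined, config$cerna_alpha, config$k_min)
    log_stage("build", sprintf("%d candidates (score), %d triplets",
                               nrow(net$candidates), nrow(net$triplets)))
    write_tsv(vc, p$validated_circ)
    write_tsv(vm, p$validated_mrna)
    write_tsv(net$candidates, p$candidates)
    write_tsv(net$triplets, p$triplets)
    suppressWarnings({
      write_network(net$triplets, "sif", p$sif)
      write_network(net$triplets, "graphml", p$graphml)
    })
  }

  if ("enrich" %in% config$steps) {
    require_stage_files("enrich", p[c("triplets", "gmt")])
    trips <- read_tsv(p$triplets)
    collection <- read_gmt(p$gmt)
    res <- if (nrow(trips)) enrich(unique(trips$mrna_id), collection)
    else suppressWarnings(enrich(character(0), collection))
    log_stage("enrich", sprintf("%d terms tested, %d significant",
                                nrow(res), sum(res$significant)))
    write_tsv(res, p$enrichment)
  }

  files <- unlist(p[setdiff(names(p), "manifest")])
  files <- files[file.exists(files)]
  row_count <- function(f) {
    if (grepl("\\.(tsv)$", f)) nrow(read_tsv(f))
    else length(readLines(f, warn = FALSE))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cernet")),
    seed = config$sim$seed,
    config = unclass(config[setdiff(names(config), "sim")]),
    sim_config = unclass(config$sim),
    files = lapply(files, function(f) {
      list(rows = row_count(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
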