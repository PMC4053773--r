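## End-to-end orchestration: reads a config (list or YAML file), runs the
## requested stages in order (parclip -> correlate -> model -> associate ->
## rank -> survival), and writes one TSV per result into the output
## directory. Identical config and seed give byte-identical outputs.

PIPELINE_STAGES <- c("parclip", "correlate", "model", "associate", "rank",
                     "survival")

default_config <- function() {
  list(thresholds = list(mirna_rrf = 1e-4, mrna_abundance = 6.5),
       options = list(mrna_kind = "array", posterior_cutoff = 0.5,
                      gt_permutations = 499, kmer_shuffles = 100,
                      run_kmer_enrichment = TRUE, train_fraction = 0.5,
                      alpha = 0.5),
       seed = 1)
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  config$thresholds <- utils::modifyList(base$thresholds,
                                         config$thresholds %||% list())
  config$options <- utils::modifyList(base$options, config$options %||% list())
  config$seed <- config$seed %||% base$seed
  config$stages <- config$stages %||% PIPELINE_STAGES
  config
}

stage_inputs <- list(
  parclip = c("reads", "transcripts", "transcript_model", "families",
              "mirna_counts"),
  correlate = c("mirna_counts", "mrna_expr", "families", "predictions"),
  model = c("predictions", "mirna_counts", "mrna_expr", "families"),
  associate = c("gene_sets"),
  rank = c("gene_sets", "cgc"),
  survival = c("sample_annotation"))

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
}

log_stage <- function(stage, t0) {
  message(sprintf("[mirti] %-10s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Stages: `parclip` (cluster reads, extract CCRs, call seed sites,
#' annotate regions, optional 7-mer enrichment), `correlate`
#' (abundance-filtered family/mRNA correlations and the target-vs-
#' background shift, overall and per subtype), `model` (elastic-net
#' classifier and MP-PCLIP selection), `associate` (gene-set global tests),
#' `rank` (activity and phenotype rankings) and `survival` (per-family
#' prognostic signature tests). Later stages consume earlier stages'
#' results, so the requested stages must form a prefix of that order.
#'
#' @param config list or YAML path: `inputs` (named file paths:
#'   reads, transcripts, transcript_model, families, mirna_counts,
#'   mrna_expr, sample_annotation, predictions, gene_sets, cgc),
#'   `thresholds` (`mirna_rrf`, `mrna_abundance`), `options`, `stages`,
#'   `seed`, `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- load_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  stages <- match.arg(config$stages, PIPELINE_STAGES, several.ok = TRUE)
  if (!identical(stages, PIPELINE_STAGES[seq_along(stages)]))
    stop("stages must form a prefix of: ",
         paste(PIPELINE_STAGES, collapse = " -> "))
  ## validate inputs for every requested stage before any computation
  for (st in stages) {
    need <- stage_inputs[[st]]
    miss <- need[!vapply(need, function(k)
      !is.null(config$inputs[[k]]) && file.exists(config$inputs[[k]]), TRUE)]
    if (length(miss))
      stop("stage '", st, "' missing input(s): ", paste(miss, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  opt <- config$options
  thr <- config$thresholds
  B <- opt$gt_permutations
  t0 <- as.numeric(Sys.time())

  inp <- config$inputs
  mirna_counts <- read_expression_matrix(inp$mirna_counts)
  families <- read_mirna_families(inp$families)
  mirna_rrf <- compute_rrf(mirna_counts)
  fam_expr <- family_expression(mirna_rrf, families)
  fam_expr <- filter_by_mean(fam_expr, thr$mirna_rrf)

  if ("parclip" %in% stages) {
    reads <- if (grepl("\\.sam$", inp$reads)) read_aligned_reads_sam(inp$reads)
             else read_aligned_reads(inp$reads)
    transcripts <- read_fasta(inp$transcripts)
    model_df <- read_transcript_model(inp$transcript_model)
    clusters <- cluster_reads(reads)
    ccrs <- extract_ccrs(clusters, transcripts)
    sites <- call_seed_sites(ccrs, families)
    interactions <- sites_to_interactions(sites, ccrs)
    regions <- annotate_regions(clusters, model_df)
    cl_df <- data.frame(
      cluster_id = vapply(clusters, `[[`, "", "cluster_id"),
      transcript_id = vapply(clusters, `[[`, "", "transcript_id"),
      start = vapply(clusters, `[[`, 0L, "start"),
      end = vapply(clusters, `[[`, 0L, "end"),
      n_reads = vapply(clusters, `[[`, 0L, "n_reads"),
      crosslinked_fraction = vapply(clusters, `[[`, 0, "crosslinked_fraction"),
      major_t2c_position = vapply(clusters, `[[`, 0L, "major_t2c_position"),
      region = regions$labels)
    write_tsv(cl_df, out_dir, "clusters")
    write_tsv(ccrs, out_dir, "ccrs")
    write_bed(data.frame(transcript_id = ccrs$transcript_id,
                         start = ccrs$start,
                         end = ccrs$start + nchar(ccrs$sequence),
                         name = ccrs$ccr_id),
              file.path(out_dir, "ccrs.bed"))
    write_tsv(sites, out_dir, "seed_sites")
    write_tsv(interactions, out_dir, "parclip_interactions")
    write_tsv(data.frame(region = names(regions$fractions),
                         fraction = regions$fractions), out_dir,
              "region_fractions")
    if (isTRUE(opt$run_kmer_enrichment) && nrow(ccrs) > 0) {
      km <- kmer_enrichment(ccrs, k = 7, n_shuffles = opt$kmer_shuffles,
                            seed = derive_seed(config$seed, "kmer"))
      write_tsv(km, out_dir, "kmer_stats")
      res$kmers <- km
    }
    res$clusters <- clusters; res$ccrs <- ccrs; res$sites <- sites
    res$interactions <- interactions; res$regions <- regions
    log_stage("parclip", t0)
  }

  if ("correlate" %in% stages) {
    mrna_expr <- read_expression_matrix(inp$mrna_expr)
    if (identical(opt$mrna_kind, "array"))
      mrna_expr <- filter_by_mean(mrna_expr, thr$mrna_abundance)
    predictions <- read_target_predictions(inp$predictions)
    tmap <- predictions[, c("family_id", "gene_id")]
    recs <- pair_correlations(fam_expr, mrna_expr, tmap)
    shift <- correlation_shift(recs)
    write_tsv(recs, out_dir, "correlations")
    write_tsv(shift, out_dir, "shift_overall")
    if (!is.null(inp$sample_annotation)) {
      ann <- read_sample_annotation(inp$sample_annotation)
      st_vec <- stats::setNames(ann$subtype, ann$sample_id)
      shifts <- try(subtype_shift(fam_expr, mrna_expr, tmap, st_vec),
                    silent = TRUE)
      if (!inherits(shifts, "try-error"))
        write_tsv(shifts, out_dir, "shift_by_subtype")
    }
    res$mrna_expr <- mrna_expr; res$target_map <- tmap
    res$correlations <- recs; res$shift <- shift
    log_stage("correlate", t0)
  }

  if ("model" %in% stages) {
    parclip_pairs <- res$interactions[, c("family_id", "gene_id")]
    crosslinked <- unique(vapply(res$clusters, `[[`, "", "transcript_id"))
    predictions <- read_target_predictions(inp$predictions)
    pairs <- assemble_and_label(predictions, parclip_pairs, crosslinked,
                                fam_expr, res$mrna_expr)
    pairs <- split_train_test(pairs, opt$train_fraction,
                              seed = derive_seed(config$seed, "split"))
    model <- fit_elastic_net(pairs, alpha = opt$alpha,
                             seed = derive_seed(config$seed, "cv"))
    ev <- evaluate_model(model, pairs)
    all_candidates <- build_pair_features(predictions, fam_expr, res$mrna_expr)
    mp <- select_mp_pclip(model, all_candidates, parclip_pairs,
                          cutoff = opt$posterior_cutoff)
    jsonlite::write_json(
      list(alpha = model$alpha, lambda = model$lambda,
           intercept = model$intercept,
           coefficients = as.list(model$coefficients),
           feature_means = as.list(model$feature_means),
           feature_sds = as.list(model$feature_sds)),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    write_tsv(data.frame(metric = c("auc_train", "auc_test", "fdr_at_cutoff"),
                         value = c(ev$auc_train, ev$auc_test,
                                   ev$fdr_at_cutoff)), out_dir, "model_eval")
    write_tsv(mp, out_dir, "mp_pclip")
    res$pairs <- pairs; res$model <- model; res$eval <- ev; res$mp_pclip <- mp
    log_stage("model", t0)
  }

  if ("associate" %in% stages) {
    gene_sets <- read_gmt(inp$gene_sets)
    assoc <- associate_sets(fam_expr, res$mrna_expr, gene_sets,
                            res$mp_pclip[, c("family_id", "gene_id")],
                            B = B, seed = derive_seed(config$seed, "assoc"))
    write_tsv(assoc, out_dir, "pathway_associations")
    res$gene_sets <- gene_sets; res$associations <- assoc
    log_stage("associate", t0)
  }

  if ("rank" %in% stages) {
    cgc <- read_gmt(inp$cgc)[[1]]
    act <- activity_ranking(fam_expr, res$mrna_expr,
                            res$mp_pclip[, c("family_id", "gene_id")],
                            res$gene_sets, cgc, B = B,
                            seed = derive_seed(config$seed, "rank"))
    write_tsv(act$ranking, out_dir, "activity_ranking")
    res$activity <- act
    if (!is.null(inp$sample_annotation)) {
      ann <- read_sample_annotation(inp$sample_annotation)
      ph <- try(phenotype_ranking(fam_expr, res$mrna_expr,
                                  res$mp_pclip[, c("family_id", "gene_id")],
                                  ann, B = B,
                                  seed = derive_seed(config$seed, "pheno")),
                silent = TRUE)
      if (!inherits(ph, "try-error")) {
        write_tsv(ph$ranking, out_dir, "phenotype_ranking")
        res$phenotype <- ph
      }
    }
    log_stage("rank", t0)
  }

  if ("survival" %in% stages) {
    ann <- read_sample_annotation(inp$sample_annotation)
    time <- stats::setNames(ann$overall_survival, ann$sample_id)
    event <- stats::setNames(ann$survival_event, ann$sample_id)
    tmap <- res$mp_pclip[, c("family_id", "gene_id")]
    fams <- intersect(rownames(fam_expr), unique(tmap$family_id))
    seeds <- run_seeded(derive_seed(config$seed, "surv"),
                        sample.int(.Machine$integer.max, length(fams)))
    rows <- lapply(seq_along(fams), function(i) {
      sg <- try(survival_signature(fams[i], fam_expr, res$mrna_expr, tmap,
                                   time, event, B = B, seed = seeds[i]),
                silent = TRUE)
      if (inherits(sg, "try-error")) return(NULL)
      data.frame(family_id = fams[i], Q = sg$gt$Q, p = sg$gt$p_perm,
                 n_genes = length(sg$genes) - 1L,
                 genes = paste(sg$genes[-1], collapse = ","))
    })
    surv <- do.call(rbind, rows)
    if (!is.null(surv)) {
      surv$bh_q <- stats::p.adjust(surv$p, method = "BH")
      write_tsv(surv, out_dir, "survival_signatures")
      res$survival <- surv
    }
    log_stage("survival", t0)
  }
  invisible(res)
}

#' Write a synthetic study to pipeline input files
#'
#' Materializes a [synth_study()] as the file formats the pipeline reads,
#' plus `ground_truth.json`, and returns a ready-to-run pipeline config.
#'
#' @param study output of [synth_study()].
#' @param dir directory to write into.
#' @return pipeline config list pointing at the written files.
#' @export
write_synth_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(study$reference$transcripts, p("transcripts.fa"))
  write_bed(data.frame(transcript_id = study$reference$model$transcript_id,
                       start = study$reference$model$start,
                       end = study$reference$model$end,
                       name = study$reference$model$region),
            p("transcript_model.bed"))
  write_mirna_families(study$reference$families, p("families.tsv"))
  write_aligned_reads(study$reads, p("reads.tsv"))
  write_expression_matrix(study$expression$mirna_counts, p("mirna_counts.tsv"))
  write_expression_matrix(study$expression$mrna_expr, p("mrna_expr.tsv"))
  write_sample_annotation(study$annotation, p("sample_annotation.tsv"))
  write_target_predictions(study$predictions, p("predictions.tsv"))
  write_gmt(study$gene_sets, p("gene_sets.gmt"))
  write_gmt(list(CGC = study$cgc_set), p("cgc.gmt"))
  jsonlite::write_json(
    list(target_map = study$truth$target_map,
         active_families = study$truth$active_families,
         signature_family = study$truth$signature_family,
         signature_genes = study$truth$signature_genes),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  list(inputs = list(reads = p("reads.tsv"), transcripts = p("transcripts.fa"),
                     transcript_model = p("transcript_model.bed"),
                     families = p("families.tsv"),
                     mirna_counts = p("mirna_counts.tsv"),
                     mrna_expr = p("mrna_expr.tsv"),
                     sample_annotation = p("sample_annotation.tsv"),
                     predictions = p("predictions.tsv"),
                     gene_sets = p("gene_sets.gmt"), cgc = p("cgc.gmt")))
}
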