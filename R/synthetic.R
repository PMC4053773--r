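## Synthetic-data generator. Emits every input the pipeline consumes —
## transcript reference with UTR/CDS structure, miRNA family table with
## planted seed sites, a patient expression cohort with subtype-specific
## planted repression, a PAR-CLIP read library with crosslinked clusters
## over the planted sites, a TargetScan-style prediction table with
## feature-label coupling, clinical phenotypes and Cox-generated survival —
## together with the ground truth needed for recovery tests. All outputs
## are deterministic given the config seed.

derive_seed <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(tag)) * 7919L) %% 2147483647L
}

#' Synthetic study configuration
#'
#' Defaults describe the study conditions the package's recovery tests run
#' under: 20 miRNA families over 100 genes, two molecular subtypes of 40
#' samples each with 3 active families per subtype, repression effect
#' `beta = 1` (log2 units per unit relative regulator abundance), expression
#' noise `sigma = 0.25`, PAR-CLIP clusters of ~8 reads with crosslink
#' probability 0.8, a 1-SD classifier feature shift, and a survival hazard
#' ratio of 2 per SD of the signature score.
#'
#' @param n_genes,n_families reference sizes.
#' @param subtypes named integer vector: samples per subtype.
#' @param active_per_subtype number of active families per subtype, or
#'   `"all"`.
#' @param targets_per_family planted targets per family.
#' @param beta repression effect (log2 units per unit relative RRF).
#' @param sigma Gaussian expression noise SD (log2 units).
#' @param reads_per_cluster mean extra reads per planted cluster (above the
#'   5-read floor).
#' @param crosslink_prob per-read probability of carrying a T-to-C
#'   conversion at the crosslink site.
#' @param background_clusters,decoy_clusters numbers of seedless >= 5-read
#'   clusters and sub-threshold (< 5 reads) decoy clusters.
#' @param feature_shift classifier feature shift for true pairs (SD units).
#' @param n_decoy_pairs decoy rows in the prediction table.
#' @param baseline_hazard,hazard_ratio survival model: exponential baseline
#'   hazard and hazard ratio per SD of signature score.
#' @param censor_max upper bound of the uniform censoring distribution.
#' @param utr5_len,cds_len,utr3_len transcript region lengths (nt).
#' @param seed master RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 100, n_families = 20,
                         subtypes = c("luminal A" = 40, "basal-like" = 40),
                         active_per_subtype = 3, targets_per_family = 8,
                         beta = 1, sigma = 0.25,
                         reads_per_cluster = 4, crosslink_prob = 0.8,
                         background_clusters = 30, decoy_clusters = 10,
                         feature_shift = 1, n_decoy_pairs = 400,
                         baseline_hazard = 0.1, hazard_ratio = 2,
                         censor_max = 30,
                         utr5_len = 60, cds_len = 240, utr3_len = 400,
                         seed = 1) {
  stopifnot(n_genes >= 1, n_families >= 1, beta >= 0, sigma >= 0,
            crosslink_prob >= 0, crosslink_prob <= 1, feature_shift >= 0)
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  structure(as.list(environment()), class = "synth_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Build the synthetic transcript reference and miRNA families
#'
#' Transcripts have a 5'UTR / CDS / 3'UTR structure of the configured
#' lengths; families carry pairwise-distinct 7-nt seeds and 21-nt mature
#' sequences whose positions 2-8 equal the seed.
#'
#' @param config a [synth_config()].
#' @return list with `transcripts` (named character), `model`
#'   (region data.frame), `families` (family table) and `gene_ids`.
#' @export
make_reference <- function(config) {
  run_seeded(derive_seed(config$seed, "reference"), {
    if (config$n_families > 4^7 / 2) stop("more families than usable seeds")
    gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
    L <- config$utr5_len + config$cds_len + config$utr3_len
    transcripts <- stats::setNames(vapply(gene_ids, function(g) random_dna(L), ""),
                                   gene_ids)
    model <- do.call(rbind, lapply(gene_ids, function(g) {
      data.frame(transcript_id = g,
                 region = c("5UTR", "CDS", "3UTR"),
                 start = c(0L, config$utr5_len, config$utr5_len + config$cds_len),
                 end = c(config$utr5_len, config$utr5_len + config$cds_len, L))
    }))
    seeds <- character(0)
    while (length(seeds) < config$n_families) {
      cand <- chartr("T", "U", random_dna(7))
      if (!cand %in% seeds) seeds <- c(seeds, cand)
    }
    fam_ids <- sprintf("miR-%d", seq_len(config$n_families))
    mature <- vapply(seeds, function(s) {
      paste0(sample(c("A", "C", "G", "U"), 1), s,
             paste(sample(c("A", "C", "G", "U"), 13, replace = TRUE), collapse = ""))
    }, "")
    families <- data.frame(family_id = fam_ids, seed_2_8 = seeds,
                           stringsAsFactors = FALSE)
    families$member_ids <- as.list(fam_ids)
    families$mature_sequences <- as.list(unname(mature))
    list(transcripts = transcripts, model = model, families = families,
         gene_ids = gene_ids)
  })
}

#' Plant ground-truth interactions into the reference
#'
#' Chooses each family's target genes, plants an 8mer seed site in each
#' target's 3'UTR with a crosslinkable T two nucleotides upstream, assigns
#' active families to subtypes and designates the survival signature (the
#' first active family of the first subtype and its targets).
#'
#' @param config a [synth_config()].
#' @param reference output of [make_reference()].
#' @return list with the modified `reference` and `truth` (target map with
#'   site and crosslink coordinates, active families per subtype, signature
#'   family and genes).
#' @export
make_ground_truth <- function(config, reference) {
  run_seeded(derive_seed(config$seed, "truth"), {
    fams <- reference$families
    utr3_start <- config$utr5_len + config$cds_len
    L <- utr3_start + config$utr3_len
    cursor <- stats::setNames(rep(utr3_start + 20L, length(reference$gene_ids)),
                              reference$gene_ids)
    ## slots are spaced beyond the maximum read span so clusters planted for
    ## different families on the same gene never merge
    site_slot <- 60L
    rows <- list()
    for (i in seq_len(nrow(fams))) {
      site <- seed_site_sequences(fams$seed_2_8[i])[["8mer"]]
      genes <- sample(reference$gene_ids,
                      min(config$targets_per_family, length(reference$gene_ids)))
      for (g in genes) {
        pos <- cursor[[g]]
        if (pos + nchar(site) > L - 5L) {
          warning("3'UTR of ", g, " too short; skipping ", fams$family_id[i])
          next
        }
        seq <- reference$transcripts[[g]]
        substr(seq, pos + 1L, pos + nchar(site)) <- site
        xlink <- pos - 2L
        substr(seq, xlink + 1L, xlink + 1L) <- "T"
        reference$transcripts[[g]] <- seq
        cursor[[g]] <- pos + site_slot
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = fams$family_id[i], gene_id = g,
          site_start = pos, crosslink_pos = xlink, stringsAsFactors = FALSE)
      }
    }
    target_map <- do.call(rbind, rows)
    subtype_names <- names(config$subtypes)
    active <- if (identical(config$active_per_subtype, "all")) {
      stats::setNames(rep(list(fams$family_id), length(subtype_names)),
                      subtype_names)
    } else {
      pool <- sample(fams$family_id)
      k <- config$active_per_subtype
      stats::setNames(lapply(seq_along(subtype_names), function(j) {
        pool[((j - 1) * k + seq_len(k) - 1) %% length(pool) + 1]
      }), subtype_names)
    }
    sig_family <- active[[1]][1]
    truth <- list(target_map = target_map,
                  active_families = active,
                  signature_family = sig_family,
                  signature_genes = target_map$gene_id[
                    target_map$family_id == sig_family])
    list(reference = reference, truth = truth)
  })
}

#' Simulate the patient expression cohort
#'
#' miRNA counts are Poisson draws around log-normal per-miRNA rates scaled
#' to log-normal library sizes (so RRF differs from raw counts). Gene
#' expression is Gaussian on the log2 scale around per-gene baselines with
#' noise `sigma`; within each subtype, targets of that subtype's active
#' families are reduced by `beta` times the regulator family's relative
#' read frequency divided by its cohort mean, so repression scales with
#' regulator abundance. Non-targets are untouched.
#'
#' @param config a [synth_config()].
#' @param truth ground truth from [make_ground_truth()].
#' @param reference (possibly modified) reference.
#' @return list with `mirna_counts` and `mrna_expr` (`ExpressionMatrix`es)
#'   and `annotation` (sample/subtype data.frame).
#' @export
simulate_expression_cohort <- function(config, truth, reference) {
  run_seeded(derive_seed(config$seed, "cohort"), {
    fams <- reference$families$family_id
    genes <- reference$gene_ids
    n <- sum(config$subtypes)
    subtype <- rep(names(config$subtypes), times = config$subtypes)
    sample_ids <- sprintf("S%03d", seq_len(n))
    lib <- round(stats::rlnorm(n, log(5e4), 0.3))
    if (any(lib <= 0)) stop("zero library size")
    base_rate <- stats::rlnorm(length(fams), 0, 1)
    counts <- vapply(seq_len(n), function(j) {
      r <- base_rate * stats::rlnorm(length(fams), 0, 0.4)
      stats::rpois(length(fams), lib[j] * r / sum(r))
    }, numeric(length(fams)))
    dimnames(counts) <- list(fams, sample_ids)
    mirna_counts <- expression_matrix(counts, entity_kind = "mirna",
                                      scale = "counts")
    rrf <- unclass(compute_rrf(mirna_counts))
    base_g <- stats::rnorm(length(genes), 8, 1.5)
    expr <- matrix(stats::rnorm(length(genes) * n, 0, config$sigma),
                   length(genes), n, dimnames = list(genes, sample_ids))
    expr <- expr + base_g
    rel <- sweep(rrf, 1, rowMeans(rrf), "/")  # family RRF / mean RRF
    for (st in names(config$subtypes)) {
      cols <- which(subtype == st)
      for (f in intersect(truth$active_families[[st]], fams)) {
        tg <- truth$target_map$gene_id[truth$target_map$family_id == f]
        tg <- intersect(tg, genes)
        if (length(tg))
          expr[tg, cols] <- expr[tg, cols] -
            config$beta * rep(rel[f, cols], each = length(tg))
      }
    }
    annotation <- data.frame(sample_id = sample_ids, subtype = subtype,
                             stringsAsFactors = FALSE)
    list(mirna_counts = mirna_counts,
         mrna_expr = expression_matrix(expr, entity_kind = "mrna",
                                       scale = "a_value"),
         annotation = annotation)
  })
}

make_cluster_reads <- function(transcript_id, seq, center, n_reads,
                               crosslink_prob, id_prefix, read_len = 26) {
  L <- nchar(seq)
  starts <- pmax(0L, pmin(L - read_len,
                          center - sample(3:(read_len - 4), n_reads, replace = TRUE)))
  do.call(rbind, lapply(seq_len(n_reads), function(i) {
    s <- starts[i]
    rseq <- substr(seq, s + 1L, s + read_len)
    t2c <- integer(0)
    if (stats::runif(1) < crosslink_prob && center >= s && center < s + read_len &&
        substr(seq, center + 1L, center + 1L) == "T") {
      substr(rseq, center - s + 1L, center - s + 1L) <- "C"
      t2c <- center
    }
    df <- data.frame(read_id = sprintf("%s_r%02d", id_prefix, i),
                     transcript_id = transcript_id, start = s,
                     end = s + read_len, sequence = rseq,
                     stringsAsFactors = FALSE)
    df$t2c_positions <- list(t2c)
    df
  }))
}

#' Simulate the PAR-CLIP read library
#'
#' For every planted (family, gene) interaction, emits a cluster of at
#' least 5 overlapping reads spanning the planted seed site, each read
#' carrying a T-to-C conversion at the fixed crosslink position with the
#' configured probability; plus seedless background clusters in CDS regions
#' and sub-threshold decoy clusters (< 5 reads) that must be filtered out
#' downstream.
#'
#' @param config a [synth_config()].
#' @param truth ground truth.
#' @param reference reference with planted sites.
#' @return aligned-read data.frame ([read_aligned_reads()] shape).
#' @export
simulate_parclip_library <- function(config, truth, reference) {
  run_seeded(derive_seed(config$seed, "parclip"), {
    out <- list()
    tm <- truth$target_map
    for (i in seq_len(nrow(tm))) {
      n_reads <- 5L + stats::rpois(1, config$reads_per_cluster)
      out[[length(out) + 1L]] <- make_cluster_reads(
        tm$gene_id[i], reference$transcripts[[tm$gene_id[i]]],
        tm$crosslink_pos[i], n_reads, config$crosslink_prob,
        sprintf("planted_%03d", i))
    }
    ## background windows stay clear of the 3'UTR so they cannot merge with
    ## planted clusters
    cds_mid <- config$utr5_len + 30L
    for (b in seq_len(config$background_clusters)) {
      g <- sample(reference$gene_ids, 1)
      seq <- reference$transcripts[[g]]
      win <- cds_mid + sample(0:max(0L, config$cds_len - 130L), 1)
      region <- substr(seq, win + 1L, win + 40L)
      toff <- as.integer(regexpr("T", region, fixed = TRUE))
      center <- if (toff > 0) win + toff - 1L else win
      out[[length(out) + 1L]] <- make_cluster_reads(
        g, seq, center, 5L + stats::rpois(1, config$reads_per_cluster),
        config$crosslink_prob, sprintf("background_%03d", b))
    }
    for (d in seq_len(config$decoy_clusters)) {
      g <- sample(reference$gene_ids, 1)
      seq <- reference$transcripts[[g]]
      center <- config$utr5_len + 10L
      out[[length(out) + 1L]] <- make_cluster_reads(
        g, seq, center, sample(2:4, 1), config$crosslink_prob,
        sprintf("decoy_%03d", d))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate the TargetScan-style prediction table
#'
#' One row per candidate pair: all planted (true) interactions plus decoy
#' pairs absent from the truth. For true pairs the context score, the
#' conservation score and the per-type site counts are drawn from
#' distributions shifted by `feature_shift` SD units relative to the decoy
#' baseline; decoys come from the baseline distributions.
#'
#' @param config a [synth_config()].
#' @param truth ground truth.
#' @param reference reference (for gene/family ids).
#' @return prediction data.frame ([read_target_predictions()] shape).
#' @export
simulate_prediction_table <- function(config, truth, reference) {
  if (config$feature_shift < 0) stop("feature_shift must be >= 0")
  run_seeded(derive_seed(config$seed, "predictions"), {
    true_pairs <- unique(truth$target_map[, c("family_id", "gene_id")])
    fams <- reference$families$family_id
    genes <- reference$gene_ids
    tk <- pair_key(true_pairs$family_id, true_pairs$gene_id)
    decoys <- data.frame(family_id = sample(fams, 3 * config$n_decoy_pairs, TRUE),
                         gene_id = sample(genes, 3 * config$n_decoy_pairs, TRUE),
                         stringsAsFactors = FALSE)
    decoys <- decoys[!duplicated(pair_key(decoys$family_id, decoys$gene_id)), ]
    decoys <- decoys[!(pair_key(decoys$family_id, decoys$gene_id) %in% tk), ]
    decoys <- utils::head(decoys, config$n_decoy_pairs)
    all_pairs <- rbind(cbind(true_pairs, is_true = TRUE),
                       cbind(decoys, is_true = FALSE))
    n <- nrow(all_pairs)
    shift <- config$feature_shift
    lam0 <- 0.3
    lam1 <- lam0 + shift * sqrt(lam0)
    lam <- ifelse(all_pairs$is_true, lam1, lam0)
    cnt <- function() stats::rpois(n, lam)
    out <- data.frame(
      family_id = all_pairs$family_id, gene_id = all_pairs$gene_id,
      aggregate_pct = pmin(1, pmax(0, stats::rnorm(n, 0.3, 0.15) +
                                     ifelse(all_pairs$is_true, shift * 0.15, 0))),
      total_context_score = stats::rnorm(n, -0.15, 0.12) -
        ifelse(all_pairs$is_true, shift * 0.12, 0),
      n_cons_7m8 = cnt(), n_cons_7a1 = cnt(), n_cons_8mer = cnt(),
      n_noncons_7m8 = cnt(), n_noncons_7a1 = cnt(), n_noncons_8mer = cnt(),
      stringsAsFactors = FALSE)
    out$n_conserved_sites <- out$n_cons_7m8 + out$n_cons_7a1 + out$n_cons_8mer
    out$n_nonconserved_sites <- out$n_noncons_7m8 + out$n_noncons_7a1 +
      out$n_noncons_8mer
    out$conserved_flag <- as.integer(out$n_conserved_sites > 0)
    attr(out, "is_true") <- all_pairs$is_true
    out
  })
}

#' Simulate clinical phenotypes and survival
#'
#' Survival and metastasis times are exponential with hazard
#' `baseline_hazard * exp(log(hazard_ratio) * z)` where `z` is the
#' standardized mean expression of the signature genes; censoring is
#' uniform on (0, `censor_max`). Binary phenotypes follow logistic links on
#' `z`; tumor size and grade are ordinal cuts of a latent `z` plus logistic
#' noise.
#'
#' @param config a [synth_config()].
#' @param truth ground truth.
#' @param expression output of [simulate_expression_cohort()].
#' @return completed sample-annotation data.frame.
#' @export
simulate_clinical <- function(config, truth, expression) {
  if (config$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  run_seeded(derive_seed(config$seed, "clinical"), {
    ann <- expression$annotation
    n <- nrow(ann)
    sig <- intersect(truth$signature_genes, rownames(expression$mrna_expr))
    score <- colMeans(unclass(expression$mrna_expr)[sig, , drop = FALSE])
    z <- as.numeric(scale(score))
    draw_surv <- function() {
      h <- config$baseline_hazard * exp(log(config$hazard_ratio) * z)
      t_event <- stats::rexp(n, h)
      t_cens <- stats::runif(n, 0, config$censor_max)
      list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
    }
    os <- draw_surv(); met <- draw_surv()
    latent <- z + stats::rlogis(n)
    ann$lymph_node_positive <- stats::rbinom(n, 1, stats::plogis(0.5 * z))
    ann$lymphovascular_invasion <- stats::rbinom(n, 1, stats::plogis(0.5 * z))
    ann$tumor_size_class <- cut(latent, c(-Inf, -0.5, 0.8, Inf),
                                labels = c("<2", "2-5", ">5"))
    ann$grade <- cut(z + stats::rlogis(n), c(-Inf, -0.5, 0.8, Inf),
                     labels = c("good", "moderate", "poor"))
    ann$tumor_size_class <- as.character(ann$tumor_size_class)
    ann$grade <- as.character(ann$grade)
    ann$time_to_metastasis <- met$time
    ann$metastasis_event <- met$event
    ann$overall_survival <- os$time
    ann$survival_event <- os$event
    ann
  })
}

#' Simulate gene sets and a cancer-gene set
#'
#' Each family gets a "home" pathway containing part of its planted targets
#' plus random genes, so every family has at least one target-containing
#' set; additional purely random sets are added. The cancer-gene set mixes
#' a couple of targets per family with random genes.
#'
#' @param config a [synth_config()].
#' @param truth ground truth.
#' @param reference reference.
#' @param n_random_sets extra random sets.
#' @return list with `gene_sets` (named list) and `cgc_set` (character).
#' @export
simulate_gene_sets <- function(config, truth, reference, n_random_sets = 5) {
  run_seeded(derive_seed(config$seed, "genesets"), {
    tm <- truth$target_map
    genes <- reference$gene_ids
    sets <- list()
    for (f in unique(tm$family_id)) {
      tg <- tm$gene_id[tm$family_id == f]
      own <- sample(tg, min(4, length(tg)))
      sets[[paste0("path_", f)]] <- unique(c(own, sample(setdiff(genes, tg), 8)))
    }
    for (i in seq_len(n_random_sets)) {
      sets[[sprintf("path_random%02d", i)]] <- sample(genes, 12)
    }
    cgc <- unique(c(unlist(lapply(unique(tm$family_id), function(f)
      sample(tm$gene_id[tm$family_id == f], min(2, sum(tm$family_id == f))))),
      sample(genes, 10)))
    list(gene_sets = sets, cgc_set = cgc)
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage in order and returns all pipeline inputs with
#' their ground truth.
#'
#' @param config a [synth_config()].
#' @return list with `reference`, `truth`, `expression`, `reads`,
#'   `predictions`, `annotation`, `gene_sets`, `cgc_set`.
#' @export
synth_study <- function(config = synth_config()) {
  ref <- make_reference(config)
  gt <- make_ground_truth(config, ref)
  expr <- simulate_expression_cohort(config, gt$truth, gt$reference)
  reads <- simulate_parclip_library(config, gt$truth, gt$reference)
  preds <- simulate_prediction_table(config, gt$truth, gt$reference)
  ann <- simulate_clinical(config, gt$truth, expr)
  gs <- simulate_gene_sets(config, gt$truth, gt$reference)
  list(reference = gt$reference, truth = gt$truth, expression = expr,
       reads = reads, predictions = preds, annotation = ann,
       gene_sets = gs$gene_sets, cgc_set = gs$cgc_set)
}
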