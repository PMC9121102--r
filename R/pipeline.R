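# End-to-end orchestration with one config, a run manifest and fixed seeds.

#' Assemble a pipeline configuration
#'
#' One source of truth for every stage's thresholds. The synthetic-data
#' config inherits the pipeline seed unless supplied explicitly.
#'
#' @param seed master seed.
#' @param sim synthetic-data settings ([sim_config()]).
#' @param annot annotation settings ([annot_config()]).
#' @param target list with `e_cutoff`, `ratio_cutoff`.
#' @param degradome list with `keep` (categories), `cut_pos`.
#' @param expression list with `high_cut`, `low_cut`, `max_shift`.
#' @param coexpress co-expression settings ([coexpress_config()]).
#' @param network list with `p_cut`, `upstream`, `dataset`
#'   ("overlap" or "overall").
#' @param clusters list with `max_gap`.
#' @return nested config list.
#' @export
pipeline_config <- function(seed = 42L,
                            sim = sim_config(seed = seed),
                            annot = annot_config(),
                            target = list(e_cutoff = 3.0,
                                          ratio_cutoff = 0.75),
                            degradome = list(keep = c(0L, 1L),
                                             cut_pos = 10L),
                            expression = list(high_cut = 100, low_cut = 10,
                                              max_shift = 2L),
                            coexpress = coexpress_config(),
                            network = list(p_cut = 1e-4, upstream = 2000L,
                                           dataset = "overlap"),
                            clusters = list(max_gap = 10000L)) {
  as.list(environment())
}

#' Validate a pipeline configuration
#'
#' All violations are collected and reported together.
#'
#' @param config configuration from [pipeline_config()].
#' @param inputs optional named character vector of required input paths
#'   (existence-checked).
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config, inputs = NULL) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  chk(config$coexpress$beta >= 1, "coexpress beta must be >= 1")
  chk(config$target$e_cutoff > 0, "target e_cutoff must be > 0")
  chk(config$target$ratio_cutoff > 0 && config$target$ratio_cutoff <= 1,
      "target ratio_cutoff must be in (0, 1]")
  chk(all(config$degradome$keep %in% 0:4),
      "degradome keep categories must be in 0..4")
  chk(config$expression$high_cut >= config$expression$low_cut,
      "expression high_cut must be >= low_cut")
  chk(config$network$p_cut > 0 && config$network$p_cut <= 1,
      "network p_cut must be in (0, 1]")
  chk(config$network$dataset %in% c("overlap", "overall"),
      "network dataset must be 'overlap' or 'overall'")
  chk(config$clusters$max_gap > 0, "clusters max_gap must be > 0")
  if (!is.null(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) {
      errs <- c(errs, sprintf("input file does not exist: %s", missing))
    }
  }
  errs
}

#' Match annotated loci to planted truth loci by coordinates
#'
#' A locus is recovered when its annotated mature arm coincides with the
#' planted mature or the planted star arm (the naming of the two arms
#' follows read abundance, which can swap under sampling noise).
#'
#' @param loci annotated locus table.
#' @param truth_loci truth table from the generator.
#' @param tol coordinate tolerance on the arm start/end, nt.
#' @return character vector (one per annotated locus) of truth locus ids,
#'   NA where unmatched.
#' @export
match_loci_to_truth <- function(loci, truth_loci, tol = 2L) {
  vapply(seq_len(nrow(loci)), function(i) {
    same <- truth_loci$chrom == loci$chrom[i] &
      truth_loci$strand == loci$strand[i]
    hit <- which(same &
      ((abs(truth_loci$mature_start - loci$mature_start[i]) <= tol &
          abs(truth_loci$mature_end - loci$mature_end[i]) <= tol) |
         (abs(truth_loci$star_start - loci$mature_start[i]) <= tol &
            abs(truth_loci$star_end - loci$mature_end[i]) <= tol)))
    if (length(hit)) truth_loci$locus_id[hit[1]] else NA_character_
  }, character(1))
}

.hash_files <- function(paths) {
  paths <- unlist(paths, use.names = FALSE)
  paths <- paths[file.exists(paths)]
  h <- tools::md5sum(sort(paths))
  setNames(unname(h), basename(names(h)))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes simulate, read preparation, locus annotation, target
#' prediction plus degradome confirmation, quantification and pattern
#' classification, correlation statistics, co-expression modules, and the
#' TF/miRNA/target network, writing stage outputs and a run manifest under
#' `out_dir`.
#'
#' @param out_dir output directory.
#' @param config configuration from [pipeline_config()].
#' @return invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop(paste(c("invalid configuration:", errs), collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  res <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest[[name]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] -
                                                  t0, 2))
    out
  }

  sim <- stage("simulate", simulate_dataset(config$sim,
                                            file.path(out_dir, "data")))
  manifest$simulate$hashes <- .hash_files(sim$paths)

  prep <- stage("srna_prep", {
    libs <- lapply(sim$paths$srna, read_fastq)
    names(libs) <- sub("\\.fastq$", "", basename(sim$paths$srna))
    clean <- lapply(libs, clean_reads)
    collapsed_clean <- collapse_unique(clean)
    pred <- lapply(clean, select_prediction_set)
    collapsed <- filter_ncrna(collapse_unique(pred), sim$ncrna)
    aln <- map_reads(collapsed, sim$genome)
    hist_tab <- do.call(rbind, lapply(names(clean), function(lib) {
      h <- length_distribution(clean[[lib]]$seq)
      data.frame(library = lib, length = as.integer(names(h$hist)),
                 count = as.integer(h$hist), stringsAsFactors = FALSE)
    }))
    f1 <- write_tsv(collapsed, file.path(out_dir, "srna",
                                         "unique_reads.tsv"))
    f2 <- write_tsv(aln, file.path(out_dir, "srna", "alignments.tsv"))
    f3 <- write_tsv(hist_tab, file.path(out_dir, "srna",
                                        "length_hist.tsv"))
    list(libs = names(libs), clean = clean, collapsed = collapsed,
         collapsed_clean = collapsed_clean, alignments = aln,
         files = c(f1, f2, f3))
  })
  manifest$srna_prep$hashes <- .hash_files(prep$files)

  annot <- stage("mirna_annot", {
    catalogue <- read_mirna_catalogue(sim$paths$catalogue)
    ann <- annotate_mirnas(prep$alignments, sim$genome, catalogue,
                           config$annot)
    ann$clusters <- detect_clusters(ann$loci,
                                    max_gap = config$clusters$max_gap)
    ann$synteny <- anchor_synteny(ann$loci, sim$blocks)
    f1 <- write_tsv(ann$loci, file.path(out_dir, "annot", "loci.tsv"))
    f2 <- write_tsv(ann$rejected, file.path(out_dir, "annot",
                                            "rejected.tsv"))
    f3 <- write_tsv(ann$clusters, file.path(out_dir, "annot",
                                            "clusters.tsv"))
    f4 <- write_tsv(ann$synteny, file.path(out_dir, "annot",
                                           "synteny.tsv"))
    gff <- data.frame(chrom = ann$loci$chrom, start = ann$loci$pre_start,
                      end = ann$loci$pre_end, strand = ann$loci$strand,
                      type = "miRNA_primary_transcript",
                      id = ann$loci$locus_id, parent = "",
                      stringsAsFactors = FALSE)
    gffm <- data.frame(chrom = ann$loci$chrom,
                       start = ann$loci$mature_start,
                       end = ann$loci$mature_end, strand = ann$loci$strand,
                       type = "miRNA",
                       id = paste0(ann$loci$locus_id, ".mature"),
                       parent = ann$loci$locus_id, stringsAsFactors = FALSE)
    f5 <- write_gff3(rbind(gff, gffm), file.path(out_dir, "annot",
                                                 "mirna.gff3"))
    ann$files <- c(f1, f2, f3, f4, f5)
    ann
  })
  manifest$mirna_annot$hashes <- .hash_files(annot$files)

  expr_stage <- stage("expression", {
    count_cols <- prep$libs
    totals <- colSums(prep$alignments[!duplicated(prep$alignments$seq),
                                      count_cols, drop = FALSE])
    loci_q <- data.frame(locus_id = annot$loci$locus_id,
                         chrom = annot$loci$chrom,
                         mature_start = annot$loci$mature_start,
                         mature_end = annot$loci$mature_end,
                         strand = annot$loci$strand,
                         stringsAsFactors = FALSE)
    rpm <- quantify_mirna_rpm(prep$alignments, loci_q, count_cols, totals,
                              max_shift = config$expression$max_shift)
    tissue_of <- sub("_r\\d+$", "", colnames(rpm))
    rpm_tissue <- average_by_tissue(rpm, tissue_of, config$sim$tissues)
    pats <- classify_patterns(rpm_tissue,
                              high_cut = config$expression$high_cut,
                              low_cut = config$expression$low_cut)
    f1 <- write_tsv(data.frame(mirna_id = rownames(rpm), rpm,
                               check.names = FALSE),
                    file.path(out_dir, "expression", "mirna_rpm_reads.tsv"))
    f2 <- write_tsv(pats, file.path(out_dir, "expression", "patterns.tsv"))
    list(rpm = rpm, rpm_tissue = rpm_tissue, patterns = pats,
         totals = totals, files = c(f1, f2))
  })
  manifest$expression$hashes <- .hash_files(expr_stage$files)

  targets <- stage("target_pred", {
    mirnas <- setNames(annot$loci$mature_seq, annot$loci$locus_id)
    preds <- scan_transcriptome(mirnas, sim$transcripts,
                                e_cutoff = config$target$e_cutoff,
                                ratio_cutoff = config$target$ratio_cutoff)
    preds
  })

  deg <- stage("degradome", {
    tags <- unlist(lapply(sim$paths$pare, function(f) {
      unname(read_fasta(f))
    }), use.names = FALSE)
    profiles <- build_density(tags, sim$transcripts)
    conf <- confirm_pairs(targets, profiles,
                          keep = config$degradome$keep,
                          cut_pos = config$degradome$cut_pos)
    list(profiles = profiles, confirmed = conf)
  })

  inter <- stage("integrate", {
    out <- integrate_methods(targets, deg$confirmed)
    f <- write_tsv(out, file.path(out_dir, "targets",
                                  "interactions.tsv"))
    attr(out, "file") <- f
    out
  })
  manifest$integrate$hashes <- .hash_files(attr(inter, "file"))

  stats_stage <- stage("stats", {
    truth_map <- match_loci_to_truth(annot$loci, sim$truth$loci)
    mi_tissue <- average_by_tissue(sim$expr$mirna_rpm,
                                   sim$expr$mirna_tissue_of,
                                   config$sim$tissues)
    tx_tissue <- average_by_tissue(sim$expr$fpkm, sim$expr$fpkm_tissue_of,
                                   config$sim$tissues)
    sel <- inter$in_overall & !is.na(truth_map[match(inter$mirna_id,
                                                     annot$loci$locus_id)])
    pairs <- data.frame(
      mirna_id = truth_map[match(inter$mirna_id[sel],
                                 annot$loci$locus_id)],
      target_id = inter$transcript_id[sel], stringsAsFactors = FALSE)
    pairs <- unique(pairs[pairs$mirna_id %in% rownames(mi_tissue) &
                            pairs$target_id %in% rownames(tx_tissue), ])
    recs <- correlate_pairs(mi_tissue, tx_tissue, pairs)
    nf <- negative_fraction(recs)
    f <- write_tsv(recs, file.path(out_dir, "stats", "correlations.tsv"))
    list(records = recs, negative = nf, mi_tissue = mi_tissue,
         tx_tissue = tx_tissue, files = f)
  })
  manifest$stats$hashes <- .hash_files(stats_stage$files)

  coex <- stage("coexpress", {
    filt <- filter_genes(sim$expr$fpkm)
    adj <- adjacency(filt$mat, beta = config$coexpress$beta)
    tom <- topological_overlap(adj)
    assignment <- detect_modules(tom, config$coexpress)
    eig <- module_eigengene(filt$mat, assignment)
    mt <- module_trait(eig, sim$expr$fpkm_tissue_of, config$coexpress,
                       config$sim$tissues)
    hubs <- kme_hubs(filt$mat, eig, assignment,
                     n_hubs = config$coexpress$n_hubs)
    f1 <- write_tsv(data.frame(gene = names(assignment),
                               module = unname(assignment)),
                    file.path(out_dir, "coexpress", "modules.tsv"))
    f2 <- write_tsv(mt, file.path(out_dir, "coexpress",
                                  "module_trait.tsv"))
    f3 <- write_tsv(hubs, file.path(out_dir, "coexpress", "hubs.tsv"))
    list(assignment = assignment, eigengenes = eig, module_trait = mt,
         hubs = hubs, files = c(f1, f2, f3))
  })
  manifest$coexpress$hashes <- .hash_files(coex$files)

  net <- stage("network", {
    dataset <- if (config$network$dataset == "overlap") {
      inter[inter$in_overlap, , drop = FALSE]
    } else {
      inter[inter$in_overall, , drop = FALSE]
    }
    mi_feats <- data.frame(id = annot$loci$locus_id,
                           chrom = annot$loci$chrom,
                           start = annot$loci$pre_start,
                           end = annot$loci$pre_end,
                           strand = annot$loci$strand,
                           stringsAsFactors = FALSE)
    gene_ids <- unique(dataset$transcript_id)
    feats <- sim$features[sim$features$type == "mRNA" &
                            sim$features$id %in% gene_ids, , drop = FALSE]
    gene_feats <- data.frame(id = feats$id, chrom = feats$chrom,
                             start = feats$start, end = feats$end,
                             strand = feats$strand,
                             stringsAsFactors = FALSE)
    mi_prom <- extract_promoters(mi_feats, sim$genome,
                                 upstream = config$network$upstream)
    gene_prom <- extract_promoters(gene_feats, sim$genome,
                                   upstream = config$network$upstream)
    mi_hits <- scan_motifs(mi_prom, sim$pwms, p_cut = config$network$p_cut)
    gene_hits <- scan_motifs(gene_prom, sim$pwms,
                             p_cut = config$network$p_cut)
    edges <- build_edges(mi_hits, gene_hits, dataset, sim$tf_map,
                         known_genes = names(sim$transcripts))
    motifs <- enumerate_motifs(edges)
    export_network(edges, file.path(out_dir, "network", "network"))
    list(edges = edges, motifs = motifs, mi_hits = mi_hits,
         gene_hits = gene_hits,
         files = file.path(out_dir, "network",
                           paste0("network",
                                  c(".sif", ".nodes.tsv", ".graphml"))))
  })
  manifest$network$hashes <- .hash_files(net$files)

  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  res <- list(sim = sim, prep = prep, annot = annot,
              expression = expr_stage, targets = targets, degradome = deg,
              interactions = inter, stats = stats_stage, coexpress = coex,
              network = net, manifest = manifest,
              manifest_path = manifest_path)
  invisible(res)
}
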