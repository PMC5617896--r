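#' Run the full regulon-inference pipeline
#'
#' Orchestrates quantification, differential expression, dependency
#' classification, clustering and promoter-motif analysis:
#' counts are converted to FPKM and expression status; each mutant is
#' tested against the reference per timepoint with the NB Wald test and
#' the published cut-offs; regulation patterns are classified into
#' minimal monotone dependency expressions with predominant activators,
#' Venn partitions and temporal switches; panel genes are clustered by
#' complete linkage on the averaged log matrix; and, when promoters are
#' supplied, the published TF motifs are scanned and RhaR-motif enrichment
#' among RhaR-dependent promoters is computed. When the generating
#' `fr_model` is supplied, ground-truth recovery metrics are added.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param lengths Tibble with `gene_id`, `length_bp` (an `fr_model`
#'   works).
#' @param design Design tibble.
#' @param promoters Optional promoter tibble (`gene_id`, `sequence`).
#' @param gene_panel Optional character vector of genes to classify and
#'   cluster (default: all genes).
#' @param model Optional `fr_model` ground truth for recovery metrics.
#' @param config [pipeline_config()].
#' @param out_dir Optional directory; when given, all result tables, the
#'   promoter FASTA hits and a JSON summary are written there.
#' @param discover_motifs Run ZOOPS-EM discovery on RhaR-dependent
#'   promoters (slower; default `FALSE`).
#' @return List of class `fr_pipeline`: `fpkm`, `status`, `size_factors`,
#'   `de`, `dependencies` (down and up, per timepoint), `venn`,
#'   `switches`, `clustering`, `mean_log`, `motif_hits`, `enrichment`,
#'   `discovery`, `recovery`, `summary`.
#' @export
run_pipeline <- function(counts, lengths, design, promoters = NULL,
                         gene_panel = NULL, model = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         discover_motifs = FALSE) {
  stopifnot(inherits(config, "fr_config"))
  validate_design(design)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[facreg] %-12s %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  panel <- gene_panel %||% counts$gene_id
  timepoints <- unique(design$timepoint)

  fpkm <- stage("quantify", compute_fpkm(counts, lengths))
  status <- stage("status", expression_status(
    fpkm, design, thresholds = c(config$fpkm_not_expressed,
                                 config$fpkm_low_max)))
  sf <- size_factors(counts)
  de <- stage("diffexp", de_all_contrasts(
    counts, design, sf = sf, fc_threshold = config$fc,
    alpha = config$alpha))

  dependencies <- stage("depclass", {
    out <- list()
    for (tp in timepoints) {
      for (dir in c("down", "up")) {
        cl <- classify_dependencies(de, tp, dir,
                                    tie_margin = config$tie_margin)
        out[[paste(tp, dir, sep = "_")]] <-
          dplyr::filter(cl, .data$gene_id %in% panel)
      }
    }
    out
  })

  expressed_at <- function(tp) {
    st <- dplyr::filter(status, .data$timepoint == tp,
                        .data$gene_id %in% panel)
    st$gene_id[st$status != "not_expressed"]
  }

  venn <- stage("venn", {
    lapply(setNames(timepoints, timepoints), function(tp) {
      dep <- dependencies[[paste0(tp, "_down")]]
      venn_partition(dplyr::filter(dep, .data$gene_id %in% expressed_at(tp)))
    })
  })

  switches <- if (length(timepoints) >= 2) {
    stage("switches", temporal_switches(
      dependencies[[paste0(timepoints[1], "_down")]],
      dependencies[[paste0(timepoints[2], "_down")]]))
  } else NULL

  mean_log <- mean_log_matrix(fpkm, design, base = config$log_base)
  panel_ml <- dplyr::filter(mean_log, .data$gene_id %in% panel)
  clustering <- if (nrow(panel_ml) >= 2) {
    stage("clustering", hclust_complete(panel_ml))
  } else NULL

  motif_hits <- enrichment <- discovery <- NULL
  if (!is.null(promoters)) {
    motif_hits <- stage("motifs", {
      tm <- tf_motifs()
      dplyr::bind_rows(lapply(seq_len(nrow(tm)), function(i) {
        h <- scan_iupac(promoters, parse_iupac(tm$pattern[i],
                                               motif_id = tm$motif_id[i]))
        if (nrow(h) > 0) h$tf <- tm$tf[i]
        h
      }))
    })
    ## RhaR-motif enrichment: RhaR-dependent promoters vs the rest
    rha_genes <- unique(unlist(lapply(timepoints, function(tp) {
      dep <- dependencies[[paste0(tp, "_down")]]
      dep$gene_id[grepl("R", dep$expression, fixed = TRUE) &
                    !dep$expression %in% c("none", "complex")]
    })))
    prom_ids <- promoters$gene_id
    if (length(rha_genes) > 0) {
      with_hit <- unique(motif_hits$seq_id[motif_hits$motif_id == "RhaR"])
      enrichment <- enrichment_from_counts(
        sum(rha_genes %in% with_hit), length(rha_genes),
        sum(setdiff(prom_ids, rha_genes) %in% with_hit),
        length(setdiff(prom_ids, rha_genes)))
    }
    if (discover_motifs && length(rha_genes) >= 5) {
      discovery <- stage("discovery", zoops_discover(
        dplyr::filter(promoters, .data$gene_id %in% rha_genes),
        width_range = config$motif_widths, seed = config$seed))
    }
  }

  recovery <- if (!is.null(model)) {
    stage("recovery", recovery_metrics(model, dependencies, fpkm, design,
                                       status, config))
  } else NULL

  summary <- list(
    n_genes = nrow(counts), panel_size = length(panel),
    timepoints = as.list(setNames(lapply(timepoints, function(tp) {
      dep <- dependencies[[paste0(tp, "_down")]]
      up <- dependencies[[paste0(tp, "_up")]]
      expr_ids <- expressed_at(tp)
      reg <- dep$gene_id[dep$expression != "none" &
                           dep$gene_id %in% expr_ids]
      reg <- union(reg, up$gene_id[up$expression != "none" &
                                     up$gene_id %in% expr_ids])
      list(regulated = length(reg),
           not_regulated = length(setdiff(expr_ids, reg)),
           not_expressed = length(panel) - length(expr_ids),
           venn = setNames(as.list(venn[[tp]]$n_genes),
                           as.character(venn[[tp]]$region)))
    }), timepoints)),
    n_switched = if (!is.null(switches)) sum(switches$switched %in% TRUE)
                 else NA_integer_,
    recovery = recovery
  )

  res <- structure(list(
    fpkm = fpkm, status = status, size_factors = sf, de = de,
    dependencies = dependencies, venn = venn, switches = switches,
    clustering = clustering, mean_log = mean_log,
    motif_hits = motif_hits, enrichment = enrichment,
    discovery = discovery, recovery = recovery, summary = summary,
    config = config), class = "fr_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

## Ground-truth recovery: fraction of truly dependent genes whose inferred
## down-direction dependency expression equals the generator's, and the
## abolished-expression check for TF genes.
recovery_metrics <- function(model, dependencies, fpkm, design, status,
                             config) {
  truth <- canonical_dnf(model$dependency)
  names(truth) <- model$gene_id
  dep_genes <- model$gene_id[truth != "none" & is.na(model$is_tf_gene)]
  per_tp <- list()
  for (nm in names(dependencies)) {
    if (!grepl("_down$", nm)) next
    dep <- dependencies[[nm]]
    idx <- match(dep_genes, dep$gene_id)
    ok <- !is.na(idx)
    acc <- mean(dep$expression[idx[ok]] == truth[dep_genes[ok]])
    per_tp[[sub("_down$", "", nm)]] <- acc
  }
  ## TF genes: expression abolished (FPKM < threshold) in every genotype
  ## deleting that TF, at every timepoint, while the reference expresses it
  tf_rows <- which(!is.na(model$is_tf_gene))
  tf_ok <- vapply(tf_rows, function(i) {
    tf <- model$is_tf_gene[i]
    g <- model$gene_id[i]
    own <- design$sample_id[vapply(design$genotype, function(gt) {
      tf %in% genotype_deleted(gt)
    }, logical(1))]
    vals <- unlist(fpkm[fpkm$gene_id == g, own])
    ref_ok <- all(status$ref_mean_fpkm[status$gene_id == g] >=
                    config$fpkm_not_expressed)
    all(vals < config$fpkm_not_expressed) && ref_ok
  }, logical(1))
  list(
    dependency_accuracy = per_tp,
    dependency_accuracy_overall = mean(unlist(per_tp)),
    n_dependent_genes = length(dep_genes),
    tf_abolished_correct = mean(tf_ok),
    n_tf_genes = length(tf_rows)
  )
}

#' Write all pipeline outputs to a directory
#'
#' TSV per result table, Venn and switch tables, motif hits, discovered
#' motifs in minimal MEME format, and a JSON summary.
#'
#' @param res `fr_pipeline` result.
#' @param out_dir Directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_tsv_(res$fpkm, fp("fpkm.tsv"))
  write_tsv_(res$status, fp("expression_status.tsv"))
  write_tsv_(res$de, fp("de_calls.tsv"))
  for (nm in names(res$dependencies)) {
    write_tsv_(res$dependencies[[nm]], fp(sprintf("dependency_%s.tsv", nm)))
  }
  for (tp in names(res$venn)) {
    v <- res$venn[[tp]]
    write_tsv_(tibble(region = as.character(v$region), n_genes = v$n_genes,
                      genes = vapply(v$genes, paste, character(1),
                                     collapse = ",")),
               fp(sprintf("venn_%s.tsv", tp)))
  }
  if (!is.null(res$switches)) write_tsv_(res$switches, fp("switches.tsv"))
  if (!is.null(res$clustering)) {
    write_tsv_(tidy(res$clustering), fp("cluster_merges.tsv"))
  }
  if (!is.null(res$motif_hits)) write_tsv_(res$motif_hits,
                                           fp("motif_hits.tsv"))
  if (!is.null(res$enrichment)) write_tsv_(res$enrichment,
                                           fp("motif_enrichment.tsv"))
  if (!is.null(res$discovery)) write_meme(res$discovery,
                                          fp("discovered_motifs.meme"))
  jsonlite::write_json(res$summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @method glance fr_pipeline
#' @export
glance.fr_pipeline <- function(x, ...) {
  tps <- x$summary$timepoints
  dplyr::bind_rows(lapply(names(tps), function(tp) {
    tibble(timepoint = tp, regulated = tps[[tp]]$regulated,
           not_regulated = tps[[tp]]$not_regulated,
           not_expressed = tps[[tp]]$not_expressed)
  }))
}

#' @export
print.fr_pipeline <- function(x, ...) {
  cat("facreg pipeline result\n")
  print(glance(x))
  if (!is.null(x$recovery)) {
    cat(sprintf("ground-truth dependency recovery: %.1f%% (TF genes: %.0f%%)\n",
                100 * x$recovery$dependency_accuracy_overall,
                100 * x$recovery$tf_abolished_correct))
  }
  invisible(x)
}
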