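#' Build the factorial deletion design
#'
#' All eight genotypes of the GaaR/AraR/RhaR deletion panel, each sampled
#' at both timepoints in replicate — the layout of the transfer experiment
#' the pipeline is built for (duplicate cultures harvested at 2 h and 8 h).
#'
#' @param replicates Replicates per genotype and timepoint (default 2,
#'   matching duplicate cultures).
#' @param timepoints Character vector of timepoint labels.
#' @param library_size Expected total mapped fragments per sample. A single
#'   number (recycled) or one per sample; enters simulation as a relative
#'   depth factor.
#' @return Tibble: `sample_id`, `genotype`, `timepoint`, `replicate`,
#'   `library_size`.
#' @export
#' @examples
#' build_design()
build_design <- function(replicates = 2, timepoints = c("2h", "8h"),
                         library_size = 1e7) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(replicate = seq_len(replicates),
                      genotype = genotype_labels(),
                      timepoint = timepoints,
                      stringsAsFactors = FALSE)
  out <- tibble(
    sample_id = sprintf("%s_%s_r%d", grid$genotype, grid$timepoint,
                        grid$replicate),
    genotype = grid$genotype,
    timepoint = grid$timepoint,
    replicate = grid$replicate,
    library_size = rep_len(library_size, nrow(grid))
  )
  dplyr::arrange(out, match(.data$genotype, genotype_labels()),
                 .data$timepoint, .data$replicate)
}

validate_design <- function(design) {
  need <- c("sample_id", "genotype", "timepoint", "replicate")
  stopifnot(all(need %in% names(design)))
  if (!"ref" %in% design$genotype) abort("Design lacks the reference genotype.")
  bad <- setdiff(unique(design$genotype), genotype_labels())
  if (length(bad) > 0) {
    abort(sprintf("Unknown genotype label(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(design)
}

#' Build a ground-truth regulatory model
#'
#' Samples per-gene regulatory logic for a synthetic transcriptome: each
#' gene gets a monotone DNF dependency over the deletion literals G, A, R
#' (or none), a log2 expression drop per clause applied when all of that
#' clause's TFs are deleted, a baseline mean count in the reference strain,
#' a length and an NB dispersion. Three TF genes (`gaaR`, `araR`, `rhaR`)
#' are flagged so the simulator can abolish their expression in their own
#' deletion strains.
#'
#' @param n_genes Number of non-TF genes.
#' @param class_mix Named proportions over dependency classes
#'   (`none`, `single`, `and`, `or`, `mixed`); must sum to 1. Gene counts
#'   per class are the largest-remainder rounding of the proportions.
#' @param effect_range Log2-reduction interval from which each clause
#'   effect is drawn uniformly; must lie in `[0, Inf)`.
#' @param dispersion NB dispersion (`Var = mu + dispersion * mu^2`): a
#'   single value or a range to draw from per gene. 0 gives Poisson counts.
#' @param baseline_range Interval for `baseline_log2` (log2 of the
#'   reference-strain mean count) of TF-dependent genes. Dependent genes
#'   are induced, hence well expressed in the reference; the default
#'   corresponds to clearly expressed genes.
#' @param baseline_range_none Baseline interval for genes with no TF
#'   dependency, which include the lowly expressed tail.
#' @param length_range Interval (bp) for gene lengths.
#' @param tf_genes Model the three TF genes themselves?
#' @param seed Integer seed; identical seeds give identical models.
#' @return Tibble of class `fr_model`: `gene_id`, `length_bp`,
#'   `baseline_log2`, `class`, `dependency`, list-columns `clauses` and
#'   `clause_effects`, `dispersion`, `is_tf_gene`.
#' @export
#' @examples
#' m <- build_model(20, seed = 1)
#' table(m$class)
build_model <- function(n_genes,
                        class_mix = c(none = 0.60, single = 0.20,
                                      and = 0.08, or = 0.08, mixed = 0.04),
                        effect_range = c(2, 6),
                        dispersion = 0.05,
                        baseline_range = c(7, 11),
                        baseline_range_none = c(3, 9),
                        length_range = c(500, 5000),
                        tf_genes = TRUE,
                        seed = 1L) {
  known <- c("none", "single", "and", "or", "mixed")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% known)) {
    abort(sprintf("class_mix names must be among: %s",
                  paste(known, collapse = ", ")))
  }
  if (any(class_mix < 0)) abort("class_mix proportions must be non-negative.")
  if (abs(sum(class_mix) - 1) > 1e-9) abort("class_mix must sum to 1.")
  if (any(effect_range < 0)) abort("effect_range must lie in [0, Inf).")
  if (any(dispersion < 0)) abort("dispersion must be >= 0.")

  counts_per_class <- apportion(n_genes, class_mix)
  pool <- monotone_dnfs()
  pool_class <- vapply(pool, dnf_class, character(1))

  withr::with_seed(seed, {
    classes <- rep(names(counts_per_class), counts_per_class)
    clauses <- lapply(classes, function(cl) {
      if (cl == "none") return(list())
      cand <- pool[pool_class == cl]
      cand[[sample.int(length(cand), 1)]]
    })
    effects <- lapply(clauses, function(cls) {
      runif(length(cls), effect_range[1], effect_range[2])
    })
    disp <- if (length(dispersion) == 2) {
      runif(n_genes, dispersion[1], dispersion[2])
    } else rep(dispersion, n_genes)

    lo <- ifelse(classes == "none", baseline_range_none[1], baseline_range[1])
    hi <- ifelse(classes == "none", baseline_range_none[2], baseline_range[2])
    genes <- tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      length_bp = as.integer(round(runif(n_genes, length_range[1],
                                         length_range[2]))),
      baseline_log2 = runif(n_genes, lo, hi),
      class = classes,
      dependency = vapply(clauses, dnf_string, character(1)),
      clauses = clauses,
      clause_effects = effects,
      dispersion = disp,
      is_tf_gene = NA_character_
    )
    if (tf_genes) {
      tf <- tibble(
        gene_id = c("gaaR", "araR", "rhaR"),
        length_bp = c(2502L, 2301L, 2703L),
        baseline_log2 = runif(3, 6, 8),
        class = "none",
        dependency = "none",
        clauses = list(list(), list(), list()),
        clause_effects = list(numeric(0), numeric(0), numeric(0)),
        dispersion = if (length(dispersion) == 2) {
          runif(3, dispersion[1], dispersion[2])
        } else rep(dispersion, 3),
        is_tf_gene = TF_ORDER
      )
      genes <- dplyr::bind_rows(tf, genes)
    }
    structure(genes, class = c("fr_model", class(genes)))
  })
}

## log2 expression drop of each gene in a genotype: satisfied clauses add
## their effects on the log2 scale.
model_log2_drop <- function(model, deleted) {
  vapply(seq_len(nrow(model)), function(i) {
    cls <- model$clauses[[i]]
    if (length(cls) == 0) return(0)
    sat <- vapply(cls, function(cl) all(cl %in% deleted), logical(1))
    sum(model$clause_effects[[i]][sat])
  }, numeric(1))
}

## Expected mean count of every gene in every sample (before NB noise),
## given the per-sample depth factors.
model_means <- function(model, design, depth) {
  vapply(seq_len(nrow(design)), function(s) {
    deleted <- genotype_deleted(design$genotype[s])
    mu <- depth[s] * 2^(model$baseline_log2 - model_log2_drop(model, deleted))
    if (any(!is.na(model$is_tf_gene))) {
      mu[!is.na(model$is_tf_gene) & model$is_tf_gene %in% deleted] <- 0
    }
    mu
  }, numeric(nrow(model)))
}

## vapply collapses the gene dimension for a 1-gene model
ensure_matrix <- function(mu, n_genes) {
  if (is.matrix(mu)) mu else matrix(mu, nrow = n_genes)
}

#' Simulate a factorial-deletion count matrix
#'
#' Draws NB counts with `mean = depth_s * 2^(baseline - sum of satisfied
#' clause effects)` and `Var = mu + dispersion * mu^2` (Poisson when the
#' dispersion is 0). The per-sample depth factor is the design's relative
#' library size times a log-uniform draw in `lib_variation`, exercising
#' size-factor normalization downstream. TF genes yield hard zero counts in
#' every genotype deleting that TF, mirroring the abolished expression of
#' *gaaR*, *araR* and *rhaR* in their own mutants.
#'
#' @param model `fr_model` from [build_model()].
#' @param design Design tibble from [build_design()].
#' @param seed Integer seed; identical inputs and seed give identical
#'   counts.
#' @param lib_variation Range of the multiplicative per-sample depth
#'   factor (drawn log-uniformly); `c(1, 1)` disables it.
#' @return Wide tibble: `gene_id` plus one integer count column per
#'   sample, in design order.
#' @export
simulate_counts <- function(model, design, seed = 1L,
                            lib_variation = c(0.8, 1.25)) {
  validate_design(design)
  stopifnot(inherits(model, "fr_model"))
  withr::with_seed(seed, {
    rel <- design$library_size / mean(design$library_size)
    depth <- rel * exp(runif(nrow(design), log(lib_variation[1]),
                             log(lib_variation[2])))
    mu <- ensure_matrix(model_means(model, design, depth), nrow(model))
    counts <- matrix(0L, nrow(model), nrow(design))
    for (s in seq_len(nrow(design))) {
      m <- mu[, s]
      k <- numeric(length(m))
      pos <- m > 0
      od <- model$dispersion > 0 & pos
      pois <- !od & pos
      if (any(od)) k[od] <- rnbinom(sum(od), size = 1 / model$dispersion[od],
                                    mu = m[od])
      if (any(pois)) k[pois] <- rpois(sum(pois), m[pois])
      counts[, s] <- as.integer(k)
    }
    colnames(counts) <- design$sample_id
    dplyr::bind_cols(tibble(gene_id = model$gene_id), as_tibble(counts))
  })
}

#' Generate promoter sequences with planted motifs
#'
#' Builds one promoter per model gene: i.i.d. background sequence with, for
#' every TF named in the gene's dependency expression, at least one planted
#' instance of that TF's binding motif (position uniform, non-overlapping;
#' strand drawn from `strands`). Instances are sampled uniformly from the
#' IUPAC pattern's expansion. The returned truth table makes planted sites
#' recoverable exactly, so scanner and discovery stages can be tested
#' against known positives.
#'
#' @param model `fr_model`.
#' @param motif_map Named character vector or list mapping TF letters to
#'   IUPAC patterns (default [tf_motif_patterns()], the published
#'   GaaR/AraR/RhaR elements).
#' @param promoter_len Promoter length in bp (default 1000, the 1-kb
#'   upstream window used for motif analysis).
#' @param background Named letter frequencies (A, C, G, T) summing to 1.
#' @param strands Strand(s) planted instances may take.
#' @param n_instances Planted instances per mentioned TF (default 1).
#' @param seed Integer seed.
#' @return List with `promoters` (tibble `gene_id`, `sequence`) and
#'   `truth` (tibble `gene_id`, `motif_id`, `strand`, `start`,
#'   `upstream_position`, `instance`). `upstream_position` is the distance
#'   from the start codon to the leftmost base of the window
#'   (`promoter_len - start + 1`).
#' @export
generate_promoters <- function(model, motif_map = tf_motif_patterns(),
                               promoter_len = 1000,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               strands = c("+", "-"),
                               n_instances = 1,
                               seed = 1L) {
  background <- check_background(background)
  motifs <- lapply(motif_map, parse_iupac)
  widths <- vapply(motifs, `[[`, numeric(1), "width")
  if (promoter_len < max(widths)) {
    abort("promoter_len must be at least the widest motif.")
  }
  letters4 <- c("A", "C", "G", "T")

  withr::with_seed(seed, {
    truth <- list()
    seqs <- character(nrow(model))
    for (i in seq_len(nrow(model))) {
      tfs <- if (model$dependency[i] %in% c("none", "complex")) character(0)
             else sort_literals(unique(unlist(model$clauses[[i]])))
      tfs <- rep(tfs, each = n_instances)
      ws <- widths[tfs]
      if (length(tfs) > 0 && sum(ws) > promoter_len) {
        abort(sprintf("Cannot plant %d motif instances in a %d bp promoter (gene %s).",
                      length(tfs), promoter_len, model$gene_id[i]))
      }
      seq_chars <- sample(letters4, promoter_len, replace = TRUE,
                          prob = background)
      occupied <- integer(0)
      for (k in seq_along(tfs)) {
        tf <- tfs[k]
        w <- widths[[tf]]
        ok <- FALSE
        for (try in 1:1000) {
          s <- sample.int(promoter_len - w + 1, 1)
          if (!any((s:(s + w - 1)) %in% occupied)) { ok <- TRUE; break }
        }
        if (!ok) abort(sprintf("Failed to place motif %s in gene %s.",
                               tf, model$gene_id[i]))
        inst <- vapply(motifs[[tf]]$sets, function(set) {
          set[sample.int(length(set), 1)]
        }, character(1))
        inst <- paste(inst, collapse = "")
        strand <- sample(strands, 1)
        planted <- if (strand == "+") inst else revcomp(inst)
        seq_chars[s:(s + w - 1)] <- strsplit(planted, "")[[1]]
        occupied <- c(occupied, s:(s + w - 1))
        truth[[length(truth) + 1]] <- tibble(
          gene_id = model$gene_id[i], motif_id = tf, strand = strand,
          start = s, upstream_position = promoter_len - s + 1,
          instance = inst)
      }
      seqs[i] <- paste(seq_chars, collapse = "")
    }
    list(
      promoters = tibble(gene_id = model$gene_id, sequence = seqs),
      truth = if (length(truth) > 0) dplyr::bind_rows(truth) else
        tibble(gene_id = character(), motif_id = character(),
               strand = character(), start = integer(),
               upstream_position = integer(), instance = character())
    )
  })
}
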