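#' Run the four-step triplet discovery pipeline on one cohort
#'
#' Orchestrates: (1) expression filtering, log2 transform and
#' permutation-calibrated differential expression; (2) co-expression
#' network construction and personalized-PageRank propagation from the ICP
#' genes; (3) purity-adjusted triplet scoring with enrichment, S scores and
#' permutation FDR; (4) regulatory pattern selection. Candidate (lncRNA,
#' ICP) pairs for scoring are the top-k propagated lncRNAs crossed with
#' the ICP seeds, screened by the PCC(ij) partial-correlation FDR inside
#' the scoring stage. Stage seeds are derived
#' deterministically from the master seed, so identical inputs and seed
#' reproduce identical outputs. A stage that fails or comes up empty marks
#' the manifest and downstream stages are skipped, leaving empty results.
#'
#' @param expr Raw-scale expression table (see [load_expression()]).
#' @param meta Sample metadata (tumor/normal, purity, survival).
#' @param catalog Gene role catalog.
#' @param pathways Named list of immune pathway gene sets.
#' @param fdr_de DE selection FDR (default 0.01).
#' @param fdr_triplet Triplet selection FDR (default 0.01).
#' @param fdr_edge Network edge retention FDR (default 0.01).
#' @param top_k Genes kept per role after propagation (default 200).
#' @param B Permutations for every permutation stage (default 1000).
#' @param seed Mandatory master seed.
#' @param gsea_p_cut Pathway enrichment cutoff (default 0.05).
#' @param use_purity Adjust correlations for tumor purity (default TRUE;
#'   FALSE gives the plain-correlation mode).
#' @param perm_mode S-score permutation mode, `"full"` or
#'   `"fixed_weights"` (see [triplet_permutation_fdr()]).
#' @param max_zero_fraction Expression-filter threshold (default 0.70).
#' @param alpha PageRank damping (default 0.85).
#' @param patterns Also call regulatory patterns (default TRUE).
#' @return An `icp_pipeline` list: `expr` (filtered log2), `de`, `edges`,
#'   `propagation`, `candidates`, `scores`, `triplets`, `calls`,
#'   `manifest`, `params`.
#' @export
run_pipeline <- function(expr, meta, catalog, pathways,
                         fdr_de = 0.01, fdr_triplet = 0.01,
                         fdr_edge = 0.01, top_k = 200L, B = 1000L, seed,
                         gsea_p_cut = 0.05, use_purity = TRUE,
                         perm_mode = c("fixed_weights", "full"),
                         max_zero_fraction = 0.70, alpha = 0.85,
                         patterns = TRUE) {
  check_seed(seed)
  perm_mode <- match.arg(perm_mode)
  params <- list(fdr_de = fdr_de, fdr_triplet = fdr_triplet,
                 fdr_edge = fdr_edge, top_k = top_k, B = B, seed = seed,
                 gsea_p_cut = gsea_p_cut, use_purity = use_purity,
                 perm_mode = perm_mode,
                 max_zero_fraction = max_zero_fraction, alpha = alpha)
  stopifnot(all(c(fdr_de, fdr_triplet, fdr_edge) > 0),
            all(c(fdr_de, fdr_triplet, fdr_edge) < 1))
  out <- list(params = params)
  manifest <- list()
  note <- function(stage, n, status = "ok") {
    manifest[[length(manifest) + 1L]] <<-
      tibble::tibble(stage = stage, n_records = n, status = status)
  }
  empty_triplets <- assemble_triplets(
    structure(list(pairs = tibble::tibble(lncRNA = character(),
                                          icp = character(), s = numeric(),
                                          n_immune = integer(),
                                          p_perm = numeric(),
                                          fdr = numeric())),
              class = "icp_triplet_scores"),
    fdr_cut = fdr_triplet)
  finish <- function() {
    out$manifest <- dplyr::bind_rows(manifest)
    out$triplets <- out$triplets %||% empty_triplets
    out$calls <- out$calls %||% tibble::tibble()
    structure(out, class = "icp_pipeline")
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      note(stage, 0L, paste0("failed: ", conditionMessage(e)))
      NULL
    })
  }
  cancer_type <- unique(meta$cancer_type)
  cancer_type <- if (length(cancer_type) == 1L && !is.na(cancer_type[1])) {
    as.character(cancer_type[1])
  } else "NA"

  # stage 1: filter + transform + differential expression
  de_sel <- run_stage("differential_expression", function() {
    filtered <- filter_low_expressed(expr, max_zero_fraction)
    lg <- log2_transform(filtered)
    al <- align_samples(lg, meta)
    out$expr <<- al$expr
    out$meta <<- al$meta
    de <- differential_expression(al$expr, al$meta)
    de <- permutation_adjust(al$expr, al$meta, de, B = B,
                             seed = stage_seed(seed, 1L))
    out$de <<- dplyr::left_join(de, catalog, by = "gene_id")
    select_de_genes(de, catalog, fdr_cut = fdr_de)
  })
  if (is.null(de_sel)) return(finish())
  note("differential_expression", nrow(de_sel))
  roles_present <- table(factor(de_sel$role,
                                c("lncRNA", "immune", "ICP")))
  if (roles_present["lncRNA"] == 0 || roles_present["ICP"] == 0 ||
      roles_present["immune"] < 2) {
    note("network", 0L, "skipped: too few DE genes per role")
    return(finish())
  }

  tum <- out$meta$group == "tumor"
  expr_t <- as_expr(expr_values(out$expr)[, tum, drop = FALSE],
                    is_log2 = TRUE)
  purity <- if (use_purity) out$meta$purity[tum] else NULL

  # stage 2: network + propagation
  cand <- run_stage("network_propagation", function() {
    de_expr <- as_expr(expr_values(expr_t)[de_sel$gene_id, , drop = FALSE],
                       is_log2 = TRUE)
    edges <- pearson_edges(de_expr, catalog, B = B,
                           seed = stage_seed(seed, 2L),
                           fdr_cut = fdr_edge)
    out$edges <<- edges
    icp_seeds <- intersect(de_sel$gene_id[de_sel$role == "ICP"],
                           attr(edges, "nodes")$gene_id)
    prop <- personalized_pagerank(edges, icp_seeds, alpha = alpha,
                                  catalog = catalog)
    out$propagation <<- prop
    list(lnc = top_k_proximal(prop, "lncRNA", top_k),
         immune = top_k_proximal(prop, "immune", top_k),
         icp = icp_seeds)
  })
  if (is.null(cand)) return(finish())
  out$candidates <- cand
  note("network_propagation", nrow(out$edges))
  if (length(cand$lnc) == 0L || length(cand$icp) == 0L ||
      length(cand$immune) < 2L) {
    note("triplet_scoring", 0L, "skipped: no candidate genes")
    return(finish())
  }

  # stage 3: triplet scoring over top-k lncRNAs x ICP seeds
  triplets <- run_stage("triplet_scoring", function() {
    sc <- score_triplets(expr_t, catalog, pathways, purity = purity,
                         lnc_genes = cand$lnc, immune_genes = cand$immune,
                         icp_genes = cand$icp,
                         B = B, seed = stage_seed(seed, 3L),
                         gsea_p_cut = gsea_p_cut, pair_fdr = fdr_triplet)
    if (nrow(sc$pairs) == 0L) return(empty_triplets)
    sc <- triplet_permutation_fdr(sc, B = B, seed = stage_seed(seed, 4L),
                                  mode = perm_mode)
    out$scores <<- sc
    assemble_triplets(sc, fdr_cut = fdr_triplet, cancer_type = cancer_type)
  })
  if (is.null(triplets)) return(finish())
  out$triplets <- triplets
  note("triplet_scoring",
       nrow(dplyr::distinct(triplets, .data$lncRNA, .data$icp)))
  if (!patterns || nrow(triplets) == 0L) return(finish())

  # stage 4: pattern inference
  calls <- run_stage("pattern_inference", function() {
    call_patterns(expr_t, triplets)
  })
  if (is.null(calls)) return(finish())
  out$calls <- calls
  note("pattern_inference", nrow(calls))
  finish()
}

#' @export
print.icp_pipeline <- function(x, ...) {
  cat("ICP-LncCRCT pipeline run\n")
  print(x$manifest)
  invisible(x)
}

#' Cross-cancer summary of pattern calls
#'
#' Per-cancer pattern proportions, plus pairwise overlap of lncRNAs and of
#' (lncRNA, ICP) pairs between cancers with hypergeometric tail p-values
#' (universe = union across all cancers).
#'
#' @param calls Pattern-call table across cancers (or list of per-cancer
#'   tables).
#' @return List with `proportions`, `lnc_overlap`, `pair_overlap` tibbles.
#' @export
cross_cancer_summary <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- dplyr::bind_rows(calls)
  proportions <- dplyr::count(calls, .data$cancer_type, .data$pattern)
  proportions <- dplyr::mutate(dplyr::group_by(proportions, .data$cancer_type),
                               prop = .data$n / sum(.data$n))
  proportions <- dplyr::ungroup(proportions)
  overlap_tbl <- function(items) {
    sets <- split(items$item, items$cancer_type)
    sets <- lapply(sets, unique)
    universe <- length(unique(items$item))
    cancers <- names(sets)
    if (length(cancers) < 2L) {
      return(tibble::tibble(cancer_a = cancers, cancer_b = cancers,
                            shared = lengths(sets), n_a = lengths(sets),
                            n_b = lengths(sets), universe = universe,
                            p_hyper = NA_real_))
    }
    combs <- utils::combn(cancers, 2L)
    rows <- lapply(seq_len(ncol(combs)), function(i) {
      a <- sets[[combs[1, i]]]; b <- sets[[combs[2, i]]]
      ov <- length(intersect(a, b))
      tibble::tibble(
        cancer_a = combs[1, i], cancer_b = combs[2, i], shared = ov,
        n_a = length(a), n_b = length(b), universe = universe,
        p_hyper = stats::phyper(ov - 1L, length(a), universe - length(a),
                                length(b), lower.tail = FALSE)
      )
    })
    dplyr::bind_rows(rows)
  }
  lnc_overlap <- overlap_tbl(
    tibble::tibble(item = calls$lncRNA, cancer_type = calls$cancer_type))
  pair_overlap <- overlap_tbl(
    tibble::tibble(item = paste(calls$lncRNA, calls$icp, sep = "|"),
                   cancer_type = calls$cancer_type))
  list(proportions = proportions, lnc_overlap = lnc_overlap,
       pair_overlap = pair_overlap)
}
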