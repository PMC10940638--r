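#' Synthetic multi-cancer cohorts with planted regulatory triplets
#'
#' The generator emits a raw-scale expression matrix, sample metadata,
#' gene catalog, immune pathway collection and a ground-truth record.
#' Planted (lncRNA, immune gene, ICP) triplets follow the structural
#' equations of one of the four regulatory patterns; tumor purity acts as
#' a confounder loaded onto immune and ICP genes (and onto decoy lncRNAs
#' whose only association with the immune system runs through purity);
#' tumor-vs-normal shifts drive the differential-expression stage; and
#' survival times follow an exponential proportional-hazards model on one
#' planted triplet.
#'
#' @name synthetic_data
NULL

#' Simulate one triplet under a regulatory pattern
#'
#' Structural equations (all noise terms independent N(0, sigma^2)):
#' * `INDEP`: L ~ N(0,1); C = a L + e; M = b L + e
#' * `COO`:   L, M ~ N(0,1) independent; C = a L + b M + e
#' * `LGI`:   L ~ N(0,1); M = a L + e; C = b M + e
#' * `LIG`:   L ~ N(0,1); C = a L + e; M = b C + e
#'
#' @param pattern One of `"INDEP"`, `"COO"`, `"LGI"`, `"LIG"`.
#' @param n Number of samples (>= 8).
#' @param a,b Structural coefficients (default 0.8).
#' @param sigma Noise standard deviation (default 0.5).
#' @param seed Mandatory RNG seed.
#' @return List of numeric vectors `L`, `M`, `C`.
#' @export
simulate_triplet <- function(pattern, n, a = 0.8, b = 0.8, sigma = 0.5,
                             seed) {
  check_seed(seed)
  if (n < 8L) abort("n must be >= 8")
  if (!pattern %in% pattern_levels) {
    abort(paste0("invalid pattern: ", pattern))
  }
  set.seed(seed)
  eps <- function() rnorm(n, 0, sigma)
  switch(pattern,
    INDEP = { L <- rnorm(n); C <- a * L + eps(); M <- b * L + eps()
              list(L = L, M = M, C = C) },
    COO = { L <- rnorm(n); M <- rnorm(n); C <- a * L + b * M + eps()
            list(L = L, M = M, C = C) },
    LGI = { L <- rnorm(n); M <- a * L + eps(); C <- b * M + eps()
            list(L = L, M = M, C = C) },
    LIG = { L <- rnorm(n); C <- a * L + eps(); M <- b * C + eps()
            list(L = L, M = M, C = C) }
  )
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: 60 tumor and 20 normal samples;
#' 50 lncRNAs, 200 immune genes, 10 ICP genes and 500 background genes;
#' one planted triplet per regulatory pattern at a = b = 0.8, sigma = 0.5;
#' five purity-decoy lncRNAs; a purity loading of 1 on immune/ICP genes; a
#' 2 log2-unit tumor-vs-normal shift on differentially expressed genes;
#' and survival tied to the first planted triplet.
#'
#' @param n_tumor,n_normal Sample counts.
#' @param n_lnc,n_immune,n_icp,n_background Gene counts per role.
#' @param planted Data frame with columns `pattern`, `a`, `b`, `sigma`,
#'   one row per planted triplet.
#' @param n_decoy_lnc Number of decoy lncRNAs associated with immune genes
#'   only through purity.
#' @param n_comembers Immune genes co-expressed with each planted immune
#'   gene (its regulatory module, hosted in the same pathways).
#' @param comember_cor Correlation of module co-members with the planted
#'   immune gene (default 0.7).
#' @param purity_effect Loading of (z-scored) purity on the
#'   infiltration-pathway immune genes, the ICP genes and the decoy
#'   lncRNAs.
#' @param n_purity_pathways Pathways whose member genes carry the purity
#'   loading (infiltration signatures; default 3).
#' @param de_effect Tumor-vs-normal shift (log2 units) on DE genes.
#' @param de_frac_immune,de_frac_lnc,de_frac_background Fractions of
#'   non-planted genes per role receiving the DE shift.
#' @param baseline_range Range of per-gene baseline log2 expression.
#' @param zero_rate Sporadic dropout probability for background genes.
#' @param n_dropout Background genes with ~80% zeros (removed by the
#'   expression filter).
#' @param survival List: `baseline_hazard`, `betas` (length 3),
#'   `censor_rate`, `triplet` (index of the risk triplet).
#' @param n_pathways,pathway_size Immune pathway collection shape.
#' @param cancer_type Cohort label.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tumor = 60L, n_normal = 20L, n_lnc = 50L,
                       n_immune = 200L, n_icp = 10L, n_background = 500L,
                       planted = tibble::tibble(
                         pattern = c("INDEP", "COO", "LGI", "LIG"),
                         a = 0.8, b = 0.8, sigma = 0.5),
                       n_decoy_lnc = 5L, n_comembers = 8L,
                       comember_cor = 0.7, purity_effect = 1,
                       n_purity_pathways = 3L,
                       de_effect = 2,
                       de_frac_immune = 0.5, de_frac_lnc = 0.5,
                       de_frac_background = 0.1,
                       baseline_range = c(3, 8),
                       zero_rate = 0.05, n_dropout = 25L,
                       survival = list(baseline_hazard = 0.1,
                                       betas = c(0.8, 0.8, 0.8),
                                       censor_rate = 0.03, triplet = 1L),
                       n_pathways = 18L, pathway_size = 25L,
                       cancer_type = "SIM", seed) {
  check_seed(seed)
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
              n_immune = n_immune, n_icp = n_icp,
              n_background = n_background, planted = planted,
              n_decoy_lnc = n_decoy_lnc, n_comembers = n_comembers,
              comember_cor = comember_cor, purity_effect = purity_effect,
              n_purity_pathways = n_purity_pathways,
              de_effect = de_effect, de_frac_immune = de_frac_immune,
              de_frac_lnc = de_frac_lnc,
              de_frac_background = de_frac_background,
              baseline_range = baseline_range, zero_rate = zero_rate,
              n_dropout = n_dropout, survival = survival,
              n_pathways = n_pathways, pathway_size = pathway_size,
              cancer_type = cancer_type, seed = as.integer(seed))
  counts <- c(n_tumor, n_normal, n_lnc, n_immune, n_icp, n_background)
  if (any(counts <= 0)) abort("all counts must be positive")
  if (nrow(planted) > 0 && any(planted$sigma <= 0)) abort("sigma must be > 0")
  if (nrow(planted) > min(n_lnc - n_decoy_lnc, n_icp) ||
      nrow(planted) * (1L + n_comembers) > n_immune) {
    abort("not enough genes to host the planted triplets")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic cohort with planted triplets
#'
#' @param config A [sim_config()].
#' @return An `icp_cohort`: list with `expr` (raw-scale expression table),
#'   `meta` (sample metadata), `catalog` (gene roles), `pathways` (named
#'   list of immune gene sets containing the planted immune genes),
#'   `truth` (planted triplets, DE genes, decoys, survival betas) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_tumor + cfg$n_normal
  tum <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))
  sample_id <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                 sprintf("N%03d", seq_len(cfg$n_normal)))
  lnc <- sprintf("LNC%03d", seq_len(cfg$n_lnc))
  imm <- sprintf("IMM%03d", seq_len(cfg$n_immune))
  icp <- sprintf("ICP%02d", seq_len(cfg$n_icp))
  bg <- sprintf("BG%04d", seq_len(cfg$n_background))
  genes <- c(lnc, imm, icp, bg)
  if (anyDuplicated(genes)) abort("gene-name collision in simulation")

  # latent signal on the log2 scale: baseline + core + shifts
  core <- matrix(rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, sample_id))

  npl <- nrow(cfg$planted)
  planted <- tibble::tibble(
    lncRNA = lnc[seq_len(npl)], immune_gene = imm[seq_len(npl)],
    icp = icp[seq_len(npl)], pattern = cfg$planted$pattern,
    a = cfg$planted$a, b = cfg$planted$b, sigma = cfg$planted$sigma
  )
  # co-expressed immune module around each planted immune gene
  nco <- cfg$n_comembers
  comembers <- lapply(seq_len(npl), function(j) {
    if (nco == 0L) return(character())
    imm[npl + (j - 1L) * nco + seq_len(nco)]
  })
  for (j in seq_len(npl)) {
    tri <- simulate_triplet(planted$pattern[j], cfg$n_tumor,
                            a = planted$a[j], b = planted$b[j],
                            sigma = planted$sigma[j],
                            seed = stage_seed(cfg$seed, 10L) + j)
    core[planted$lncRNA[j], tum] <- tri$L
    core[planted$immune_gene[j], tum] <- tri$M
    core[planted$icp[j], tum] <- tri$C
    if (nco > 0L) {
      cc <- cfg$comember_cor
      zM <- as.numeric(scale(tri$M))
      noise <- matrix(rnorm(nco * cfg$n_tumor, 0, sqrt(1 - cc^2)),
                      nco, cfg$n_tumor)
      core[comembers[[j]], tum] <- cc *
        matrix(zM, nco, cfg$n_tumor, byrow = TRUE) + noise
    }
  }

  decoy <- if (cfg$n_decoy_lnc > 0) {
    lnc[(cfg$n_lnc - cfg$n_decoy_lnc + 1L):cfg$n_lnc]
  } else character()

  # immune pathways: random sets hosting each planted module
  pathways <- simulate_pathways(imm, planted$immune_gene, comembers,
                                n_pathways = cfg$n_pathways,
                                size = cfg$pathway_size,
                                seed = stage_seed(cfg$seed, 20L))

  # purity confounder: infiltration-signature pathways, the ICP genes and
  # the decoy lncRNAs carry the loading
  purity <- rbeta(cfg$n_tumor, 5, 2)
  zp <- as.numeric(scale(purity))
  purity_pathways <- if (cfg$n_purity_pathways > 0) {
    sample(names(pathways), min(cfg$n_purity_pathways, length(pathways)))
  } else character()
  loaded <- unique(c(unlist(pathways[purity_pathways]), icp, decoy))
  core[loaded, tum] <- core[loaded, tum] +
    cfg$purity_effect * matrix(zp, length(loaded), cfg$n_tumor, byrow = TRUE)

  # tumor-vs-normal differential expression
  pick <- function(pool, frac) {
    k <- round(frac * length(pool))
    if (k > 0) sample(pool, k) else character()
  }
  module_genes <- c(planted$immune_gene, unlist(comembers))
  de_genes <- unique(c(
    planted$lncRNA, module_genes, planted$icp, decoy, icp,
    pick(setdiff(imm, module_genes), cfg$de_frac_immune),
    pick(setdiff(lnc, c(planted$lncRNA, decoy)), cfg$de_frac_lnc),
    pick(bg, cfg$de_frac_background)
  ))
  de_sign <- sample(c(-1, 1), length(de_genes), replace = TRUE)
  core[de_genes, tum] <- core[de_genes, tum] + de_sign * cfg$de_effect

  baseline <- runif(length(genes), cfg$baseline_range[1],
                    cfg$baseline_range[2])
  log2mat <- core + baseline
  raw <- pmax(2^log2mat - 1, 0)

  # zero inflation: sporadic dropouts on background genes, plus a block of
  # high-dropout genes the 70%-zero filter must remove
  if (cfg$zero_rate > 0) {
    zi <- matrix(runif(cfg$n_background * n) < cfg$zero_rate,
                 cfg$n_background, n)
    raw[bg, ][zi] <- 0
  }
  n_drop <- min(cfg$n_dropout, cfg$n_background)
  if (n_drop > 0) {
    drop_genes <- bg[seq_len(n_drop)]
    zi <- matrix(runif(n_drop * n) < 0.8, n_drop, n)
    raw[drop_genes, ][zi] <- 0
  }

  # survival tied to one planted triplet (tumor samples only)
  os_time <- rep(NA_real_, n); os_event <- rep(NA_real_, n)
  sv <- cfg$survival
  sv_genes <- character()
  if (!is.null(sv) && npl >= sv$triplet) {
    sv_genes <- unlist(planted[sv$triplet, c("lncRNA", "immune_gene", "icp")])
    Zr <- zscore_rows(log2mat[sv_genes, tum, drop = FALSE])
    risk <- as.numeric(crossprod(Zr, sv$betas))
    t_ev <- rexp(cfg$n_tumor, rate = sv$baseline_hazard * exp(risk))
    t_cs <- rexp(cfg$n_tumor, rate = sv$censor_rate)
    os_time[tum] <- pmin(t_ev, t_cs)
    os_event[tum] <- as.numeric(t_ev <= t_cs)
  }

  meta <- tibble::tibble(
    sample_id = sample_id,
    group = ifelse(tum, "tumor", "normal"),
    purity = replace(rep(NA_real_, n), tum, purity),
    os_time = os_time, os_event = os_event,
    cancer_type = cfg$cancer_type
  )
  catalog <- gene_catalog(lncRNA = lnc, immune = imm, icp = icp)
  truth <- list(planted = planted, comembers = comembers,
                de_genes = de_genes, decoy_lnc = decoy,
                purity_pathways = purity_pathways,
                purity_loaded = loaded,
                survival = list(genes = unname(sv_genes),
                                betas = sv$betas))
  structure(list(expr = as_expr(raw, is_log2 = FALSE), meta = meta,
                 catalog = catalog, pathways = pathways, truth = truth,
                 config = cfg),
            class = "icp_cohort")
}

# Immune pathway collection: random immune-gene sets; each planted immune
# gene and its co-member module are inserted into two host pathways so the
# module can drive enrichment.
simulate_pathways <- function(immune_genes, planted_immune, comembers,
                              n_pathways, size, seed) {
  set.seed(seed)
  sets <- lapply(seq_len(n_pathways), function(i) {
    sample(immune_genes, min(size, length(immune_genes)))
  })
  names(sets) <- sprintf("IMMUNE_PATHWAY_%02d", seq_len(n_pathways))
  for (j in seq_along(planted_immune)) {
    module <- c(planted_immune[j], comembers[[j]])
    host <- sample(n_pathways, 2L)
    for (h in host) {
      sets[[h]] <- unique(c(module, sets[[h]]))
    }
  }
  sets
}

#' Simulate a null cohort (no planted structure)
#'
#' All genes are i.i.d. noise around their baselines; the purity loading on
#' immune and ICP genes is retained (it is part of the null for the
#' purity-adjusted statistics) but there is no differential expression, no
#' planted triplet and no expression-linked survival.
#'
#' @param config A [sim_config()]; `planted`, DE and decoy settings are
#'   ignored.
#' @return An `icp_cohort` with empty ground truth.
#' @export
simulate_null_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$planted <- cfg$planted[0, ]
  cfg$n_decoy_lnc <- 0L
  cfg$de_frac_immune <- 0; cfg$de_frac_lnc <- 0; cfg$de_frac_background <- 0
  cfg$de_effect <- 0
  cfg$survival <- NULL
  out <- simulate_cohort(cfg)
  # independent survival, unlinked to expression
  set.seed(stage_seed(cfg$seed, 30L))
  tum <- out$meta$group == "tumor"
  t_ev <- rexp(sum(tum), rate = config$survival$baseline_hazard)
  t_cs <- rexp(sum(tum), rate = config$survival$censor_rate)
  out$meta$os_time[tum] <- pmin(t_ev, t_cs)
  out$meta$os_event[tum] <- as.numeric(t_ev <= t_cs)
  out$truth <- list(planted = out$truth$planted[0, ],
                    de_genes = character(), decoy_lnc = character(),
                    survival = NULL)
  out
}

#' Write a cohort's artifacts to a directory
#'
#' Emits `expr.tsv`, `meta.tsv`, `catalog.tsv`, `immune_pathways.gmt` and
#' `truth.json` (when jsonlite is available).
#'
#' @param cohort An `icp_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expr.tsv"))
  readr::write_tsv(cohort$meta, file.path(dir, "meta.tsv"))
  readr::write_tsv(cohort$catalog, file.path(dir, "catalog.tsv"))
  write_gene_sets(cohort$pathways, file.path(dir, "immune_pathways.gmt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
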