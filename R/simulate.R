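# Seeded generators emulating the paired LCM sampling design: one apical and
# one basal sample per subject and villus zone (tip/base), negative-binomial
# UMI counts with a basal library-size deficit, a matched log-normal iBAQ
# proteome with left-censored missingness, per-cell smFISH intensities with
# additive background, and a cell-type signature matrix with planted
# enterocyte-specific genes.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators with defaults
#' matching the study design being emulated: 8 human subjects, 5 mice, 4
#' proteomics patients, paired apical/basal samples at villus tip and base,
#' and a basal-compartment sequencing-depth deficit.
#'
#' @param n_genes Number of genes.
#' @param n_subjects_human,n_subjects_mouse Cohort sizes.
#' @param frac_polarized Fraction of genes truly polarized.
#' @param effect_size_log2 Absolute true log2 apical/basal ratio of polarized
#'   genes (signs are balanced half apical, half basal).
#' @param basal_depth_factor Basal library size as a fraction of the apical
#'   mean depth, in (0, 1].
#' @param dispersion Negative-binomial overdispersion (gamma-Poisson).
#' @param depth_mean Mean UMIs per apical sample.
#' @param frac_zonated Fraction of genes whose polarization shifts between
#'   villus tip and base.
#' @param zone_shift_log2 Absolute tip-minus-base shift of the log2 ratio for
#'   zonated genes.
#' @param proteome_detect_floor Abundance quantile below which simulated iBAQ
#'   values are censored to missing.
#' @param contaminant_frac Fraction of extra contaminant rows added to the
#'   simulated proteome.
#' @param n_subjects_proteome Proteomics cohort size.
#' @param ibaq_noise_sd Log2-scale noise SD of simulated iBAQ values.
#' @param seed Integer seed; all generators are fully reproducible from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_subjects_human = 8,
                       n_subjects_mouse = 5,
                       frac_polarized = 0.1,
                       effect_size_log2 = 1.5,
                       basal_depth_factor = 0.5,
                       dispersion = 0.15,
                       depth_mean = 1e5,
                       frac_zonated = 0,
                       zone_shift_log2 = 2,
                       proteome_detect_floor = 0.25,
                       contaminant_frac = 0.05,
                       n_subjects_proteome = 4,
                       ibaq_noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_subjects_human = as.integer(n_subjects_human),
    n_subjects_mouse = as.integer(n_subjects_mouse),
    frac_polarized = frac_polarized,
    effect_size_log2 = effect_size_log2,
    basal_depth_factor = basal_depth_factor,
    dispersion = dispersion,
    depth_mean = depth_mean,
    frac_zonated = frac_zonated,
    zone_shift_log2 = zone_shift_log2,
    proteome_detect_floor = proteome_detect_floor,
    contaminant_frac = contaminant_frac,
    n_subjects_proteome = as.integer(n_subjects_proteome),
    ibaq_noise_sd = ibaq_noise_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_genes <= 0L) stop("n_genes must be positive")
  if (cfg$n_subjects_human <= 0L || cfg$n_subjects_mouse <= 0L ||
      cfg$n_subjects_proteome <= 0L) {
    stop("subject counts must be positive")
  }
  for (f in c("frac_polarized", "frac_zonated", "proteome_detect_floor",
              "contaminant_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$basal_depth_factor <= 0 || cfg$basal_depth_factor > 1) {
    stop("basal_depth_factor must lie in (0, 1]")
  }
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  structure(cfg, class = "sim_config")
}

.gene_ids <- function(n, species) {
  stem <- sprintf("gene%05d", seq_len(n))
  if (species == "human") toupper(stem) else {
    paste0("Gene", substring(stem, 5))
  }
}

# Per-gene ground truth shared by both compartment profiles. Signs of
# polarized genes are balanced (half apical, half basal) so the two
# compartment profiles can be made to sum to the same total, which keeps the
# expected normalized ratio of every non-polarized gene at exactly 1.
.draw_truth <- function(cfg) {
  n <- cfg$n_genes
  L <- numeric(n)
  m <- round(cfg$frac_polarized * n)
  polarized <- rep(FALSE, n)
  if (m > 0L) {
    idx <- sample.int(n, m)
    polarized[idx] <- TRUE
    signs <- rep(c(1, -1), length.out = m)
    L[idx] <- signs * cfg$effect_size_log2
  }
  zonated <- rep(FALSE, n)
  shift <- numeric(n)
  mz <- round(cfg$frac_zonated * n)
  if (mz > 0L) {
    zidx <- sample.int(n, mz)
    zonated[zidx] <- TRUE
    shift[zidx] <- sample(c(1, -1), mz, replace = TRUE) * cfg$zone_shift_log2
  }
  data.frame(
    true_log2_ratio = L,
    is_polarized = polarized,
    is_zonated = zonated,
    true_zone_shift = shift
  )
}

# Build apical/basal relative-abundance profiles with per-gene ratio exactly
# 2^L after normalization. The baseline abundance of up-polarized genes is
# rescaled so both compartment profiles carry equal total mass.
.compartment_profiles <- function(rel, L) {
  B <- rel
  up <- L > 0
  dn <- L < 0
  if (any(up) && any(dn)) {
    alpha <- sum(rel[dn] * (1 - 2^L[dn])) / sum(rel[up] * (2^L[up] - 1))
    B[up] <- rel[up] * alpha
  }
  A <- B * 2^L
  list(apical = A / sum(A), basal = B / sum(B))
}

.rnbinom_mean <- function(mu, dispersion) {
  lambda <- stats::rgamma(length(mu), shape = 1 / dispersion,
                          scale = mu * dispersion)
  stats::rpois(length(mu), lambda)
}

#' Simulate a paired apical/basal LCM RNA-seq experiment
#'
#' Generates one apical and one basal UMI count sample per subject and villus
#' zone. Counts are gamma-Poisson (negative binomial) around
#' `depth * profile`, where the apical and basal relative-abundance profiles
#' are constructed so that the expected normalized apical/basal ratio of each
#' gene equals `2^true_log2_ratio` exactly (1 for non-polarized genes), and
#' basal samples carry `basal_depth_factor` times the apical depth. Zonated
#' genes shift their log2 ratio by `+shift/2` at the tip and `-shift/2` at
#' the base.
#'
#' @param config A [sim_config()].
#' @param species `"human"` or `"mouse"`; selects cohort size and gene-id
#'   style (human ids uppercase, mouse title-case).
#' @param truth Optional ground-truth data frame from a previous call, to
#'   reuse gene-level truth (e.g., for a matched second species).
#' @return A list with `counts` (a [count_matrix()]) and `truth` (per-gene
#'   data frame: `gene_id`, `true_log2_ratio`, `is_polarized`, `is_zonated`,
#'   `true_zone_shift`).
#' @export
simulate_lcm_rnaseq <- function(config, species = c("human", "mouse"),
                                truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  species <- match.arg(species)
  set.seed(config$seed + ifelse(species == "human", 0L, 1L))
  n_sub <- if (species == "human") config$n_subjects_human else config$n_subjects_mouse
  genes <- .gene_ids(config$n_genes, species)
  if (is.null(truth)) {
    truth <- .draw_truth(config)
  } else {
    stopifnot(nrow(truth) == config$n_genes)
    truth <- truth[, c("true_log2_ratio", "is_polarized", "is_zonated",
                       "true_zone_shift")]
  }
  rel <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1.5)
  rel <- rel / sum(rel)

  zones <- c("tip", "base")
  profiles <- lapply(zones, function(z) {
    Lz <- truth$true_log2_ratio + ifelse(truth$is_zonated,
                                         truth$true_zone_shift / 2 *
                                           ifelse(z == "tip", 1, -1), 0)
    .compartment_profiles(rel, Lz)
  })
  names(profiles) <- zones

  prefix <- if (species == "human") "H" else "M"
  meta <- expand.grid(
    compartment = c("apical", "basal"), zone = zones,
    subject = paste0(prefix, seq_len(n_sub)),
    stringsAsFactors = FALSE
  )
  meta$species <- species
  meta$sample_id <- paste(meta$subject, meta$zone, meta$compartment, sep = "_")
  meta <- meta[, c("sample_id", "subject", "species", "compartment", "zone")]

  vals <- matrix(0L, nrow = config$n_genes, ncol = nrow(meta),
                 dimnames = list(genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    depth <- config$depth_mean *
      if (meta$compartment[j] == "basal") config$basal_depth_factor else 1
    p <- profiles[[meta$zone[j]]][[meta$compartment[j]]]
    vals[, j] <- .rnbinom_mean(depth * p, config$dispersion)
  }
  tr <- cbind(gene_id = genes, truth)
  rownames(tr) <- NULL
  list(counts = count_matrix(vals, meta), truth = tr)
}

#' Simulate a matched human/mouse pair with orthology
#'
#' Generates human and mouse LCM RNA-seq experiments sharing gene-level
#' ground truth, with `n_changed` polarized genes sign-flipped in the mouse
#' (these are the true interspecies polarization changes), and the one-to-one
#' orthology table linking the species-native gene ids.
#'
#' @param config A [sim_config()].
#' @param n_changed Number of polarized genes whose polarization direction is
#'   flipped in the mouse.
#' @return A list with `human`, `mouse` (each as from
#'   [simulate_lcm_rnaseq()]), `orthology` (data frame `human_id`,
#'   `mouse_id`, `relationship`) and `changed_human_ids`.
#' @export
simulate_species_pair <- function(config, n_changed = 5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth_h <- .draw_truth(config)
  pol <- which(truth_h$is_polarized)
  if (n_changed > length(pol)) {
    stop("n_changed exceeds the number of polarized genes")
  }
  flip <- sort(sample(pol, n_changed))
  truth_m <- truth_h
  truth_m$true_log2_ratio[flip] <- -truth_m$true_log2_ratio[flip]
  human <- simulate_lcm_rnaseq(config, "human", truth = truth_h)
  mouse <- simulate_lcm_rnaseq(config, "mouse", truth = truth_m)
  orthology <- data.frame(
    human_id = human$truth$gene_id,
    mouse_id = mouse$truth$gene_id,
    relationship = "one2one"
  )
  list(
    human = human, mouse = mouse, orthology = orthology,
    changed_human_ids = human$truth$gene_id[flip]
  )
}

#' Simulate an LCM iBAQ proteome matched to RNA ground truth
#'
#' Log-normal iBAQ values per protein and sample: apical and basal means
#' differ by the per-protein true log2 ratio (taken from the RNA ground
#' truth), values below the `proteome_detect_floor` abundance quantile are
#' censored to missing (left-censoring, emulating detection limits), and
#' synthetic contaminant rows plus a unique-peptide-count column with some
#' rows below 2 are included so the cleaning filters have work to do.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth data frame from [simulate_lcm_rnaseq()].
#' @return A list with `proteins` (a [protein_table()], raw/unnormalized) and
#'   `truth` (per-protein `protein_id`, `true_log2_ratio`; contaminant rows
#'   carry NA).
#' @export
simulate_proteome <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  set.seed(config$seed + 2L)
  n_prot <- nrow(truth)
  prot_ids <- truth$gene_id
  L <- truth$true_log2_ratio

  meta <- expand.grid(
    compartment = c("apical", "basal"), zone = c("tip", "base"),
    subject = paste0("P", seq_len(config$n_subjects_proteome)),
    stringsAsFactors = FALSE
  )
  meta$species <- "human"
  meta$sample_id <- paste(meta$subject, meta$zone, meta$compartment, sep = "_")
  meta <- meta[, c("sample_id", "subject", "species", "compartment", "zone")]

  base_log2 <- stats::rnorm(n_prot, mean = 20, sd = 2)
  vals <- matrix(NA_real_, n_prot, nrow(meta),
                 dimnames = list(prot_ids, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    side <- if (meta$compartment[j] == "apical") 0.5 else -0.5
    vals[, j] <- 2^(base_log2 + side * L +
                      stats::rnorm(n_prot, 0, config$ibaq_noise_sd))
  }

  n_cont <- round(config$contaminant_frac * n_prot)
  if (n_cont > 0L) {
    cont_ids <- sprintf("CONT%04d", seq_len(n_cont))
    cont <- matrix(2^(stats::rnorm(n_cont * nrow(meta), 18, 2)),
                   n_cont, nrow(meta), dimnames = list(cont_ids, meta$sample_id))
    vals <- rbind(vals, cont)
  }
  contaminant <- c(rep(FALSE, n_prot), rep(TRUE, max(n_cont, 0L)))

  # left-censor low abundances
  if (config$proteome_detect_floor > 0) {
    floor_val <- stats::quantile(vals, config$proteome_detect_floor,
                                 na.rm = TRUE, names = FALSE)
    vals[vals < floor_val] <- NA_real_
  }

  peptides <- 2L + stats::rpois(nrow(vals), 5)
  low <- sample.int(nrow(vals), max(1L, round(0.05 * nrow(vals))))
  peptides[low] <- 1L

  tbl <- protein_table(vals, meta, peptides, contaminant)
  prot_truth <- data.frame(
    protein_id = rownames(vals),
    true_log2_ratio = c(L, rep(NA_real_, max(n_cont, 0L)))
  )
  list(proteins = tbl, truth = prot_truth)
}

#' Simulate per-cell smFISH intensity measurements
#'
#' Per cell, apical and basal median intensities are `background +
#' signal * noise`, where the apical/basal signal ratio is `true_ratio` and
#' the multiplicative log-normal noise has unit mean. Paired apical/basal
#' structure, per-cell areas and area-proportional spot-intensity sums are
#' included so both the intensity-ratio and spot-density statistics can be
#' exercised.
#'
#' @param n_subjects,n_cells Number of subjects and cells per subject.
#' @param true_ratio True apical/basal signal ratio (positive).
#' @param background Additive background intensity (nonnegative).
#' @param noise_sd Log-scale noise SD (must be positive).
#' @param seed Integer seed.
#' @return A data frame of class `"fish_measurements"` with one row per cell.
#' @export
simulate_fish_measurements <- function(n_subjects, n_cells, true_ratio,
                                       background, noise_sd, seed = 1L) {
  if (n_subjects < 1L || n_cells < 1L) stop("need at least 1 subject and 1 cell")
  if (true_ratio <= 0) stop("true_ratio must be positive")
  if (background < 0) stop("background must be nonnegative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  set.seed(seed)
  n <- n_subjects * n_cells
  noise <- function() exp(stats::rnorm(n, 0, noise_sd) - noise_sd^2 / 2)
  signal <- stats::rlnorm(n, meanlog = log(100), sdlog = 0.3)
  out <- data.frame(
    subject = rep(paste0("S", seq_len(n_subjects)), each = n_cells),
    cell_id = paste0("cell", seq_len(n)),
    apical_intensity = background + signal * true_ratio * noise(),
    basal_intensity = background + signal * noise(),
    apical_background = background,
    basal_background = background,
    apical_area = stats::runif(n, 50, 150),
    basal_area = stats::runif(n, 20, 60)
  )
  density <- signal / 10
  out$apical_spot_sum <- density * true_ratio * out$apical_area * noise()
  out$basal_spot_sum <- density * out$basal_area * noise()
  class(out) <- c("fish_measurements", "data.frame")
  out
}

#' Simulate a cell-type signature matrix with planted enterocyte-specific genes
#'
#' Builds a cell-type x gene signature matrix whose rows each sum to 1, in
#' which exactly `n_enterocyte_specific` planted genes satisfy the
#' enterocyte-specificity rule `(E + pn)/(N + pn) > 2 & E > 1e-5` (E =
#' enterocyte expression, N = max non-enterocyte expression, pn = smallest
#' positive entry) and every other gene fails it by construction.
#'
#' @param n_celltypes Number of cell types (>= 2; the first is "enterocyte").
#' @param n_genes Number of genes.
#' @param n_enterocyte_specific Number of planted specific genes.
#' @param seed Integer seed.
#' @return A list with `signature` (matrix, rows = cell types summing to 1)
#'   and `specific_genes` (character vector of planted gene ids).
#' @export
simulate_signature_matrix <- function(n_celltypes, n_genes,
                                      n_enterocyte_specific, seed = 1L) {
  if (n_celltypes < 2L) stop("need at least 2 cell types")
  if (n_enterocyte_specific > n_genes) {
    stop("n_enterocyte_specific cannot exceed n_genes")
  }
  set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  types <- c("enterocyte", paste0("celltype_", seq_len(n_celltypes - 1L) + 1L))
  other <- matrix(stats::rlnorm((n_celltypes - 1L) * n_genes, 0, 2),
                  nrow = n_celltypes - 1L,
                  dimnames = list(types[-1], genes))
  other <- other / rowSums(other)
  N <- apply(other, 2, max)

  planted <- sort(sample.int(n_genes, n_enterocyte_specific))
  is_planted <- seq_len(n_genes) %in% planted
  E <- numeric(n_genes)
  E[is_planted] <- pmax(3 * N[is_planted], 1e-4)
  mass_planted <- sum(E[is_planted])
  if (mass_planted >= 0.95) {
    stop("planted specific genes would exceed the enterocyte expression budget; ",
         "use fewer specific genes or more genes")
  }
  u <- stats::runif(n_genes, 0.05, 0.5)
  # non-planted enterocyte values: u*N rescaled so the row sums to 1, clamped
  # below 1.8*N so the specificity ratio stays < 2 regardless of the rescale
  free <- !is_planted
  beta <- 1
  clamped <- rep(FALSE, n_genes)
  for (iter in 1:50) {
    active <- free & !clamped
    denom <- sum(u[active] * N[active])
    if (denom <= 0) stop("degenerate signature construction")
    beta <- (1 - mass_planted - sum(1.8 * N[free & clamped])) / denom
    if (beta <= 0) {
      stop("planted specific genes leave no enterocyte expression budget")
    }
    newly <- active & (u * beta > 1.8)
    if (!any(newly)) break
    clamped <- clamped | newly
  }
  E[free & clamped] <- 1.8 * N[free & clamped]
  E[free & !clamped] <- u[free & !clamped] * beta * N[free & !clamped]

  sig <- rbind(enterocyte = E, other)
  rownames(sig) <- types
  # construction guarantee: verify the rule end-to-end
  pn <- min(sig[sig > 0])
  ratio <- (sig["enterocyte", ] + pn) / (N + pn)
  specific <- ratio > 2 & sig["enterocyte", ] > 1e-5
  if (!identical(unname(specific), unname(is_planted))) {
    stop("internal error: planted specificity pattern not realized")
  }
  list(signature = sig, specific_genes = genes[planted])
}
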