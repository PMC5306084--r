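#' Configuration for the synthetic expression-study generator
#'
#' Defaults emulate the study conditions of the array-based test systems:
#' log2 baseline intensities around N(7, 2^2), four biological replicates
#' per group, planted developmental and toxicant effects with absolute
#' log2 fold changes uniform on [1.5, 3.3] (2.8- to 10-fold, so both tiers
#' of the 2/5/10-fold analysis are populated), replicate noise of 0.3 log2
#' units, and a dominant antagonistic overlap (80%) between compound effects
#' and spontaneous development. 20,000 probes keep test runs fast; pass
#' \code{n_probes = 54675} for a full-size array.
#'
#' @param n_probes Number of probe sets.
#' @param n_replicates Biological replicates per group.
#' @param d_up,d_down Planted developmental up/down probe counts.
#' @param t_total Planted toxicant-deregulated probes per compound.
#' @param overlap Planted overlap (toxicant probes drawn from the
#'   developmental set); must not exceed \code{min(d_up + d_down, t_total)}.
#' @param antagonism_fraction Fraction of overlap probes whose toxicant
#'   effect opposes the developmental direction.
#' @param compounds Character vector of compound labels.
#' @param fc_range Range of planted |log2FC| (both developmental and
#'   toxicant effects).
#' @param noise_sd Replicate noise SD (log2).
#' @param baseline_mean,baseline_sd Per-probe baseline distribution (log2).
#' @param n_batches Number of batches (samples split evenly within each
#'   group, so batch is never confounded with biology).
#' @param batch_additive_sd SD of per-batch, per-probe additive offsets
#'   (log2; 0 disables).
#' @param batch_multiplicative Per-batch noise-scale factors (recycled;
#'   1 disables).
#' @param multi_map_rate Fraction of probes annotated to a second gene.
#' @return Config list, validated.
#' @export
synth_config <- function(n_probes = 20000, n_replicates = 4,
                         d_up = 500, d_down = 500,
                         t_total = 100, overlap = 50,
                         antagonism_fraction = 0.8,
                         compounds = "compound_1",
                         fc_range = c(1.5, 3.3), noise_sd = 0.3,
                         baseline_mean = 7, baseline_sd = 2,
                         n_batches = 1, batch_additive_sd = 0,
                         batch_multiplicative = 1,
                         multi_map_rate = 0.05) {
  cfg <- as.list(environment())
  D <- d_up + d_down
  if (overlap > min(D, t_total)) {
    stop("planted overlap exceeds min(D, T) = ", min(D, t_total))
  }
  if (D + t_total > n_probes) stop("planted counts exceed n_probes")
  if (antagonism_fraction < 0 || antagonism_fraction > 1) {
    stop("antagonism_fraction must be in [0, 1]")
  }
  cfg
}

#' Generate a synthetic expression study with planted truth
#'
#' Produces an expression matrix, sample design, probe annotation and a
#' truth object sufficient to compute the expected value of every
#' downstream statistic. Developmental shifts are applied to the
#' differentiated control and treated groups (treated cells still
#' differentiate); toxicant shifts apply to treated samples only, with the
#' configured overlap and antagonism structure. Fully reproducible from the
#' seed.
#'
#' @param config From \code{\link{synth_config}}.
#' @param seed Integer seed.
#' @return List with \code{matrix}, \code{design}, \code{annotation},
#'   \code{truth} (planted sets, per-probe effects, expected Dp/Di, batch
#'   parameters).
#' @export
generate_dataset <- function(config = synth_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_probes
  probes <- sprintf("PS%05d", seq_len(n))
  base <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

  D <- config$d_up + config$d_down
  d_idx <- sample.int(n, D)
  d_up_idx <- d_idx[seq_len(config$d_up)]
  d_down_idx <- d_idx[-seq_len(config$d_up)]
  d_eff <- numeric(n)
  d_eff[d_up_idx] <- stats::runif(config$d_up, config$fc_range[1], config$fc_range[2])
  d_eff[d_down_idx] <- -stats::runif(config$d_down, config$fc_range[1], config$fc_range[2])

  t_eff <- list()
  t_idx_all <- list()
  for (cm in config$compounds) {
    ov_idx <- sample(d_idx, config$overlap)
    rest <- sample(setdiff(seq_len(n), d_idx), config$t_total - config$overlap)
    eff <- numeric(n)
    antag <- stats::runif(config$overlap) < config$antagonism_fraction
    mag <- stats::runif(config$overlap, config$fc_range[1], config$fc_range[2])
    eff[ov_idx] <- ifelse(antag, -sign(d_eff[ov_idx]), sign(d_eff[ov_idx])) * mag
    eff[rest] <- sample(c(-1, 1), length(rest), replace = TRUE) *
      stats::runif(length(rest), config$fc_range[1], config$fc_range[2])
    t_eff[[cm]] <- eff
    t_idx_all[[cm]] <- sort(c(ov_idx, rest))
  }

  roles <- c(rep("day0_control", config$n_replicates),
             rep("diff_control", config$n_replicates),
             rep("treated", config$n_replicates * length(config$compounds)))
  compound <- c(rep(NA_character_, 2 * config$n_replicates),
                rep(config$compounds, each = config$n_replicates))
  sample_ids <- paste0("S", sprintf("%02d", seq_along(roles)), "_",
                       ifelse(is.na(compound), roles, compound))
  # balanced batch assignment within each group
  grp <- paste(roles, ifelse(is.na(compound), "", compound))
  batch <- character(length(roles))
  for (ix in split(seq_along(roles), grp)) {
    batch[ix] <- rep_len(paste0("batch", seq_len(config$n_batches)), length(ix))
  }

  batch_add <- matrix(0, n, config$n_batches)
  if (config$batch_additive_sd > 0) {
    batch_add[] <- stats::rnorm(n * config$n_batches, 0, config$batch_additive_sd)
  }
  batch_mult <- rep_len(config$batch_multiplicative, config$n_batches)

  m <- matrix(NA_real_, n, length(roles),
              dimnames = list(probes, sample_ids))
  for (j in seq_along(roles)) {
    mu <- base
    if (roles[j] != "day0_control") mu <- mu + d_eff
    if (roles[j] == "treated") mu <- mu + t_eff[[compound[j]]]
    b <- as.integer(sub("batch", "", batch[j]))
    m[, j] <- mu + batch_add[, b] +
      stats::rnorm(n, 0, config$noise_sd * batch_mult[b])
  }

  design <- data.frame(
    sample_id = sample_ids, role = roles, compound = compound,
    compound_class = ifelse(is.na(compound), NA, "synthetic"),
    concentration = ifelse(roles == "treated", 1, NA),
    conc_unit = ifelse(roles == "treated", "uM", NA),
    system = "synthetic", batch = unname(batch),
    replicate = stats::ave(seq_along(roles), grp, FUN = seq_along),
    stringsAsFactors = FALSE)

  n_genes <- ceiling(n / 2)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  ann <- data.frame(probe_id = probes,
                    symbol = genes[ceiling(seq_len(n) / 2)],
                    stringsAsFactors = FALSE)
  extra <- which(stats::runif(n) < config$multi_map_rate)
  if (length(extra)) {
    ann <- rbind(ann, data.frame(probe_id = probes[extra],
                                 symbol = sample(genes, length(extra),
                                                 replace = TRUE),
                                 stringsAsFactors = FALSE))
    ann <- unique(ann)
  }

  T_ <- config$t_total
  truth <- list(
    d_up = probes[d_up_idx], d_down = probes[d_down_idx],
    t_probes = lapply(t_idx_all, function(ix) probes[ix]),
    overlap = lapply(t_idx_all, function(ix) probes[intersect(ix, d_idx)]),
    d_effects = stats::setNames(d_eff, probes),
    t_effects = lapply(t_eff, stats::setNames, probes),
    expected_dp = config$overlap / D,
    expected_di = (config$overlap / T_) / (D / n),
    batch_additive = batch_add, batch_multiplicative = batch_mult,
    config = config, seed = seed)

  list(matrix = m, design = design, annotation = ann, truth = truth)
}

#' Generate a co-expressed transcription-factor panel with planted modules
#'
#' Latent-factor model: each module shares one factor, and each gene is
#' \code{sqrt(rho) * factor + sqrt(1 - rho) * noise}, giving within-module
#' correlation rho and ~0 across modules.
#'
#' @param n_modules Number of modules.
#' @param module_size Genes per module.
#' @param n_samples Number of samples.
#' @param rho Within-module correlation (default 0.8).
#' @param seed Integer seed.
#' @return List with \code{matrix} (genes x samples, gene names TF001...),
#'   \code{modules} (named integer vector, the planted membership).
#' @export
generate_coexpression <- function(n_modules = 3, module_size = 10,
                                  n_samples = 200, rho = 0.8, seed = 1) {
  if (n_modules < 2) stop("need at least 2 modules")
  set.seed(seed)
  g <- n_modules * module_size
  genes <- sprintf("TF%03d", seq_len(g))
  modules <- rep(seq_len(n_modules), each = module_size)
  factors <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  m <- sqrt(rho) * factors[modules, , drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(g * n_samples), g, n_samples)
  dimnames(m) <- list(genes, paste0("sample", seq_len(n_samples)))
  list(matrix = m, modules = stats::setNames(modules, genes))
}

#' Generate resazurin viability plates with 4PL truth
#'
#' Fluorescence = blank + span * 4PL(conc)/100 + noise, with vehicle and
#' blank wells included, five technical wells per concentration and three
#' biological replicate plates by default.
#'
#' @param concentrations Dilution series (ascending, > 0).
#' @param ec50,hill,top,bottom Truth parameters of the 4PL viability curve.
#' @param noise_sd Noise SD in viability percent points (0 = noiseless).
#' @param n_technical Technical wells per concentration.
#' @param n_biological Biological replicate plates.
#' @param blank_fluor,span Fluorescence offset and full-scale span.
#' @param seed Integer seed.
#' @return List with \code{plates} (list of plate data.frames with columns
#'   \code{well}, \code{concentration}, \code{conc_unit}, \code{role},
#'   \code{fluorescence}), \code{truth} (parameters and the implied EC10).
#' @export
generate_viability <- function(concentrations = c(1, 3.16, 10, 31.6, 100, 316),
                               ec50 = 30, hill = 1.5, top = 100, bottom = 0,
                               noise_sd = 0, n_technical = 5, n_biological = 3,
                               blank_fluor = 50, span = 1000, seed = 1) {
  if (length(concentrations) < 4) stop("need at least 4 concentrations")
  set.seed(seed)
  plates <- lapply(seq_len(n_biological), function(b) {
    rows <- list()
    for (conc in concentrations) {
      v <- four_pl(conc, top, bottom, ec50, hill) +
        stats::rnorm(n_technical, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        well = paste0("T", conc, "_", seq_len(n_technical)),
        concentration = conc, conc_unit = "uM", role = "treated",
        fluorescence = blank_fluor + span * v / 100)
    }
    vehicle <- 100 + stats::rnorm(n_technical, 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      well = paste0("V", seq_len(n_technical)), concentration = NA,
      conc_unit = NA, role = "vehicle_control",
      fluorescence = blank_fluor + span * vehicle / 100)
    rows[[length(rows) + 1L]] <- data.frame(
      well = paste0("B", seq_len(3)), concentration = NA, conc_unit = NA,
      role = "blank", fluorescence = rep(blank_fluor, 3))
    do.call(rbind, rows)
  })
  # concentration at which the truth curve reaches 90% viability
  ec10 <- if (top > 90 && bottom < 90) {
    10^(log10(ec50) + log10((top - 90) / (90 - bottom)) / hill)
  } else NA_real_
  list(plates = plates,
       truth = list(top = top, bottom = bottom, ec50 = ec50, hill = hill,
                    ec10 = ec10, concentrations = concentrations, seed = seed))
}
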