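#' Configuration for the synthetic panel generator
#'
#' The generator emulates a Biocrates p180-style targeted panel measured on
#' a breed-comparison design: log-normal concentrations, class-structured
#' metabolite names, sex and carcass-weight effects on a metabolite subset,
#' block correlation through shared latent factors, planted
#' group-discriminant metabolites with multiplicative effect sizes, QC
#' replicate pairs, and LOD annotation. Defaults mirror the study design
#' the pipeline targets: 3 breeds x 12 pigs, 186 metabolites in seven
#' analyte classes, two QC replicates on a single plate.
#'
#' @param n_groups number of sample groups (breeds).
#' @param n_per_group samples per group.
#' @param n_metabolites panel width.
#' @param n_discriminant metabolites planted as discriminant per group
#'   pair (each metabolite is assigned to one pair; its elevated level in
#'   the pair's first-listed group also shifts that group's contrasts with
#'   the remaining groups, as a breed-specific signature would).
#' @param effect_size_range fold-change range for planted effects
#'   (multiplicative, > 1).
#' @param log_mean_range range of per-metabolite base log-concentration
#'   means (natural log of micromolar).
#' @param log_sd_range range of per-metabolite log-scale standard
#'   deviations.
#' @param covariate_frac fraction of metabolites carrying each covariate
#'   effect (sex, weight); applied to independent random subsets so
#'   adjustment is non-trivial but not universal.
#' @param beta_weight_range per-kg log-scale slope range for the carcass
#'   weight effect.
#' @param beta_sex_range log-scale offset range for the sex effect
#'   (castrated male vs gilt).
#' @param block_sizes integer vector: sizes of correlated metabolite
#'   blocks (consecutive metabolites share a latent factor).
#' @param rho target within-block correlation on the log scale, in [0, 1).
#' @param lod_frac fraction of metabolites given a non-trivial limit of
#'   detection (the rest get LOD 0).
#' @param lod_quantile marginal quantile of the metabolite's distribution
#'   at which its LOD is placed; values below the LOD are reported as-is
#'   (no censoring of the stored number), with the LOD recorded.
#' @param qc_cv_percent target coefficient of variation of the QC
#'   replicate pair, in percent.
#' @param weight_mean,weight_sd carcass weight distribution (kg).
#' @param group_labels labels for the groups; defaults to the three
#'   Italian heavy pig breeds (ILA, ILW, IDU) then G4, G5, ...
#' @param seed integer seed fixing the whole generation stream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 3,
                       n_per_group = 12,
                       n_metabolites = 186,
                       n_discriminant = 8,
                       effect_size_range = c(1.5, 3),
                       log_mean_range = log(c(0.1, 500)),
                       log_sd_range = c(0.2, 0.6),
                       covariate_frac = 0.3,
                       beta_weight_range = c(-0.012, 0.012),
                       beta_sex_range = c(-0.4, 0.4),
                       block_sizes = rep(8L, 6),
                       rho = 0.5,
                       lod_frac = 0.1,
                       lod_quantile = 0.05,
                       qc_cv_percent = 10,
                       weight_mean = 130,
                       weight_sd = 8,
                       group_labels = NULL,
                       seed = 1L) {
  block_sizes <- as.integer(unlist(block_sizes))
  if (n_groups < 1 || n_per_group < 1 || n_metabolites < 1) {
    stop("counts must be >= 1")
  }
  n_pairs <- choose(n_groups, 2)
  if (n_pairs * n_discriminant > n_metabolites) {
    stop("n_discriminant (", n_discriminant, " per pair over ", n_pairs,
         " pairs) exceeds n_metabolites (", n_metabolites, ")")
  }
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (qc_cv_percent < 0) stop("qc_cv_percent must be >= 0")
  if (sum(block_sizes) > n_metabolites) {
    stop("block sizes exceed the number of metabolites")
  }
  if (is.null(group_labels)) {
    pool <- c("ILA", "ILW", "IDU", paste0("G", seq_len(max(0, n_groups - 3)) + 3))
    group_labels <- pool[seq_len(n_groups)]
  }
  if (length(group_labels) != n_groups) {
    stop("group_labels must have length n_groups")
  }
  structure(as.list(environment()), class = "sim_config")
}

# p180-like class composition: 21 AA, 40 AC, 19 BA, 1 hexose, 14 LysoPC,
# 76 PC, 15 SM out of 186; scaled proportionally for other panel widths.
panel_classes <- function(n_metabolites) {
  ref <- c(AA = 21, AC = 40, BA = 19, hexose = 1, LysoPC = 14, PC = 76,
           SM = 15)
  counts <- floor(ref / sum(ref) * n_metabolites)
  counts["hexose"] <- min(1, n_metabolites)
  while (sum(counts) < n_metabolites) {
    k <- which.max(ref / sum(ref) - counts / n_metabolites)
    counts[k] <- counts[k] + 1
  }
  while (sum(counts) > n_metabolites) {
    k <- which.max(counts)
    counts[k] <- counts[k] - 1
  }
  rep(names(counts), counts)
}

#' Generate a synthetic metabolite panel with ground truth
#'
#' Concentrations are drawn as
#' `exp(log_mean + group effect + beta_w * (w - mean(w)) + beta_s * s +
#' latent block factor + noise)`, so planted group effects are fold
#' changes, covariate confounding is linear on the log scale, and
#' within-block correlation is induced by a shared standard-normal factor
#' (weight `log_sd * sqrt(rho)`) — always a valid correlation structure.
#' Two QC replicate rows are generated from a common latent profile with
#' the configured CV.
#'
#' @param config a [sim_config()].
#' @return a list with elements `panel` (a [metabolite_panel()]) and
#'   `truth` (class `SyntheticTruth`: `discriminant_sets` mapping each
#'   ordered group pair `"A-B"` to its planted metabolites and realized
#'   fold changes, `covariate_effects` per metabolite, and
#'   `correlation_blocks`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  n_g <- cfg$n_groups
  n <- n_g * cfg$n_per_group
  p <- cfg$n_metabolites
  labels <- cfg$group_labels

  ## -- sample metadata ------------------------------------------------
  group <- rep(labels, each = cfg$n_per_group)
  sex <- character(n)
  for (g in seq_len(n_g)) {
    idx <- which(group == labels[g])
    # sex balance mirrors the reference design: 5 castrates / 7 gilts in
    # the first group, near-even elsewhere
    n_cm <- if (g == 1) floor(cfg$n_per_group * 5 / 12)
            else floor(cfg$n_per_group / 2)
    sex[idx] <- c(rep("castrated_male", n_cm),
                  rep("gilt", length(idx) - n_cm))
  }
  weight <- stats::rnorm(n, cfg$weight_mean, cfg$weight_sd)
  weight <- pmax(weight, cfg$weight_mean * 0.5)
  sample_id <- sprintf("%s_%02d", group,
                       stats::ave(seq_len(n), group, FUN = seq_along))

  ## -- metabolite skeleton --------------------------------------------
  classes <- panel_classes(p)
  met_names <- sprintf("%s_%03d", classes,
                       stats::ave(seq_len(p), classes, FUN = seq_along))
  log_mean <- stats::runif(p, cfg$log_mean_range[1], cfg$log_mean_range[2])
  log_sd <- stats::runif(p, cfg$log_sd_range[1], cfg$log_sd_range[2])

  ## -- correlation blocks ---------------------------------------------
  block_id <- rep(0L, p)
  if (length(cfg$block_sizes) > 0 && sum(cfg$block_sizes) > 0) {
    block_id[seq_len(sum(cfg$block_sizes))] <-
      rep(seq_along(cfg$block_sizes), cfg$block_sizes)
  }
  lambda <- ifelse(block_id > 0, log_sd * sqrt(cfg$rho), 0)
  eps_sd <- ifelse(block_id > 0, log_sd * sqrt(1 - cfg$rho), log_sd)

  ## -- planted group effects ------------------------------------------
  delta <- matrix(0, n_g, p, dimnames = list(labels, met_names))
  pair_assign <- list()
  if (n_g >= 2 && cfg$n_discriminant > 0) {
    pool <- sample.int(p)  # disjoint assignment across pairs
    k <- 0
    for (a in seq_len(n_g - 1)) {
      for (b in (a + 1):n_g) {
        take <- pool[(k + 1):(k + cfg$n_discriminant)]
        k <- k + cfg$n_discriminant
        eff <- stats::runif(length(take), cfg$effect_size_range[1],
                            cfg$effect_size_range[2])
        delta[a, take] <- delta[a, take] + log(eff)
        pair_assign[[paste(labels[a], labels[b], sep = "-")]] <-
          list(metabolites = met_names[take], effect = eff)
      }
    }
  }

  ## -- covariate effects ----------------------------------------------
  beta_w <- beta_s <- numeric(p)
  n_cov <- round(cfg$covariate_frac * p)
  if (n_cov > 0) {
    iw <- sample.int(p, n_cov)
    beta_w[iw] <- stats::runif(n_cov, cfg$beta_weight_range[1],
                               cfg$beta_weight_range[2])
    is <- sample.int(p, n_cov)
    beta_s[is] <- stats::runif(n_cov, cfg$beta_sex_range[1],
                               cfg$beta_sex_range[2])
  }

  ## -- draw concentrations --------------------------------------------
  s01 <- as.numeric(sex == "castrated_male")
  wc <- weight - mean(weight)
  n_blocks <- max(block_id)
  f <- if (n_blocks > 0) {
    matrix(stats::rnorm(n_blocks * n), n_blocks, n)
  } else {
    matrix(0, 0, n)
  }
  g_idx <- match(group, labels)
  log_conc <- matrix(0, n, p, dimnames = list(sample_id, met_names))
  for (j in seq_len(p)) {
    latent <- if (block_id[j] > 0) lambda[j] * f[block_id[j], ] else 0
    log_conc[, j] <- log_mean[j] + delta[g_idx, j] + beta_w[j] * wc +
      beta_s[j] * s01 + latent + stats::rnorm(n, 0, eps_sd[j])
  }
  conc <- exp(log_conc)

  ## -- QC replicate pair ----------------------------------------------
  qc_sd <- sqrt(log(1 + (cfg$qc_cv_percent / 100)^2))
  qc_profile <- exp(log_mean)
  qc <- matrix(qc_profile, 2, p, byrow = TRUE) *
    exp(matrix(stats::rnorm(2 * p, 0, qc_sd), 2, p))
  dimnames(qc) <- list(c("QC_01", "QC_02"), met_names)

  ## -- LOD annotation --------------------------------------------------
  lod <- numeric(p)
  n_lod <- round(cfg$lod_frac * p)
  if (n_lod > 0) {
    il <- sample.int(p, n_lod)
    lod[il] <- exp(log_mean[il] + stats::qnorm(cfg$lod_quantile) * log_sd[il])
  }

  sm <- data.frame(
    sample_id = c(sample_id, rownames(qc)),
    group = c(group, "QC", "QC"),
    sex = c(sex, "gilt", "gilt"),
    carcass_weight = c(weight, mean(weight), mean(weight)),
    is_qc = c(rep(FALSE, n), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  mm <- data.frame(name = met_names, analyte_class = classes, lod = lod,
                   stringsAsFactors = FALSE)
  panel <- metabolite_panel(rbind(conc, qc), sm, mm)

  # realized per-pair fold differences (includes spillover onto third
  # groups from breed-specific effects)
  disc <- list()
  if (n_g >= 2) {
    for (a in seq_len(n_g - 1)) {
      for (b in (a + 1):n_g) {
        d <- delta[a, ] - delta[b, ]
        hit <- which(d != 0)
        disc[[paste(labels[a], labels[b], sep = "-")]] <- list(
          metabolites = met_names[hit],
          effect = as.numeric(exp(abs(d[hit])))
        )
      }
    }
  }
  truth <- structure(
    list(
      discriminant_sets = disc,
      covariate_effects = data.frame(name = met_names, beta_weight = beta_w,
                                     beta_sex = beta_s,
                                     stringsAsFactors = FALSE),
      correlation_blocks = lapply(seq_len(n_blocks), function(b) {
        list(metabolites = met_names[block_id == b], rho = cfg$rho)
      })
    ),
    class = "SyntheticTruth"
  )
  list(panel = panel, truth = truth)
}

#' Write the standard fixture catalogue
#'
#' Generates four named panels covering the regimes the pipeline must
#' handle — `null` (no planted effects), `strong` (two groups of 12, ten
#' metabolites at fold change 3-4), `confounded` (covariate effects on
#' every metabolite), `censored` (heavy LOD annotation) — and writes each
#' as a wide TSV with a metabolite-metadata sidecar and a truth JSON, plus
#' a `manifest.json` recording the configurations and seeds so the suite
#' can be regenerated byte-identically.
#'
#' @param out_dir writable output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  configs <- fixture_configs()
  manifest <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    gen <- generate_panel(cfg)
    panel_path <- file.path(out_dir, paste0(nm, "_panel.tsv"))
    meta_path <- file.path(out_dir, paste0(nm, "_metabolites.tsv"))
    truth_path <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_panel(gen$panel, panel_path, metabolite_meta_path = meta_path)
    jsonlite::write_json(unclass(gen$truth), truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest[[nm]] <- list(seed = cfg$seed,
                           config = unclass(cfg),
                           files = basename(c(panel_path, meta_path,
                                              truth_path)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Catalogue definitions; seeds are part of the fixture identity.
fixture_configs <- function() {
  list(
    null = sim_config(n_groups = 3, n_per_group = 12, n_metabolites = 40,
                      n_discriminant = 0, block_sizes = rep(5L, 4),
                      seed = 101L),
    # strong-signal regime: fold 3.5-5 on tightly dispersed metabolites
    # (log-sd ~0.2), i.e. planted separation of roughly 4-6 within-group
    # SDs after the raw-scale residualization — near-separable by design
    strong = sim_config(n_groups = 2, n_per_group = 12, n_metabolites = 60,
                        n_discriminant = 10,
                        effect_size_range = c(3.5, 5),
                        log_sd_range = c(0.15, 0.25),
                        block_sizes = rep(6L, 4), seed = 202L),
    confounded = sim_config(n_groups = 2, n_per_group = 12,
                            n_metabolites = 40, n_discriminant = 6,
                            covariate_frac = 1,
                            beta_weight_range = c(0.02, 0.04),
                            beta_sex_range = c(0.3, 0.6),
                            block_sizes = rep(5L, 4), seed = 303L),
    censored = sim_config(n_groups = 3, n_per_group = 12,
                          n_metabolites = 40, n_discriminant = 4,
                          lod_frac = 0.4, lod_quantile = 0.25,
                          block_sizes = rep(5L, 4), seed = 404L)
  )
}
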