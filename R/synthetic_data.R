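# Seed-deterministic synthetic-data generators. Every table the pipeline
# consumes can be generated with known ground truth (emitted as a sidecar),
# so all downstream stages are testable without any external download.
# Noise models: multiplicative log-normal for concentrations and instrument
# readings (keeps values positive, matches GC/MIMS behavior), additive
# Gaussian for qPCR Cq, multinomial at the counts level for metagenomes.

#' Scenario configuration for the synthetic generators
#'
#' Defaults describe the study conditions the pipeline was built around:
#' seven flooded paddy samples at 31.3-36.7 degC and salinity 2; dissolved
#' N2O between roughly 124 and 236 nmol/L; potential rates centred on
#' R_N2 = 24.63 +/- 6.76 and R_N2O = 0.51 +/- 0.20 umol N kg^-1 h^-1; a
#' 100 umol/L 15NO3- spike at 99.6 % purity over a small ambient pool; and
#' gene-community shapes with Proteobacteria-dominated napA/nirS and a more
#' even nosZ_II community.
#'
#' @param seed RNG seed (integer).
#' @param n_samples number of field/soil samples.
#' @param r_n2_mean,r_n2_sd across-sample distribution of the true potential
#'   N2 production rate (umol N kg^-1 h^-1).
#' @param r_n2o_mean,r_n2o_sd same for the potential N2O emission rate.
#' @param ambient_no3_um ambient 14NO3- in the slurry (umol L^-1).
#' @param added_15no3_um 15NO3- spike (umol L^-1).
#' @param label_purity 15N atom fraction of the spike.
#' @param temp_range_c field temperature range (degC).
#' @param salinity field salinity.
#' @param dissolved_range_nmol_l range of true dissolved N2O (nmol L^-1).
#' @param gc_noise_rel relative SD of the GC headspace reading (log-normal).
#' @param mims_noise_rel relative SD of MIMS isotopologue amounts.
#' @param cq_noise_sd additive SD of qPCR Cq.
#' @param n_replicates vials per incubation group.
#' @param depth metagenome reads mapped per sample-gene (multinomial size).
#' @param orfs_per_gene ORFs generated per gene per sample.
#' @param community per-gene named list of Dirichlet concentration vectors
#'   over taxa; NULL uses a built-in paddy-like shape.
#' @param vote_fidelity probability that a nosZ reference hit matches the
#'   ORF's true clade.
#' @param gene_log10_means named log10 copies-per-gram means for qPCR genes.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_samples = 7L,
                            r_n2_mean = 24.63, r_n2_sd = 6.76,
                            r_n2o_mean = 0.51, r_n2o_sd = 0.20,
                            ambient_no3_um = 5, added_15no3_um = 100,
                            label_purity = 0.996,
                            temp_range_c = c(31.3, 36.7),
                            salinity = 2,
                            dissolved_range_nmol_l = c(123.65, 235.59),
                            gc_noise_rel = 0.03,
                            mims_noise_rel = 0.10,
                            cq_noise_sd = 0.1,
                            n_replicates = 3L,
                            depth = 1e5,
                            orfs_per_gene = 40L,
                            community = NULL,
                            vote_fidelity = 0.9,
                            gene_log10_means = c(`16S` = 10, nirS = 8.7,
                                                 nirK = 8.0, nosZ_I = 7.2,
                                                 nosZ_II = 8.4)) {
  stopifnot(n_samples >= 1, gc_noise_rel >= 0, mims_noise_rel >= 0,
            cq_noise_sd >= 0, r_n2_mean > 0, added_15no3_um > 0,
            vote_fidelity >= 0, vote_fidelity <= 1)
  if (is.null(community)) community <- .default_community()
  stopifnot(all(vapply(community, function(v) all(v > 0), logical(1))))
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 r_n2_mean = r_n2_mean, r_n2_sd = r_n2_sd,
                 r_n2o_mean = r_n2o_mean, r_n2o_sd = r_n2o_sd,
                 ambient_no3_um = ambient_no3_um,
                 added_15no3_um = added_15no3_um,
                 label_purity = label_purity,
                 temp_range_c = temp_range_c, salinity = salinity,
                 dissolved_range_nmol_l = dissolved_range_nmol_l,
                 gc_noise_rel = gc_noise_rel,
                 mims_noise_rel = mims_noise_rel,
                 cq_noise_sd = cq_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 depth = depth, orfs_per_gene = as.integer(orfs_per_gene),
                 community = community, vote_fidelity = vote_fidelity,
                 gene_log10_means = gene_log10_means),
            class = "scenario_config")
}

# Paddy-like Dirichlet concentrations: napA/nirS concentrated on
# Proteobacteria, nirK spread over unclassified/Proteo/Actino/Chloroflexi,
# norB Proteo-led with several nosZ-poor phyla, nosZ_II diverse.
.default_community <- function() {
  taxa <- c("Proteobacteria", "Actinobacteria", "Chloroflexi",
            "Acidobacteria", "Bacteroidetes", "Myxococcus",
            "Gemmatimonadetes", "unclassified bacteria")
  mk <- function(...) stats::setNames(c(...), taxa)
  list(
    napA = mk(70, 3, 1, 1, 1, 5, 1, 13),
    nirS = mk(89, 1, 2, 0.5, 0.5, 0.5, 0.5, 8),
    nirK = mk(32, 16, 13, 4, 2, 2, 2, 26),
    norB = mk(45, 9, 4, 6, 5, 6, 2, 20),
    nosZ_I = mk(80, 5, 1, 1, 1, 3, 0.5, 8),
    nosZ_II = mk(23, 5, 3, 16, 14, 11, 5, 16)
  )
}

# log-normal multiplicative jitter with relative SD `rel` and mean 1
.ln_jitter <- function(n, rel) {
  if (rel == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rel^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Dirichlet draw via normalized gammas
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(g / sum(g), names(alpha))
}

#' Generate a synthetic field survey with headspace measurements
#'
#' Physiochemistry is sampled within the configured field ranges; true
#' dissolved N2O is drawn per sample; headspace concentrations follow by
#' exact forward partitioning (the closed-form inverse of the headspace
#' mass balance) and are then perturbed by multiplicative GC noise. Vial
#' geometry: 12.5 mL vial with 5 mL He headspace over 7.5 mL water.
#'
#' @param cfg a [scenario_config()].
#' @return list of data.frames: `survey` (pipeline input) and `truth`
#'   (per-sample true dissolved concentration).
#' @export
gen_field_survey <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  temp_c <- stats::runif(n, cfg$temp_range_c[1], cfg$temp_range_c[2])
  true_cl <- stats::runif(n, cfg$dissolved_range_nmol_l[1],
                          cfg$dissolved_range_nmol_l[2])
  gas_ml <- rep(5, n)
  liq_ml <- rep(7.5, n)
  cg <- vapply(seq_len(n), function(i) {
    ctx <- solubility_context(temperature_c = temp_c[i],
                              salinity = cfg$salinity)
    dissolved_to_headspace(true_cl[i], gas_ml[i], liq_ml[i], ctx)
  }, numeric(1))
  cg_obs <- cg * .ln_jitter(n, cfg$gc_noise_rel)
  ids <- sprintf("S%d", seq_len(n))
  list(
    survey = data.frame(sample_id = ids, temp_c = temp_c,
                        salinity = cfg$salinity,
                        headspace_conc_nmol_l = cg_obs,
                        gas_volume_ml = gas_ml, liquid_volume_ml = liq_ml),
    truth = data.frame(sample_id = ids, true_dissolved_nmol_l = true_cl,
                       true_headspace_nmol_l = cg)
  )
}

#' Generate synthetic isotope-pairing incubation vials
#'
#' Per sample, replicate T0 and T2 vials. N2 produced over the interval is
#' allocated to 29N2 / 30N2 by the random-pairing proportions at the
#' configured 15N fraction (so at zero noise the estimator chain inverts the
#' generation exactly); dissolved N2O accumulates linearly at the true
#' emission rate. Instrument noise is multiplicative log-normal per vial.
#' Vial geometry: 1.5 g soil in 10.5 mL slurry (1:7 weight : volume).
#'
#' @param cfg a [scenario_config()].
#' @return list: `vials` (pipeline input), `labeling` (labeling table),
#'   `truth` (true per-sample rates and f15).
#' @export
gen_incubation <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples
  lab <- labeling_state(cfg$ambient_no3_um, cfg$added_15no3_um,
                        cfg$label_purity)
  f15 <- labeling_fraction(lab)$f15
  r_n2 <- pmax(stats::rnorm(n, cfg$r_n2_mean, cfg$r_n2_sd), 0.5)
  r_n2o <- pmax(stats::rnorm(n, cfg$r_n2o_mean, cfg$r_n2o_sd), 0.01)
  soil_g <- 1.5
  slurry_ml <- 10.5
  dt <- 2
  cl0 <- 0.05  # residual dissolved N2O after He flushing, umol/L
  ids <- sprintf("S%d", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    # per-litre N2O accumulation implied by the per-kg-N rate
    slope_um_l_h <- r_n2o[i] / 2 * (soil_g / 1000) / (slurry_ml / 1000)
    cl2 <- cl0 + slope_um_l_h * dt
    total_n2_n <- r_n2[i] * dt  # umol N per kg over the interval
    p30_true <- total_n2_n * f15 / 2
    d29_true <- total_n2_n * (1 - f15)
    for (rep_i in seq_len(cfg$n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[i], vial_id = sprintf("%s_t0_%d", ids[i], rep_i),
        group = "t0", time_h = 0,
        n2o_umol_l = cl0 * .ln_jitter(1, cfg$mims_noise_rel),
        d29 = 0, p30 = 0, soil_g = soil_g, slurry_ml = slurry_ml)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[i], vial_id = sprintf("%s_t2_%d", ids[i], rep_i),
        group = "t2", time_h = dt,
        n2o_umol_l = cl2 * .ln_jitter(1, cfg$mims_noise_rel),
        d29 = d29_true * .ln_jitter(1, cfg$mims_noise_rel),
        p30 = p30_true * .ln_jitter(1, cfg$mims_noise_rel),
        soil_g = soil_g, slurry_ml = slurry_ml)
    }
  }
  list(
    vials = do.call(rbind, rows),
    labeling = data.frame(sample_id = ids,
                          ambient_no3_um = cfg$ambient_no3_um,
                          added_15no3_um = cfg$added_15no3_um,
                          purity = cfg$label_purity),
    truth = data.frame(sample_id = ids, true_r_n2 = r_n2,
                       true_r_n2o = r_n2o, f15 = f15)
  )
}

#' Generate a synthetic annotated-ORF table with nosZ hit votes
#'
#' Per sample and gene, taxon TPM shares are drawn from the configured
#' Dirichlet; ORFs get uniform lengths (300-2000 bp) and multinomial read
#' counts whose length-weighted expectation reproduces the drawn shares.
#' With `exact = TRUE` counts are set to their (non-integer) expectations,
#' giving the infinite-depth limit in which aggregated shares equal the
#' Dirichlet draw exactly. nosZ ORFs carry a true clade and a 10-hit vote
#' list whose per-hit accuracy is `vote_fidelity`.
#'
#' @param cfg a [scenario_config()].
#' @param exact use expected counts instead of multinomial sampling.
#' @param nosz_ii_share probability a nosZ ORF is truly clade II.
#' @return list: `orfs`, `nosz_hits`, `truth_shares` (drawn per-taxon
#'   shares), `truth_clades` (true clade per nosZ ORF).
#' @export
gen_orf_table <- function(cfg, exact = FALSE, nosz_ii_share = 0.8) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 2L)
  ids <- sprintf("S%d", seq_len(cfg$n_samples))
  genes <- names(cfg$community)
  ko_of <- c(napA = "K02567", nirS = "K15864", nirK = "K00368",
             norB = "K04561", nosZ_I = "K00376", nosZ_II = "K00376")
  orf_rows <- list(); hit_rows <- list(); share_rows <- list()
  clade_rows <- list()
  for (sid in ids) {
    for (g in genes) {
      alpha <- cfg$community[[g]]
      shares <- .rdirichlet(alpha)
      taxa <- names(alpha)
      n_orf <- cfg$orfs_per_gene
      # assign each ORF a taxon proportional to shares, at least the
      # expected composition; per-ORF abundance = taxon share / ORFs in taxon
      taxon_of <- sample(taxa, n_orf, replace = TRUE, prob = shares)
      ab <- as.numeric(shares[taxon_of]) /
        as.numeric(table(taxon_of)[taxon_of])
      len <- round(stats::runif(n_orf, 300, 2000))
      p <- ab * len / sum(ab * len)
      counts <- if (exact) cfg$depth * p else
        as.numeric(stats::rmultinom(1, cfg$depth, p))
      # realized shares: taxa that drew no ORF carry no mass, so the truth
      # sidecar renormalizes over the taxa actually present
      realized <- vapply(taxa, function(t) sum(ab[taxon_of == t]), numeric(1))
      realized <- realized / sum(realized)
      gene_lab <- if (startsWith(g, "nosZ")) "nosZ" else g
      orf_ids <- sprintf("%s_%s_%03d", sid, g, seq_len(n_orf))
      orf_rows[[length(orf_rows) + 1]] <- data.frame(
        orf_id = orf_ids, sample_id = sid, ko_id = unname(ko_of[g]),
        taxon_lineage = paste0("d__Bacteria;p__",
                               ifelse(taxon_of == "unclassified bacteria",
                                      "", taxon_of)),
        length_bp = len, read_count = counts)
      share_rows[[length(share_rows) + 1]] <- data.frame(
        sample_id = sid, gene = g, taxon = taxa,
        dirichlet_share = as.numeric(shares),
        true_share = as.numeric(realized))
      if (startsWith(g, "nosZ")) {
        true_clade <- if (g == "nosZ_I") "I" else "II"
        for (oid in orf_ids) {
          correct <- stats::rbinom(10, 1, cfg$vote_fidelity) == 1
          hit_clade <- ifelse(correct, true_clade,
                              if (true_clade == "I") "II" else "I")
          hit_rows[[length(hit_rows) + 1]] <- data.frame(
            orf_id = oid, hit_rank = 1:10, clade = hit_clade)
          clade_rows[[length(clade_rows) + 1]] <- data.frame(
            orf_id = oid, true_clade = true_clade)
        }
      }
    }
  }
  list(orfs = do.call(rbind, orf_rows),
       nosz_hits = do.call(rbind, hit_rows),
       truth_shares = do.call(rbind, share_rows),
       truth_clades = do.call(rbind, clade_rows))
}

#' Generate synthetic qPCR standards and sample plates
#'
#' A 10-fold dilution series (10^3..10^8 copies, triplicate) around a slope
#' of -3.32 (near-100 % efficiency) plus per-sample true copy numbers drawn
#' log-normally around the configured per-gene means; Cq values carry
#' additive Gaussian noise.
#'
#' @param cfg a [scenario_config()].
#' @return list: `standards` (gene, log10_copies, cq), `samples` (sample_id,
#'   gene, cq, dilution, mass_g), `truth` (true copies per gram).
#' @export
gen_qpcr <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 3L)
  ids <- sprintf("S%d", seq_len(cfg$n_samples))
  genes <- names(cfg$gene_log10_means)
  slope <- -3.32
  intercept <- 38
  std_l10 <- rep(3:8, each = 3)
  std_rows <- lapply(genes, function(g) data.frame(
    gene = g, log10_copies = std_l10,
    cq = intercept + slope * std_l10 + stats::rnorm(length(std_l10), 0,
                                                    cfg$cq_noise_sd)))
  smp_rows <- list(); truth_rows <- list()
  for (g in genes) {
    true_cpg <- 10^stats::rnorm(cfg$n_samples, cfg$gene_log10_means[[g]], 0.3)
    cq <- intercept + slope * log10(true_cpg) +
      stats::rnorm(cfg$n_samples, 0, cfg$cq_noise_sd)
    smp_rows[[g]] <- data.frame(sample_id = ids, gene = g, cq = cq,
                                dilution = 1, mass_g = 1)
    truth_rows[[g]] <- data.frame(sample_id = ids, gene = g,
                                  true_copies_per_g = true_cpg)
  }
  list(standards = do.call(rbind, std_rows),
       samples = do.call(rbind, smp_rows),
       truth = do.call(rbind, truth_rows))
}
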