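# Declarative multi-stage pipeline: one config (list or YAML) drives the
# per-stage and cross-stage analyses and writes a reproducible TSV bundle
# plus a manifest. For a fixed config and seed the output TSVs are
# byte-identical across runs.

#' Default pipeline configuration
#'
#' All analysis defaults pre-filled: DLR threshold 3 Mb, long-range cutoff
#' 50 Mb, TAD size bounds 150-500 kb with delta 0.01, saddle quantiles and
#' corner fraction, radial cuts 20/80%, QC constants. Every field can be
#' overridden by the user config.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    stages = c("stage1", "stage2"),
    seed = 1,
    out_dir = "hicdyn_out",
    synthetic = list(
      chrom_lengths = c(chrA = 200e6, chrB = 150e6),
      resolution = 1e6,
      alpha = 1.0, s = 0.4, depth = 2e6, trans_level = 0.01,
      long_range_boost = 1.0, long_range_cutoff = 50e6,
      tad_boost = 1.0, switch_fraction = 0.02, ab_bias = 0.5
    ),
    params = list(
      min_fraction_of_median = 0.1,
      dlr_threshold = 3e6,
      long_range_cutoff = 50e6,
      n_log_bins = 20,
      saddle_quantiles = 20, corner_fraction = 0.2,
      insulation_windows = NULL,  # defaults to 3/5/10 bins at run time
      tad_delta = 0.01, tad_min = 150e3, tad_max = 500e3,
      pileup_flank = 0.5e6,
      inter_tad_edges = c(0, 20e6, 40e6, 60e6, 80e6, Inf),
      center_cut = 0.2, peripheral_cut = 0.8,
      qc_min_beads = 20, qc_sd_multiplier = 3, radius_top_fraction = 0.05
    ),
    ensemble = NULL
  )
}

# recursive override of defaults by user values
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

# rolling polynomial hash of a string, as 8 hex digits (manifest config
# fingerprint; stays within exact double-precision integer range)
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full multi-stage analysis from one configuration
#'
#' Per stage: coverage masking, balancing, distance-decay curve, long-range
#' fraction, compartment PC1 track, saddle and strength, DLR and ICF tracks
#' with compartment stratification, insulation track and TAD calls. Across
#' stages: switching tables, domain-strength dynamics on the
#' reference-stage TADs, inter-TAD distance proportions, and (if an
#' ensemble is configured) QC-filtered radial profiles. Everything is
#' written under `out_dir` together with a manifest recording the config,
#' its hash, the seed, and every file produced.
#'
#' @param config list or path to a YAML file; missing fields fall back to
#'   [default_config()].
#' @return (invisibly) list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (length(cfg$stages) == 0) stop("configuration error: empty stage list")
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write_tsv(df, path)
    files <<- c(files, path)
    path
  }

  syn <- cfg$synthetic
  genome <- genome_spec(unlist(syn$chrom_lengths), syn$resolution)
  nb <- n_bins(genome)
  n_stages <- length(cfg$stages)

  # --- inputs: simulate (or read) one matrix per stage ------------------
  if (!is.null(cfg$matrices)) {
    mats <- lapply(cfg$matrices, read_matrix)
    names(mats) <- cfg$stages
    profiles <- NULL
  } else {
    base_profile <- with_seed(cfg$seed, sample(c(1, -1), nb, replace = TRUE))
    stages <- lapply(seq_len(n_stages), function(k) {
      stage_spec(cfg$stages[k], alpha = syn$alpha, profile = base_profile,
                 s = syn$s, tad_boost = syn$tad_boost,
                 long_range_boost = syn$long_range_boost,
                 long_range_cutoff = syn$long_range_cutoff,
                 trans_level = syn$trans_level, depth = syn$depth,
                 seed = cfg$seed * 1000 + k)
    })
    series <- simulate_stage_series(genome, stages,
                                    switch_fraction = syn$switch_fraction,
                                    ab_bias = syn$ab_bias)
    mats <- series$matrices
    profiles <- series$profiles
    emit(series$switch_truth, "switch_truth.tsv")
  }

  # --- per-stage analyses ----------------------------------------------
  res <- list()
  tracks <- list()
  for (k in seq_len(n_stages)) {
    st <- cfg$stages[k]
    cm <- mask_low_coverage(mats[[k]], p$min_fraction_of_median)
    cm <- balance_matrix(cm)
    curve <- contact_frequency_vs_distance(cm, p$n_log_bins,
                                           use = "balanced",
                                           normalize = TRUE)
    lrf <- long_range_fraction(cm, p$long_range_cutoff)
    reference <- if (!is.null(profiles)) profiles[[k]] else
      if (!is.null(cfg$reference_track))
        read_bedgraph(cfg$reference_track, genome) else rowSums(cm$counts)
    ct <- compartment_track(cm, reference)
    sad <- saddle(cm, ct, n_quantiles = min(p$saddle_quantiles, nb),
                  corner_fraction = p$corner_fraction)
    ratios <- compartment_contact_ratio(cm, ct, scope = "cis")
    dlr_tr <- dlr(cm, p$dlr_threshold)
    icf_tr <- icf(cm)
    wins <- if (is.null(p$insulation_windows))
      cm$resolution * c(3, 5, 10) else p$insulation_windows
    ins <- insulation_score(cm, wins)
    tads_k <- find_boundaries(ins, delta = p$tad_delta,
                              min_size = p$tad_min, max_size = p$tad_max)
    emit(data.frame(ct), sprintf("%s_compartments.tsv", st))
    emit(curve, sprintf("%s_distance_curve.tsv", st))
    emit(data.frame(dlr_tr), sprintf("%s_dlr.tsv", st))
    emit(data.frame(icf_tr), sprintf("%s_icf.tsv", st))
    emit(data.frame(ins)[, 1:4], sprintf("%s_insulation.tsv", st))
    emit(tads_k$boundaries, sprintf("%s_boundaries.tsv", st))
    dlr_strat <- stratify_track(dlr_tr$dlr, ct$label,
                                test_groups = c("B", "A"))
    scalars <- data.frame(
      stage = st, long_range_fraction = lrf,
      compartment_strength = sad$strength,
      log2_AA = ratios["AA"], log2_BB = ratios["BB"], log2_AB = ratios["AB"],
      dlr_B_minus_A = dlr_strat$summary$mean[dlr_strat$summary$group == "B"] -
        dlr_strat$summary$mean[dlr_strat$summary$group == "A"],
      dlr_p_value = dlr_strat$test$p_value,
      mean_icf = mean(icf_tr$icf, na.rm = TRUE),
      n_boundaries = nrow(tads_k$boundaries))
    rownames(scalars) <- NULL
    res[[st]] <- list(matrix = cm, track = ct, saddle = sad, tads = tads_k,
                      scalars = scalars)
    tracks[[st]] <- ct
  }
  emit(do.call(rbind, lapply(res, `[[`, "scalars")), "stage_summary.tsv")

  # --- cross-stage analyses --------------------------------------------
  switch_rows <- NULL
  if (n_stages > 1) {
    for (k in 2:n_stages) {
      sw <- classify_switching(tracks[[k - 1]], tracks[[k]])
      switch_rows <- rbind(switch_rows, data.frame(
        transition = paste(cfg$stages[k - 1], cfg$stages[k], sep = ">"),
        t(as.numeric(sw$counts)),
        switching_fraction = sw$switching_fraction))
    }
    colnames(switch_rows)[2:5] <- c("A_A", "A_B", "B_A", "B_B")
    emit(switch_rows, "switching.tsv")
  }
  ref_tads <- res[[1]]$tads
  dynamics <- NULL
  if (nrow(ref_tads$domains) > 0) {
    dynamics <- strength_dynamics(lapply(res, `[[`, "matrix"), ref_tads)
    emit(dynamics$dynamics, "tad_strength_dynamics.tsv")
  }
  itp <- lapply(cfg$stages, function(st) {
    if (nrow(ref_tads$domains) == 0) return(NULL)
    cbind(stage = st,
          inter_tad_distance_proportions(res[[st]]$matrix, ref_tads,
                                         p$inter_tad_edges))
  })
  itp <- do.call(rbind, itp)
  if (!is.null(itp)) emit(itp, "inter_tad_proportions.tsv")

  # --- radial profiles --------------------------------------------------
  radial <- NULL
  if (!is.null(cfg$ensemble)) {
    en <- cfg$ensemble
    rgenome <- genome_spec(unlist(en$chrom_lengths), en$resolution)
    rbins <- genome_bins(rgenome)
    lads <- if (!is.null(en$lads)) en$lads else NULL
    lad_flag <- bin_in_intervals(rbins, lads)
    es <- ensemble_spec(en$n_models, rbins[, c("chrom", "start", "end")],
                        lad_flag = lad_flag, radius = en$radius,
                        beta = en$beta,
                        degraded_fraction = en$degraded_fraction %||% 0,
                        seed = cfg$seed + 7L)
    ens <- simulate_bead_ensemble(es)
    qc <- qc_filter(ens, min_beads = p$qc_min_beads,
                    sd_multiplier = p$qc_sd_multiplier,
                    top_fraction = p$radius_top_fraction)
    prof <- ensemble_radial_profile(qc$ensemble, rgenome, lads,
                                    center_cut = p$center_cut,
                                    peripheral_cut = p$peripheral_cut)
    emit(data.frame(prof), "radial_profile.tsv")
    emit(qc$exclusions, "radial_exclusions.tsv")
    radial <- list(qc = qc, profile = prof)
  }

  manifest <- list(
    package = "hicdyn",
    version = as.character(utils::packageVersion("hicdyn")),
    seed = cfg$seed,
    config = cfg,
    config_hash = fnv1a(jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                                         auto_unbox = TRUE, digits = NA)),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(stages = res, switching = switch_rows, dynamics = dynamics,
                 inter_tad = itp, radial = radial, manifest = manifest,
                 files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
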