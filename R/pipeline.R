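#' Pipeline configuration
#'
#' Exactly one of `scenario` (a [sim_scenario()] or preset name) or
#' `input` (path to a GenePop file, with `dialect`) must be given.
#'
#' @param scenario a [sim_scenario()] or a [make_preset()] name
#' @param input path to a GenePop genotype file
#' @param dialect [file_dialect()] for `input`
#' @param k_grid K values for the admixture scan
#' @param r replicates per K
#' @param sampler a [sampler_config()] (its seed is overridden by `seed`)
#' @param block_size,n_permutations,stability_window block-protocol settings
#' @param mode_threshold mode-partition similarity threshold
#' @param flock settings list for the reallocation stages
#' @param dapc settings list (`k_max`, `retained_pcs`, `retained_das`)
#' @param power optional [power_design()] to run
#' @param out_dir output directory for artifacts
#' @param seed global seed; every stage derives its own stream from it
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(scenario = NULL, input = NULL,
                            dialect = file_dialect("genepop"),
                            k_grid = 2:8, r = 10L,
                            sampler = sampler_config(),
                            block_size = 5L, n_permutations = 10L,
                            stability_window = 4L,
                            mode_threshold = 0.9,
                            flock = list(), dapc = list(), power = NULL,
                            out_dir = tempfile("msatclust_run_"),
                            seed = 1L) {
  if (is.null(scenario) == is.null(input))
    stop("exactly one of scenario/input must be given")
  structure(list(scenario = scenario, input = input, dialect = dialect,
                 k_grid = as.integer(k_grid), r = as.integer(r),
                 sampler = sampler, block_size = as.integer(block_size),
                 n_permutations = as.integer(n_permutations),
                 stability_window = as.integer(stability_window),
                 mode_threshold = mode_threshold, flock = flock,
                 dapc = dapc, power = power, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  path
}

#' Run the full evaluation pipeline
#'
#' simulate/load -> summary statistics (F-statistics, pairwise F_ST, PCoA)
#' -> admixture K-scan -> delta-K / block-convergence / mode / ghost
#' diagnostics -> hierarchical reallocation clustering -> DAPC ->
#' consolidated JSON report comparing `K_opt[Evanno]`, `K_opt[Pritchard]`,
#' `K_opt[FLOCK]`, `K_opt[DAPC]` and the clean-K set.  Per-stage artifacts
#' are written to `cfg$out_dir`; the K-scan is cached there so diagnostics
#' can be re-run cheaply.
#'
#' @param cfg a [pipeline_config()]
#' @param stages character vector of stages to run (default all)
#' @return a `pipeline_report` list (also written as `report.json`)
#' @export
run_pipeline <- function(cfg, stages = c("data", "stats", "kscan", "diagnose",
                                         "flock", "dapc", "power", "report")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  log_msg <- function(...) message("[msatclust] ", sprintf(...))
  t0 <- proc.time()[3]

  cached <- function(name, producer) {
    f <- file.path(cache_dir, paste0(name, ".rds"))
    if (file.exists(f)) {
      obj <- readRDS(f)
      if (identical(obj$cfg_seed, cfg$seed)) {
        log_msg("stage %-8s: cached", name)
        return(obj$value)
      }
    }
    t1 <- proc.time()[3]
    value <- producer()
    saveRDS(list(cfg_seed = cfg$seed, value = value), f)
    log_msg("stage %-8s: %.1fs", name, proc.time()[3] - t1)
    value
  }

  # data
  g <- cached("data", function() {
    if (!is.null(cfg$input)) return(read_genepop(cfg$input, cfg$dialect))
    if (is.character(cfg$scenario)) return(make_preset(cfg$scenario,
                                                       seed = cfg$seed)$genotypes)
    s <- cfg$scenario; s$seed <- derive_seed(cfg$seed, "scenario")
    sample_genotypes(sample_frequencies(s), s)
  })
  write_genepop(g, file.path(cfg$out_dir, "genotypes.gen"))
  report <- list(seed = cfg$seed, n_individuals = n_ind(g),
                 n_loci = n_loci(g), n_populations = nlevels(g$pop))

  if ("stats" %in% stages) {
    st <- cached("stats", function() {
      fs <- wc_f_statistics(g)
      fmat <- pairwise_fst_matrix(g)
      pc <- pcoa(fmat)
      list(fstat = fs, fst_matrix = fmat, pcoa = pc)
    })
    utils::write.csv(st$fst_matrix, file.path(cfg$out_dir, "pairwise_fst.csv"))
    utils::write.csv(st$pcoa$coordinates, file.path(cfg$out_dir, "pcoa_coordinates.csv"))
    report$f_st <- st$fstat$f_st; report$f_is <- st$fstat$f_is
    report$pcoa_explained <- st$pcoa$explained[seq_len(min(3, length(st$pcoa$explained)))]
  }

  scan <- NULL
  if (any(c("kscan", "diagnose", "report") %in% stages)) {
    scan <- cached("kscan", function() {
      smp <- cfg$sampler; smp$seed <- derive_seed(cfg$seed, "kscan")
      run_kscan(g, cfg$k_grid, cfg$r, smp)
    })
  }

  if ("diagnose" %in% stages && !is.null(scan)) {
    diag <- cached("diagnose", function() {
      dk <- evanno_delta_k(scan)
      pk <- pritchard_kopt(scan)
      br <- block_analysis(scan, cfg$block_size, cfg$n_permutations,
                           cfg$stability_window, derive_seed(cfg$seed, "blocks"))
      parts <- list(); ghosts <- list()
      for (k in scan$grid) {
        key <- as.character(k)
        parts[[key]] <- align_and_partition_modes(scan$runs[[key]],
                                                  cfg$mode_threshold)
        mq <- mean_q_by_population(parts[[key]]$mean_q_major, g$pop)
        ghosts[[key]] <- detect_ghosts(mq)
      }
      list(delta_k = dk, pritchard = pk, blocks = br, partitions = parts,
           ghosts = ghosts, clean_k = clean_k_set(parts, ghosts))
    })
    utils::write.csv(data.frame(k = diag$delta_k$k_interior,
                                delta_k = diag$delta_k$delta_k),
                     file.path(cfg$out_dir, "delta_k.csv"), row.names = FALSE)
    report$k_opt_evanno <- diag$delta_k$k_opt_evanno
    report$k_opt_pritchard <- diag$pritchard
    report$block_verdict <- diag$blocks$verdict
    report$clean_k <- diag$clean_k
    report$n_ghosts_by_k <- vapply(diag$ghosts, function(gh) gh$n_ghosts, integer(1))
    report$major_fraction_by_k <- vapply(diag$partitions,
                                         function(p) p$major_fraction, numeric(1))
  }

  if ("flock" %in% stages) {
    fl <- cached("flock", function() {
      fcfg <- utils::modifyList(list(seed = derive_seed(cfg$seed, "flock")),
                                cfg$flock)
      hierarchical_flock(g, fcfg)
    })
    report$k_opt_flock <- fl$k_opt_flock
    report$flock_leaves <- lapply(fl$leaves, identity)
  }

  if ("dapc" %in% stages) {
    dp <- cached("dapc", function() {
      dcfg <- cfg$dapc
      dapc_engine(g,
                  k_max = dcfg$k_max %||% NULL,
                  retained_pcs = dcfg$retained_pcs %||% 50L,
                  retained_das = dcfg$retained_das %||% 8L,
                  seed = derive_seed(cfg$seed, "dapc"))
    })
    utils::write.csv(dp$bic_curve, file.path(cfg$out_dir, "dapc_bic.csv"),
                     row.names = FALSE)
    report$k_opt_dapc <- dp$k_opt_dapc
    if (!is.null(dp$dapc))
      report$dapc_mean_reassignment <- mean(dp$dapc$reassignment)
  }

  if ("power" %in% stages && !is.null(cfg$power)) {
    pw <- cached("power", function() {
      power_sim(sim_scenario(n_pops = 1, seed = derive_seed(cfg$seed, "powerbase")),
                cfg$power, seed = derive_seed(cfg$seed, "power"))
    })
    report$power <- as.list(pw$rejection)
  }

  report$elapsed_s <- round(proc.time()[3] - t0, 1)
  report$elapsed_s <- NULL  # keep report byte-identical across re-runs
  write_json_artifact(report, file.path(cfg$out_dir, "report.json"))
  structure(report, class = "pipeline_report")
}

#' Re-run the pipeline on a population subset
#'
#' @param cfg a [pipeline_config()]
#' @param pops character vector of population labels to keep
#' @param ... passed on to [run_pipeline()]
#' @return a `pipeline_report` for the restricted dataset
#' @export
subset_reanalysis <- function(cfg, pops, ...) {
  if (!length(pops)) stop("empty population subset")
  full_g <- if (!is.null(cfg$input)) {
    read_genepop(cfg$input, cfg$dialect)
  } else if (is.character(cfg$scenario)) {
    make_preset(cfg$scenario, seed = cfg$seed)$genotypes
  } else {
    s <- cfg$scenario; s$seed <- derive_seed(cfg$seed, "scenario")
    sample_genotypes(sample_frequencies(s), s)
  }
  sub <- subset_populations(full_g, pops)
  subdir <- file.path(cfg$out_dir, paste0("subset_", length(pops), "pops"))
  f <- file.path(subdir, "subset.gen")
  dir.create(subdir, showWarnings = FALSE, recursive = TRUE)
  write_genepop(sub, f)
  cfg2 <- cfg
  cfg2$scenario <- NULL; cfg2$input <- f
  cfg2$out_dir <- subdir
  run_pipeline(cfg2, ...)
}
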