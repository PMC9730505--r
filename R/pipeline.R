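# End-to-end orchestration: one declarative config drives registry
# synthesis/loading, cohort generation, TcEMM derivation, survival
# screening, Lasso selection with post-selection inference, network
# profiling, positional comparison and (optionally) a registry
# version-sensitivity run. All artifacts are written with a checksum
# manifest; identical config + seed reproduce identical checksums.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param registry_fasta optional path to a registry FASTA; if `NULL`, a
#'   synthetic registry is generated.
#' @param registry_version version tag of the (loaded or synthetic)
#'   registry.
#' @param n_alleles_per_locus,n_polymorphic_sites synthetic-registry size.
#' @param n_haplotypes haplotype-pool size.
#' @param n_pairs cohort size.
#' @param q_bind presentation-model binding fraction.
#' @param self_repertoire_binding_filtered engine flag (see
#'   [derive_tcemm()]).
#' @param n_planted,planted_beta number and common AFT log-time coefficient
#'   of planted harmful cores (chosen among frequent cores at dry run).
#' @param min_support screening support filter.
#' @param alpha screening significance threshold on q.
#' @param n_folds cross-validation folds for the Lasso.
#' @param posi_method `"split"` or `"naive"`.
#' @param network_beta soft power for the adjacency.
#' @param adjacency_threshold network edge cutoff.
#' @param n_perm permutations for the positional comparison.
#' @param version_diff if `TRUE`, also run a registry version-sensitivity
#'   analysis against a copy of the registry with one edited allele.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       registry_fasta = NULL, registry_version = "synth-1",
                       n_alleles_per_locus = 4L, n_polymorphic_sites = 10L,
                       n_haplotypes = 12L, n_pairs = 2000L,
                       q_bind = 0.2,
                       self_repertoire_binding_filtered = FALSE,
                       n_planted = 5L, planted_beta = -0.5,
                       min_support = 50L, alpha = 0.05,
                       n_folds = 10L, posi_method = "split",
                       network_beta = 4, adjacency_threshold = 0.3,
                       n_perm = 1000L, version_diff = FALSE) {
  cfg <- as.list(environment())
  if (!is.null(cfg$registry_fasta) && !file.exists(cfg$registry_fasta)) {
    stop("registry FASTA not found: ", cfg$registry_fasta, call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key: '", unknown[1L], "'", call. = FALSE)
  }
  do.call(run_config, vals)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes registry setup, cohort generation (with planted effects),
#' per-TcEMM screening, Lasso selection with post-selection inference,
#' co-expression profiling, positional comparison and, optionally, a
#' registry version-sensitivity analysis, writing every artifact plus an
#' MD5 checksum manifest into `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return the manifest (named list of file checksums plus summary
#'   statistics), invisibly also written as `manifest.json`.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seeds <- derive_seeds(config$seed, 8L, salt = 3L)

  stage_log("registry", "setting up")
  registry <- if (!is.null(config$registry_fasta)) {
    load_registry(config$registry_fasta, config$registry_version)
  } else {
    synthesize_registry(config$n_alleles_per_locus,
                        config$n_polymorphic_sites, seeds[1L],
                        version_tag = config$registry_version)
  }
  write_registry(registry, out("registry.fasta"))
  jsonlite::write_json(registry_summary(registry), out("registry.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  model <- default_presentation_model(registry, q_bind = config$q_bind,
                                      seed = seeds[2L])
  pool <- sample_haplotype_pool(registry, config$n_haplotypes, seeds[3L])

  stage_log("cohort", "generating ", config$n_pairs, " pairs")
  # dry run to find plantable cores, then the definitive cohort
  base_cfg <- cohort_config(n_pairs = config$n_pairs, seed = seeds[4L])
  dry <- generate_cohort(registry, pool, model, base_cfg)
  planted <- if (config$n_planted > 0) {
    cores <- choose_planted_cores(dry$matrix, config$n_planted,
                                  support_range = c(config$min_support,
                                                    0.8 * config$n_pairs))
    setNames(rep(config$planted_beta, length(cores)), cores)
  } else numeric(0)
  cfg <- cohort_config(n_pairs = config$n_pairs, seed = seeds[4L],
                       planted_effects = planted)
  gen <- generate_cohort(registry, pool, model, cfg,
                         precomputed = dry[c("pairs", "matrix")])
  write_pair_table(gen$pairs, out("pairs.tsv"))
  write.table(gen$cohort, out("cohort.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_tcemm_matrix(gen$matrix, out("tcemm_matrix.tsv"))
  write.table(data.frame(pair_id = names(gen$matrix$scores),
                         pirche_score = as.integer(gen$matrix$scores)),
              out("scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(planted_effects = as.list(gen$truth$planted_effects),
                            mu = gen$truth$mu, sigma = gen$truth$sigma,
                            event_fraction = gen$truth$event_fraction),
                       out("truth.json"), auto_unbox = TRUE, pretty = TRUE)

  stage_log("screen", "AFT screening")
  screen <- screen_tcemm(gen$cohort, gen$matrix,
                         min_support = config$min_support)
  write.table(screen, out("screen.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  assoc <- score_association(gen$cohort, gen$matrix$scores)

  stage_log("select", "Lasso + post-selection inference")
  X_base <- cohort_design(gen$cohort)
  keep <- gen$matrix$support >= config$min_support &
    gen$matrix$support < config$n_pairs
  X_tcemm <- as.matrix(gen$matrix$incidence[, keep, drop = FALSE])
  design <- cbind(X_tcemm, X_base)
  penalized <- c(rep(TRUE, ncol(X_tcemm)), rep(FALSE, ncol(X_base)))
  path <- cv_select_lambda(gen$cohort$time, gen$cohort$event, design,
                           penalized, n_folds = config$n_folds,
                           seed = seeds[5L])
  posi <- posi_inference(gen$cohort$time, gen$cohort$event, design,
                         penalized, method = config$posi_method,
                         seed = seeds[6L],
                         class_origin = gen$matrix$class_origin)
  sel_tab <- data.frame(tcemm = colnames(X_tcemm),
                        class_origin = unname(gen$matrix$class_origin[keep]),
                        selected = colnames(X_tcemm) %in% path$selected,
                        posi_significant = colnames(X_tcemm) %in%
                          posi$posi_significant,
                        stringsAsFactors = FALSE)
  write.table(sel_tab, out("selection.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(lambda = path$lambdas, cv_mean = path$cv_mean,
                         cv_se = path$cv_se, n_nonzero = path$n_nonzero),
              out("cv_curve.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  stage_log("network", "co-expression profiles")
  net <- soft_adjacency(tcemm_correlation(gen$matrix,
                                          min_support = config$min_support),
                        beta = config$network_beta)
  prof <- build_profiles(net, config$adjacency_threshold)
  ann <- data.frame(tcemm = screen$tcemm,
                    aft_significant = !is.na(screen$q) &
                      screen$q < config$alpha,
                    lasso_selected = screen$tcemm %in% path$selected,
                    posi_significant = screen$tcemm %in%
                      posi$posi_significant)
  export_graph(net, prof, ann, out("network.graphml"), "graphml")
  prof_tab <- do.call(rbind, c(list(
    data.frame(tcemm = character(0), profile = integer(0))),
    lapply(seq_along(prof$profiles), function(i) {
      data.frame(tcemm = prof$profiles[[i]], profile = i)
    })))
  write.table(prof_tab, out("profiles.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  stage_log("logo", "positional comparison")
  logo <- NULL
  unsel <- setdiff(sel_tab$tcemm, path$selected)
  if (length(path$selected) >= 2 && length(unsel) >= 2) {
    logo <- compare_position_groups(path$selected, unsel,
                                    n_perm = config$n_perm,
                                    seed = seeds[7L])
    write.table(logo, out("logo.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    stage_log("logo", "skipped (fewer than 2 cores in a group)")
  }

  vdiff <- NULL
  if (isTRUE(config$version_diff)) {
    stage_log("version", "registry sensitivity")
    rec <- registry$records
    target <- rec$name[rec$locus == "B"][1L]
    pos <- max(1L, rec$length[match(target, rec$name)] %/% 2L)
    cur <- substr(rec$sequence[match(target, rec$name)], pos, pos)
    reg2 <- edit_registry_allele(registry, target, pos,
                                 setdiff(AMINO_ACIDS, cur)[1L],
                                 paste0(registry$version_tag, "+1"))
    vdiff <- diff_versions(gen$pairs, registry, reg2, model)
    jsonlite::write_json(vdiff[c("version_v1", "version_v2",
                                 "n_tcemm_only_v1", "n_tcemm_only_v2",
                                 "n_tcemm_population_diff",
                                 "n_pairs_affected",
                                 "fraction_pairs_affected")],
                         out("version_diff.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    write.table(vdiff$pair_changes, out("version_diff_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_pairs = config$n_pairs,
    n_distinct_tcemm = length(gen$matrix$tcemm_ids),
    event_fraction = gen$truth$event_fraction,
    n_screened = sum(screen$included),
    n_aft_associated = sum(!is.na(screen$q) & screen$q < config$alpha),
    n_selected = length(path$selected),
    n_posi_significant = length(posi$posi_significant),
    hr_log_score_univariable = assoc$univariable$hr,
    hr_log_score_multivariable = assoc$multivariable$hr,
    n_profiles = length(prof$profiles),
    fraction_in_profiles = prof$fraction_in_profiles)
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(checksums) <- files
  manifest <- list(summary = summary, checksums = checksums)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_log("done", length(files), " artifacts in ", config$out_dir)
  invisible(manifest)
}
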