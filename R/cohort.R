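# Synthetic transplant cohorts: LD-structured genotypes sampled from a
# haplotype pool, clinical covariates, and death-censored graft-failure
# times from a Weibull accelerated-failure-time model with planted per-core
# effects and administrative censoring.

#' Haplotype pool constructor
#'
#' A pool of five-locus haplotypes with frequencies. Sampling whole
#' haplotypes (rather than independent alleles per locus) induces linkage
#' disequilibrium between loci, and hence correlated TcEMM columns, as in
#' real HLA data.
#'
#' @param haplotypes data frame with columns `A`, `B`, `C`, `DRB1`, `DQB1`
#'   of allele names; one row per haplotype.
#' @param frequencies nonnegative weights summing to 1 (tolerance 1e-9).
#' @param registry optional `hla_registry`; if given, all alleles are
#'   checked to resolve in it.
#' @return A `haplotype_pool` object.
#' @export
haplotype_pool <- function(haplotypes, frequencies, registry = NULL) {
  stopifnot(is.data.frame(haplotypes),
            all(HLA_LOCI %in% names(haplotypes)),
            nrow(haplotypes) == length(frequencies))
  if (nrow(haplotypes) == 0L) stop("empty haplotype pool", call. = FALSE)
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-9) {
    stop("haplotype frequencies must be nonnegative and sum to 1",
         call. = FALSE)
  }
  if (!is.null(registry)) {
    registry_sequences(registry,
                       unique(unlist(haplotypes[HLA_LOCI],
                                     use.names = FALSE)))
  }
  structure(list(haplotypes = haplotypes[HLA_LOCI],
                 frequencies = frequencies),
            class = "haplotype_pool")
}

#' Sample a random haplotype pool from a registry
#'
#' Draws `n_haplotypes` five-locus allele combinations from the registry
#' (without replacement among combinations where possible) and Dirichlet(1)
#' frequencies, giving an unequal, LD-inducing haplotype distribution.
#'
#' @param registry an `hla_registry`.
#' @param n_haplotypes number of haplotypes.
#' @param seed integer seed.
#' @return A `haplotype_pool`.
#' @export
sample_haplotype_pool <- function(registry, n_haplotypes, seed) {
  rec <- registry$records
  withr::with_seed(seed, {
    hap <- as.data.frame(lapply(setNames(HLA_LOCI, HLA_LOCI), function(l) {
      alleles <- rec$name[rec$locus == l]
      sample(alleles, n_haplotypes, replace = TRUE)
    }), stringsAsFactors = FALSE)
    hap <- unique(hap)
    w <- rexp(nrow(hap))
    haplotype_pool(hap, w / sum(w), registry)
  })
}

#' Sample pair genotypes from a haplotype pool
#'
#' Each individual is two independent haplotype draws; donors and
#' recipients are drawn independently of one another.
#'
#' @param pool a `haplotype_pool`.
#' @param n_pairs number of donor:recipient pairs.
#' @param seed integer seed.
#' @return list of `pair_genotype` objects with ids `"P0001"`, ....
#' @export
sample_genotypes <- function(pool, n_pairs, seed) {
  stopifnot(n_pairs >= 1)
  H <- nrow(pool$haplotypes)
  withr::with_seed(seed, {
    draws <- matrix(sample.int(H, 4L * n_pairs, replace = TRUE,
                               prob = pool$frequencies), ncol = 4L)
    lapply(seq_len(n_pairs), function(i) {
      gt <- function(h1, h2) {
        setNames(lapply(HLA_LOCI, function(l) {
          c(pool$haplotypes[[l]][h1], pool$haplotypes[[l]][h2])
        }), HLA_LOCI)
      }
      pair_genotype(sprintf("P%05d", i),
                    donor = gt(draws[i, 1L], draws[i, 2L]),
                    recipient = gt(draws[i, 3L], draws[i, 4L]))
    })
  })
}

# Default clinical covariate distributions. Continuous scales are years,
# hours or ratios; categories follow rough US deceased-donor program
# proportions. All draws are complete (no missingness is simulated).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate clinical covariates
#'
#' Draws a complete covariate block for `n_pairs` transplant pairs:
#' recipient age/sex/time on dialysis/insurance, donor age/sex/type,
#' transplant era, induction agent, calcineurin-inhibitor type, steroid
#' use, cold-ischemia time and donor:recipient weight ratio.
#'
#' @param n_pairs number of rows.
#' @param seed integer seed.
#' @return data frame with one row per pair; factors for categoricals.
#' @export
generate_covariates <- function(n_pairs, seed) {
  withr::with_seed(seed, {
    data.frame(
      recip_age = rtrunc_norm(n_pairs, 50, 13, 18, 80),
      recip_sex = factor(ifelse(rbinom(n_pairs, 1, 0.40) == 1, "F", "M"),
                         levels = c("M", "F")),
      dialysis_years = pmin(rexp(n_pairs, rate = 1 / 2.5), 12),
      insurance = factor(sample(c("public", "private", "other"), n_pairs,
                                replace = TRUE, prob = c(0.55, 0.35, 0.10)),
                         levels = c("public", "private", "other")),
      donor_age = rtrunc_norm(n_pairs, 42, 15, 5, 75),
      donor_sex = factor(ifelse(rbinom(n_pairs, 1, 0.5) == 1, "F", "M"),
                         levels = c("M", "F")),
      donor_type = factor(ifelse(rbinom(n_pairs, 1, 0.65) == 1,
                                 "deceased", "living"),
                          levels = c("deceased", "living")),
      era = factor(sample(c("2000-2004", "2005-2009", "2010-2015"), n_pairs,
                          replace = TRUE, prob = c(0.30, 0.35, 0.35)),
                   levels = c("2000-2004", "2005-2009", "2010-2015")),
      induction = factor(sample(c("depleting", "nondepleting", "none"),
                                n_pairs, replace = TRUE,
                                prob = c(0.45, 0.30, 0.25)),
                         levels = c("depleting", "nondepleting", "none")),
      cni_type = factor(ifelse(rbinom(n_pairs, 1, 0.75) == 1,
                               "tacrolimus", "cyclosporine"),
                        levels = c("tacrolimus", "cyclosporine")),
      steroid = factor(ifelse(rbinom(n_pairs, 1, 0.70) == 1, "yes", "no"),
                       levels = c("yes", "no")),
      cold_ischemia_h = pmin(rgamma(n_pairs, shape = 3, scale = 14 / 3), 48),
      weight_ratio = rlnorm(n_pairs, meanlog = 0, sdlog = 0.25),
      stringsAsFactors = FALSE)
  })
}

# Expand a covariate data frame into a numeric design matrix: continuous
# columns centered and scaled, factors as treatment-coded indicators.
covariate_design <- function(covariates, scale_continuous = TRUE) {
  num <- vapply(covariates, is.numeric, logical(1))
  X <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  if (scale_continuous) {
    for (cn in names(covariates)[num]) {
      if (cn %in% colnames(X)) {
        v <- X[, cn]
        s <- sd(v)
        X[, cn] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
      }
    }
  }
  X
}

# Default modest covariate effects (AFT log-time scale, per design column
# of the centered/scaled design); kept small so planted TcEMM signal
# dominates.
default_covariate_betas <- function() {
  c(recip_age = -0.10, recip_sexF = 0.05, dialysis_years = -0.08,
    insuranceprivate = 0.05, insuranceother = 0.00,
    donor_age = -0.15, donor_sexF = 0.00, donor_typeliving = 0.20,
    `era2005-2009` = 0.05, `era2010-2015` = 0.10,
    inductionnondepleting = -0.05, inductionnone = -0.08,
    cni_typecyclosporine = -0.10, steroidno = 0.00,
    cold_ischemia_h = -0.08, weight_ratio = 0.05)
}

#' Cohort simulation configuration
#'
#' Collects the parameters of the synthetic data-generating model. Defaults
#' follow a registry-scale kidney-transplant setting scaled to desk size:
#' administrative censoring at 15 years, Weibull AFT with scale
#' `weibull_sigma = 0.9`, an independent random censoring (death) process,
#' and a target death-censored graft-failure event fraction of 0.17 reached
#' by tuning the log-time intercept.
#'
#' @param n_pairs number of donor:recipient pairs (>= 2).
#' @param seed integer master seed.
#' @param admin_censor_time administrative censoring horizon (years).
#' @param weibull_mu log-time intercept; `NA` (default) means auto-tuned by
#'   bisection so that the realized event fraction matches
#'   `target_event_fraction`.
#' @param weibull_sigma Weibull AFT scale parameter (> 0).
#' @param covariate_betas named log-time coefficients for design columns
#'   (default [default_covariate_betas()]).
#' @param planted_effects named numeric vector: 9-mer core -> AFT log-time
#'   coefficient (negative values shorten graft survival).
#' @param target_event_fraction event fraction the intercept is tuned to.
#' @param random_censor_rate exponential rate of the independent censoring
#'   (death) process, per year.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_pairs = 2000L, seed = 1L,
                          admin_censor_time = 15,
                          weibull_mu = NA_real_, weibull_sigma = 0.9,
                          covariate_betas = default_covariate_betas(),
                          planted_effects = numeric(0),
                          target_event_fraction = 0.17,
                          random_censor_rate = 0.02) {
  stopifnot(n_pairs >= 2, admin_censor_time > 0, weibull_sigma > 0,
            target_event_fraction > 0, target_event_fraction < 1)
  structure(list(n_pairs = as.integer(n_pairs), seed = as.integer(seed),
                 admin_censor_time = admin_censor_time,
                 weibull_mu = weibull_mu, weibull_sigma = weibull_sigma,
                 covariate_betas = covariate_betas,
                 planted_effects = planted_effects,
                 target_event_fraction = target_event_fraction,
                 random_censor_rate = random_censor_rate),
            class = "cohort_config")
}

#' Simulate right-censored Weibull AFT survival times
#'
#' Latent log failure time `log T* = mu + x'beta + sigma * W` with `W`
#' standard minimum-Gumbel; observed time is the minimum of `T*`, the
#' administrative horizon and an independent exponential censoring time,
#' with `event = 1` iff the failure time is smallest.
#'
#' @param design numeric design matrix (rows = pairs).
#' @param betas named coefficients; names must be design column names
#'   (columns without a coefficient get 0).
#' @param mu log-time intercept.
#' @param sigma AFT scale (> 0).
#' @param admin_censor_time administrative horizon (years).
#' @param random_censor_rate exponential censoring rate (0 disables).
#' @param seed integer seed.
#' @return data frame with columns `time` and `event`, plus attribute
#'   `event_fraction`.
#' @export
simulate_survival <- function(design, betas, mu, sigma, admin_censor_time,
                              random_censor_rate = 0, seed = 1L) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  unknown <- setdiff(names(betas), colnames(design))
  if (length(unknown) > 0) {
    stop("coefficient for unknown design column: '", unknown[1L], "'",
         call. = FALSE)
  }
  n <- nrow(design)
  withr::with_seed(seed, {
    lp <- as.numeric(design[, names(betas), drop = FALSE] %*% betas)
    w <- log(rexp(n))  # standard minimum-Gumbel
    t_fail <- exp(mu + lp + sigma * w)
    c_rand <- if (random_censor_rate > 0) {
      rexp(n, rate = random_censor_rate)
    } else rep(Inf, n)
    time <- pmin(t_fail, c_rand, admin_censor_time)
    event <- as.integer(t_fail <= pmin(c_rand, admin_censor_time))
    out <- data.frame(time = time, event = event)
    attr(out, "event_fraction") <- mean(event)
    out
  })
}

# Bisection on mu to match the target event fraction. Uses fixed random
# draws (same seed) so the fraction is monotone nonincreasing in mu.
tune_mu <- function(design, betas, sigma, admin_censor_time,
                    random_censor_rate, target, seed,
                    interval = c(-4, 8), tol = 0.002) {
  frac_at <- function(mu) {
    attr(simulate_survival(design, betas, mu, sigma, admin_censor_time,
                           random_censor_rate, seed), "event_fraction")
  }
  lo <- interval[1L]; hi <- interval[2L]
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    f <- frac_at(mid)
    if (abs(f - target) < tol) return(mid)
    if (f > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Recipient DRB1 indicator columns: one 0/1 column per allele carried by at
# least min_count recipients, reference (most frequent) dropped.
drb1_indicators <- function(pairs, min_count = 1L) {
  alleles <- lapply(pairs, function(p) unique(p$recipient$DRB1))
  all_alleles <- sort(unique(unlist(alleles)))
  counts <- vapply(all_alleles, function(a) {
    sum(vapply(alleles, function(x) a %in% x, logical(1)))
  }, integer(1))
  keep <- all_alleles[counts >= min_count]
  if (length(keep) > 1) keep <- setdiff(keep, keep[which.max(counts[match(keep, all_alleles)])])
  if (length(keep) == 0) {
    return(matrix(numeric(0), nrow = length(pairs), ncol = 0))
  }
  m <- vapply(keep, function(a) {
    vapply(alleles, function(x) as.numeric(a %in% x), numeric(1))
  }, numeric(length(pairs)))
  colnames(m) <- paste0("drb1_", gsub("[*:]", "_", keep))
  m
}

#' Generate a full synthetic cohort
#'
#' End-to-end synthetic data generation: genotypes from the haplotype pool,
#' TcEMM derivation, clinical covariates, and Weibull AFT survival with
#' planted per-core effects. The log-time intercept is tuned by bisection
#' so the realized event fraction matches the configured target.
#'
#' @param registry an `hla_registry`.
#' @param pool a `haplotype_pool`.
#' @param model a `presentation_model`.
#' @param config a [cohort_config()].
#' @param precomputed optional list with `pairs` and `matrix` from an
#'   earlier call under the same registry, pool, model and seed (e.g. a dry
#'   run used to choose plantable cores); skips re-deriving the TcEMM
#'   matrix.
#' @return list with `cohort` (data frame: pair_id, covariates, recipient
#'   DRB1 indicator columns, time, event), `matrix` (a `tcemm_matrix`),
#'   `pairs` (genotypes), and `truth` (list: planted effects, tuned mu,
#'   sigma, covariate betas, realized event fraction).
#' @export
generate_cohort <- function(registry, pool, model, config,
                            precomputed = NULL) {
  seeds <- derive_seeds(config$seed, 4L)
  if (is.null(precomputed)) {
    pairs <- sample_genotypes(pool, config$n_pairs, seeds[1L])
    sets <- derive_tcemm_all(pairs, registry, model)
    mat <- build_tcemm_matrix(sets)
  } else {
    pairs <- precomputed$pairs
    mat <- precomputed$matrix
    stopifnot(length(pairs) == config$n_pairs)
  }

  planted <- config$planted_effects
  if (length(planted) > 0) {
    missing <- setdiff(names(planted), mat$tcemm_ids)
    if (length(missing) > 0) {
      stop("planted cores not realizable from the pool: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  covariates <- generate_covariates(config$n_pairs, seeds[2L])
  X_clin <- covariate_design(covariates)
  X_planted <- if (length(planted) > 0) {
    as.matrix(mat$incidence[, names(planted), drop = FALSE])
  } else {
    matrix(numeric(0), nrow = config$n_pairs, ncol = 0)
  }
  design <- cbind(X_clin, X_planted)
  betas <- c(config$covariate_betas[names(config$covariate_betas) %in%
                                      colnames(X_clin)],
             planted)

  mu <- config$weibull_mu
  if (is.na(mu)) {
    mu <- tune_mu(design, betas, config$weibull_sigma,
                  config$admin_censor_time, config$random_censor_rate,
                  config$target_event_fraction, seeds[3L])
  }
  surv <- simulate_survival(design, betas, mu, config$weibull_sigma,
                            config$admin_censor_time,
                            config$random_censor_rate, seeds[3L])

  drb1 <- drb1_indicators(pairs)
  cohort <- cbind(data.frame(pair_id = mat$pair_ids,
                             stringsAsFactors = FALSE),
                  covariates, as.data.frame(drb1), surv)
  list(cohort = cohort, matrix = mat, pairs = pairs,
       truth = list(planted_effects = planted, mu = mu,
                    sigma = config$weibull_sigma,
                    covariate_betas = betas,
                    event_fraction = attr(surv, "event_fraction")))
}

#' Choose plantable cores from a derived matrix
#'
#' Convenience helper for simulation studies: picks `n` distinct cores with
#' support inside `support_range`, most frequent first.
#'
#' @param matrix a `tcemm_matrix`.
#' @param n number of cores.
#' @param support_range inclusive bounds on pair support.
#' @return character vector of core sequences.
#' @export
choose_planted_cores <- function(matrix, n,
                                 support_range = c(50, Inf)) {
  ok <- matrix$support >= support_range[1L] &
    matrix$support <= support_range[2L]
  cand <- matrix$tcemm_ids[ok][order(-matrix$support[ok])]
  if (length(cand) < n) {
    stop("only ", length(cand), " cores available in support range",
         call. = FALSE)
  }
  cand[seq_len(n)]
}

#' Write pair genotypes to TSV
#'
#' Columns: pair_id, then `donor_<locus>_1/2` and `recipient_<locus>_1/2`
#' for the five loci.
#'
#' @param pairs list of `pair_genotype` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  rows <- lapply(pairs, function(p) {
    vals <- c(p$pair_id,
              unlist(lapply(HLA_LOCI, function(l) p$donor[[l]])),
              unlist(lapply(HLA_LOCI, function(l) p$recipient[[l]])))
    vals
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("pair_id",
                 paste0("donor_", rep(HLA_LOCI, each = 2), "_", 1:2),
                 paste0("recipient_", rep(HLA_LOCI, each = 2), "_", 1:2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pair genotypes from TSV
#'
#' @param path TSV written by [write_pair_table()].
#' @return list of `pair_genotype` objects.
#' @export
read_pair_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    side <- function(prefix) {
      setNames(lapply(HLA_LOCI, function(l) {
        c(df[[paste0(prefix, "_", l, "_1")]][i],
          df[[paste0(prefix, "_", l, "_2")]][i])
      }), HLA_LOCI)
    }
    pair_genotype(df$pair_id[i], side("donor"), side("recipient"))
  })
}
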