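test_that("haplotype pools validate their inputs", {
  reg <- tiny_registry()
  pool <- sample_haplotype_pool(reg, 8, seed = 3)
  expect_s3_class(pool, "haplotype_pool")
  expect_equal(sum(pool$frequencies), 1, tolerance = 1e-12)

  hap <- pool$haplotypes
  expect_error(haplotype_pool(hap, rep(1, nrow(hap))), "sum to 1")
  bad <- hap
  bad$A[1] <- "A*01:99"
  expect_error(haplotype_pool(bad, pool$frequencies, registry = reg),
               "A\\*01:99")
  expect_error(haplotype_pool(hap[0, ], numeric(0)), "empty")
})

test_that("a single-haplotype pool makes every pair genotype-identical", {
  reg <- tiny_registry()
  hap <- sample_haplotype_pool(reg, 5, seed = 3)$haplotypes[1, ]
  pool <- haplotype_pool(hap, 1)
  pairs <- sample_genotypes(pool, 6, seed = 4)
  for (p in pairs) {
    expect_identical(p$donor, p$recipient)
    for (l in names(p$donor)) {
      expect_equal(p$donor[[l]][1], p$donor[[l]][2])  # homozygous
    }
  }
  model <- default_presentation_model(reg, q_bind = 0.5, seed = 2)
  mat <- build_tcemm_matrix(derive_tcemm_all(pairs, reg, model))
  expect_length(mat$tcemm_ids, 0L)
})

test_that("haplotype sampling frequencies match the pool weights", {
  reg <- tiny_registry()
  haps <- sample_haplotype_pool(reg, 5, seed = 3)$haplotypes[1:2, ]
  pool <- haplotype_pool(haps, c(0.9, 0.1))
  pairs <- sample_genotypes(pool, 2500, seed = 9)
  # 10,000 haplotype draws across donors and recipients
  a1 <- haps$A[1]
  n_h1 <- sum(vapply(pairs, function(p) {
    sum(c(p$donor$A, p$recipient$A) == a1)
  }, numeric(1)))
  expect_lt(abs(n_h1 / 10000 - 0.9), 0.01)
  expect_identical(sample_genotypes(pool, 20, seed = 5),
                   sample_genotypes(pool, 20, seed = 5))
})

test_that("covariate generation is complete, bounded and reproducible", {
  cov <- generate_covariates(1000, seed = 21)
  expect_equal(nrow(cov), 1000L)
  expect_false(anyNA(cov))
  expect_true(all(c("recip_age", "recip_sex", "dialysis_years", "insurance",
                    "donor_age", "donor_sex", "donor_type", "era",
                    "induction", "cni_type", "steroid", "cold_ischemia_h",
                    "weight_ratio") %in% names(cov)))
  expect_true(all(cov$recip_age >= 18 & cov$recip_age <= 80))
  expect_identical(cov, generate_covariates(1000, seed = 21))
})

test_that("survival simulation recovers Weibull closed forms", {
  # sigma = 1, no covariates: times are exponential with rate exp(-mu);
  # Kaplan-Meier median close to exp(mu) * ln 2
  n <- 20000
  mu <- log(5)
  X <- matrix(numeric(0), n, 0)
  d <- simulate_survival(X, numeric(0), mu = mu, sigma = 1,
                         admin_censor_time = 1e6, seed = 31)
  km <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  km_med <- unname(summary(km)$table["median"])
  expect_lt(abs(km_med - exp(mu) * log(2)) / (exp(mu) * log(2)), 0.05)

  # planted binary effect: carrier median = e^beta x non-carrier median
  x <- rbinom(n, 1, 0.5)
  X2 <- cbind(core = x)
  beta <- -0.5
  d2 <- simulate_survival(X2, c(core = beta), mu = mu, sigma = 0.8,
                          admin_censor_time = 1e6, seed = 32)
  med <- function(idx) median(d2$time[idx])
  ratio <- med(x == 1) / med(x == 0)
  expect_lt(abs(ratio - exp(beta)) / exp(beta), 0.05)

  # immediate administrative censoring: no events
  d3 <- simulate_survival(X2, c(core = beta), mu = mu, sigma = 0.8,
                          admin_censor_time = 0.001, seed = 33)
  expect_lt(mean(d3$event), 0.005)
  expect_true(all(d3$time <= 0.001))

  expect_error(simulate_survival(X2, c(core = beta), mu, sigma = 0,
                                 admin_censor_time = 1), "sigma")
  expect_error(simulate_survival(X2, c(oops = 1), mu, 1, 1),
               "unknown design column")
})

test_that("generated cohorts hit the target event fraction", {
  reg <- tiny_registry()
  model <- default_presentation_model(reg, q_bind = 0.2, seed = 5)
  pool <- sample_haplotype_pool(reg, 10, seed = 3)
  cfg <- cohort_config(n_pairs = 500, seed = 11)
  gen <- generate_cohort(reg, pool, model, cfg)
  expect_equal(nrow(gen$cohort), 500L)
  expect_length(gen$truth$planted_effects, 0L)
  expect_lt(abs(gen$truth$event_fraction - 0.17), 0.05)
  expect_true(all(gen$cohort$time <= cfg$admin_censor_time))
  expect_true(all(gen$cohort$event[gen$cohort$time ==
                                     cfg$admin_censor_time] == 0))
  expect_false(anyNA(gen$cohort))

  # planted cores must be realizable
  cfg_bad <- cohort_config(n_pairs = 100, seed = 11,
                           planted_effects = c(WWWWWWWWW = -0.5))
  expect_error(generate_cohort(reg, pool, model, cfg_bad),
               "WWWWWWWWW")

  planted <- setNames(rep(-0.5, 3),
                      choose_planted_cores(gen$matrix, 3, c(50, 450)))
  cfg2 <- cohort_config(n_pairs = 500, seed = 11,
                        planted_effects = planted)
  gen2 <- generate_cohort(reg, pool, model, cfg2,
                          precomputed = gen[c("pairs", "matrix")])
  expect_true(all(names(planted) %in% gen2$matrix$tcemm_ids))
  expect_equal(gen2$truth$planted_effects, planted)
})

test_that("haplotype structure induces positive core correlation", {
  # two haplotypes: cores private to haplotype-1 alleles co-occur, so
  # their matrix columns correlate positively
  reg <- tiny_registry(n_alleles = 4L, n_sites = 10L, seed = 41)
  rec <- reg$records
  hap <- data.frame(A = rec$name[rec$locus == "A"][c(1, 2)],
                    B = rec$name[rec$locus == "B"][c(1, 2)],
                    C = rec$name[rec$locus == "C"][c(1, 2)],
                    DRB1 = rec$name[rec$locus == "DRB1"][c(1, 2)],
                    DQB1 = rec$name[rec$locus == "DQB1"][c(1, 2)])
  pool <- haplotype_pool(hap, c(0.5, 0.5))
  model <- default_presentation_model(reg, q_bind = 0.5, seed = 2)
  pairs <- sample_genotypes(pool, 400, seed = 8)
  mat <- build_tcemm_matrix(derive_tcemm_all(pairs, reg, model))
  keep <- mat$support >= 20 & mat$support <= 380
  ids <- mat$tcemm_ids[keep]
  # cores private to haplotype-1 alleles co-occur (and likewise for
  # haplotype 2), so within-haplotype correlations are positive
  seqs1 <- lookup_seq(reg, unlist(hap[1, ]))
  seqs2 <- lookup_seq(reg, unlist(hap[2, ]))
  in_h <- function(core, seqs) any(vapply(seqs, grepl, logical(1),
                                          pattern = core, fixed = TRUE))
  private1 <- ids[vapply(ids, in_h, logical(1), seqs = seqs1) &
                    !vapply(ids, in_h, logical(1), seqs = seqs2)]
  X <- as.matrix(mat$incidence[, private1, drop = FALSE])
  expect_gt(length(private1), 2L)
  cors <- cor(X)
  expect_gt(median(cors[upper.tri(cors)]), 0)
})

test_that("pair genotype tables round-trip through TSV", {
  reg <- tiny_registry()
  pool <- sample_haplotype_pool(reg, 8, seed = 3)
  pairs <- sample_genotypes(pool, 12, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(pairs, path)
  back <- read_pair_table(path)
  expect_equal(length(back), 12L)
  for (i in seq_along(pairs)) {
    expect_identical(back[[i]]$donor, pairs[[i]]$donor)
    expect_identical(back[[i]]$recipient, pairs[[i]]$recipient)
    expect_identical(back[[i]]$pair_id, pairs[[i]]$pair_id)
  }
})
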