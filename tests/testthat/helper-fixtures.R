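# Shared fixtures: tiny registries, crafted genotypes, a brute-force TcEMM
# oracle written independently of the engine (plain nested loops over
# donor 15-mers, their 9-mer core windows and recipient DRB1 alleles), and
# a synthetic binary TcEMM-matrix builder for screening/selection tests.

tiny_registry <- function(n_alleles = 3L, n_sites = 8L, seed = 101L) {
  synthesize_registry(n_alleles, n_sites, seed = seed)
}

# one genotype using allele index i at every locus
uniform_genotype <- function(registry, i = 1L, j = i) {
  rec <- registry$records
  setNames(lapply(c("A", "B", "C", "DRB1", "DQB1"), function(l) {
    alleles <- rec$name[rec$locus == l]
    c(alleles[i], alleles[j])
  }), c("A", "B", "C", "DRB1", "DQB1"))
}

random_pair <- function(registry, pair_id, seed) {
  rec <- registry$records
  withr::with_seed(seed, {
    side <- function() {
      setNames(lapply(c("A", "B", "C", "DRB1", "DQB1"), function(l) {
        sample(rec$name[rec$locus == l], 2L, replace = TRUE)
      }), c("A", "B", "C", "DRB1", "DQB1"))
    }
    pair_genotype(pair_id, side(), side())
  })
}

lookup_seq <- function(registry, name) {
  registry$records$sequence[match(name, registry$records$name)]
}

# Brute-force TcEMM derivation: enumerate every donor 15-mer, each of its
# seven 9-mer windows, and each recipient DRB1 allele, one at a time.
oracle_derive <- function(pair, registry, model) {
  donor_alleles <- unique(unlist(pair$donor, use.names = FALSE))
  recip_alleles <- unique(unlist(pair$recipient, use.names = FALSE))
  drb1 <- unique(pair$recipient$DRB1)

  donor_cores <- character(0)
  for (al in donor_alleles) {
    s <- lookup_seq(registry, al)
    L <- nchar(s)
    if (L >= 15) {
      for (i in 1:(L - 14)) {
        p15 <- substr(s, i, i + 14)
        for (j in 1:7) {
          donor_cores <- c(donor_cores, substr(p15, j, j + 8))
        }
      }
    }
  }
  donor_cores <- unique(donor_cores)

  self <- character(0)
  for (al in recip_alleles) {
    s <- lookup_seq(registry, al)
    L <- nchar(s)
    if (L >= 9) {
      for (i in 1:(L - 8)) self <- c(self, substr(s, i, i + 8))
    }
  }
  self <- unique(self)

  out <- character(0)
  for (core in setdiff(donor_cores, self)) {
    pres <- FALSE
    for (d in drb1) {
      if (model$presented(core, d)) pres <- TRUE
    }
    if (pres) out <- c(out, core)
  }
  sort(out)
}

# Random 9-mers over the amino-acid alphabet
random_cores <- function(n, seed) {
  withr::with_seed(seed, {
    apply(matrix(sample(AMINO_ACIDS, n * 9L, replace = TRUE), ncol = 9L),
          1L, paste, collapse = "")
  })
}

# Build a genuine tcemm_matrix with given column frequencies by sampling
# per-pair core sets; class origin alternates I/II. With n_blocks set,
# columns within a block are noisy copies of a latent indicator (flip
# probability block_noise), mimicking LD-driven co-expression.
synthetic_tcemm_matrix <- function(n_pairs, n_cores, seed,
                                   freq_range = c(0.1, 0.5),
                                   cores = NULL, n_blocks = NULL,
                                   block_noise = 0.05) {
  cores <- cores %||% random_cores(n_cores, seed + 7L)
  withr::with_seed(seed, {
    if (is.null(n_blocks)) {
      freqs <- runif(n_cores, freq_range[1L], freq_range[2L])
      carried <- lapply(seq_len(n_pairs), function(i) {
        cores[runif(n_cores) < freqs]
      })
    } else {
      block_of <- rep_len(seq_len(n_blocks), n_cores)
      bfreq <- runif(n_blocks, freq_range[1L], freq_range[2L])
      latent <- matrix(runif(n_pairs * n_blocks) <
                         rep(bfreq, each = n_pairs), n_pairs, n_blocks)
      flips <- matrix(runif(n_pairs * n_cores) < block_noise,
                      n_pairs, n_cores)
      M <- latent[, block_of] != flips  # xor
      carried <- lapply(seq_len(n_pairs), function(i) cores[M[i, ]])
    }
  })
  block_map <- if (!is.null(n_blocks)) {
    setNames(rep_len(seq_len(n_blocks), n_cores), cores)
  }
  classes <- rep(c("I", "II"), length.out = n_cores)
  sets <- lapply(seq_len(n_pairs), function(i) {
    cs <- carried[[i]]
    structure(list(pair_id = sprintf("P%05d", i), cores = cs,
                   presentations = setNames(as.list(rep("DRB1*01:01",
                                                        length(cs))), cs),
                   class_origin = setNames(as.list(
                     classes[match(cs, cores)]), cs),
                   pirche_score = length(cs)),
              class = "tcemm_set")
  })
  out <- build_tcemm_matrix(sets)
  attr(out, "block_of") <- block_map
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal cohort around an existing tcemm_matrix: covariates + survival
# with optional planted log-time effects on named cores.
synthetic_cohort_for <- function(mat, seed, planted = numeric(0),
                                 sigma = 0.9, target = 0.17) {
  n <- length(mat$pair_ids)
  covariates <- generate_covariates(n, seed + 1L)
  X_clin <- tcemm:::covariate_design(covariates)
  X_pl <- if (length(planted) > 0) {
    as.matrix(mat$incidence[, names(planted), drop = FALSE])
  } else matrix(numeric(0), n, 0)
  design <- cbind(X_clin, X_pl)
  betas <- c(default_covariate_betas()[
    names(default_covariate_betas()) %in% colnames(X_clin)], planted)
  mu <- tcemm:::tune_mu(design, betas, sigma, 15, 0.02, target, seed + 2L)
  surv <- simulate_survival(design, betas, mu, sigma, 15, 0.02, seed + 2L)
  cbind(data.frame(pair_id = mat$pair_ids, stringsAsFactors = FALSE),
        covariates, surv)
}

# Construct a controlled registry edit: one allele's sequence changes at
# one interior position between version v1 and v2, and only a known set of
# pairs carries that allele.
make_version_fixture <- function(n_carriers = 3, n_pairs = 30, seed = 201) {
  reg1 <- synthesize_registry(3, 10, seed = seed, version_tag = "v1")
  rec <- reg1$records
  target <- rec$name[rec$locus == "B"][3L]
  pos <- 60L
  cur <- substr(rec$sequence[match(target, rec$name)], pos, pos)
  reg2 <- edit_registry_allele(reg1, target, pos,
                               setdiff(AMINO_ACIDS, cur)[1L], "v2")
  # carriers get the target allele on the donor side; all other pairs and
  # all recipients avoid it
  other_b <- rec$name[rec$locus == "B"][1L]
  base <- function(pid, donor_b) {
    gt <- uniform_genotype(reg1, 1L, 2L)
    donor <- gt
    donor$B <- c(donor_b, other_b)
    recip <- uniform_genotype(reg1, 2L, 2L)
    recip$B <- c(other_b, other_b)
    pair_genotype(pid, donor, recip)
  }
  pairs <- lapply(seq_len(n_pairs), function(i) {
    base(sprintf("P%03d", i),
         if (i <= n_carriers) target else other_b)
  })
  list(pairs = pairs, reg1 = reg1, reg2 = reg2, target = target)
}
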