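test_that("15-mer enumeration matches a direct window oracle", {
  s15 <- paste(rep("A", 15), collapse = "")
  expect_equal(enumerate_15mers(s15), s15)

  s20 <- random_cores(1, 5)
  s20 <- paste0(s20, substr(s20, 1, 2))  # length 20, as two windows would
  s20 <- paste0(random_cores(1, 6), "ACDEFGHIKLM")  # length 20
  expect_length(enumerate_15mers(s20), 6L)

  s16 <- "ACDEFGHIKLMNPQRS"
  expect_equal(enumerate_15mers(s16),
               c("ACDEFGHIKLMNPQR", "CDEFGHIKLMNPQRS"))

  # independent slicing oracle on a random protein
  s <- paste(random_cores(20, 9), collapse = "")
  oracle <- vapply(1:(nchar(s) - 14), function(i) substr(s, i, i + 14),
                   character(1))
  expect_equal(enumerate_15mers(s), oracle)

  expect_warning(out <- enumerate_15mers("ACDEFGHIK"), "shorter")
  expect_length(out, 0L)
})

test_that("9-mer core enumeration gives the seven windows", {
  expect_equal(enumerate_cores(paste(rep("A", 15), collapse = "")),
               rep(paste(rep("A", 9), collapse = ""), 7L))
  p <- "ACDEFGHIKLMNPQR"
  cores <- enumerate_cores(p)
  expect_length(cores, 7L)
  oracle <- vapply(1:7, function(j) substr(p, j, j + 8), character(1))
  expect_equal(cores, oracle)
  expect_error(enumerate_cores("ACDEFGHIK"), "15-mer")
})

test_that("self repertoire is the union of recipient 9-mer windows", {
  reg <- tiny_registry()
  recip <- uniform_genotype(reg, 1L)
  rep1 <- self_repertoire(recip, reg)

  # window oracle over the five distinct proteins
  oracle <- unique(unlist(lapply(unique(unlist(recip)), function(al) {
    s <- lookup_seq(reg, al)
    vapply(1:(nchar(s) - 8), function(i) substr(s, i, i + 8), character(1))
  })))
  expect_setequal(rep1, oracle)

  # two alleles differing at one site contribute both variant cores
  recip2 <- uniform_genotype(reg, 1L, 2L)
  rep2 <- self_repertoire(recip2, reg)
  expect_true(all(rep1 %in% rep2))

  # a residue absent from every recipient protein cannot appear
  letters_used <- unique(unlist(strsplit(
    lookup_seq(reg, unique(unlist(recip))), "")))
  expect_true(all(unlist(strsplit(rep1, "")) %in% letters_used))

  bad <- recip
  bad$A[1] <- "A*01:99"
  expect_error(self_repertoire(bad, reg), "A\\*01:99")
})

test_that("presentation model is deterministic and calibrated", {
  reg <- tiny_registry()
  drb1 <- reg$records$name[reg$records$locus == "DRB1"]
  m1 <- default_presentation_model(reg, q_bind = 0.2, seed = 5)
  m2 <- default_presentation_model(reg, q_bind = 0.2, seed = 5)
  probe <- random_cores(200, 31)
  expect_identical(m1$presented(probe, drb1[1]),
                   m2$presented(probe, drb1[1]))

  # calibration: fresh random cores presented at about q_bind
  fresh <- random_cores(10000, 77)
  frac <- mean(m1$presented(fresh, drb1[1]))
  expect_lt(abs(frac - 0.2), 0.01)

  # different alleles get different weight matrices
  expect_false(identical(m1$weights(drb1[1]), m1$weights(drb1[2])))

  expect_error(m1$presented(probe[1], "A*01:01"), "not a DRB1")
})

test_that("identical donor and recipient genotypes yield no mismatches", {
  reg <- tiny_registry()
  model <- default_presentation_model(reg, q_bind = 0.5, seed = 2)
  gt <- uniform_genotype(reg, 2L)
  pair <- pair_genotype("p1", gt, gt)
  set <- derive_tcemm(pair, reg, model)
  expect_length(set$cores, 0L)
  expect_equal(set$pirche_score, 0L)
})

test_that("a single substitution yields at most nine localized mismatches", {
  # donor differs from recipient by one residue in one protein; with a
  # permissive binding model the TcEMM set is confined to donor cores
  # overlapping the substituted site
  reg <- tiny_registry(n_alleles = 1L, n_sites = 0L, seed = 55)
  rec <- reg$records
  target <- rec$name[rec$locus == "A"][1L]
  pos <- 50L
  cur <- substr(rec$sequence[match(target, rec$name)], pos, pos)
  reg2 <- edit_registry_allele(reg, target, pos,
                               setdiff(AMINO_ACIDS, cur)[1L], "don")
  # one registry holding both variants under different names
  don_name <- "A*01:02"
  reg_both <- reg
  new_rec <- reg2$records[match(target, reg2$records$name), ]
  new_rec$name <- don_name
  reg_both$records <- rbind(reg_both$records, new_rec)

  gt_r <- uniform_genotype(reg, 1L)
  gt_d <- gt_r
  gt_d$A <- c(don_name, don_name)
  pair <- pair_genotype("p1", gt_d, gt_r)
  model <- default_presentation_model(reg_both, q_bind = 0.99, seed = 9)
  set <- derive_tcemm(pair, reg_both, model)
  expect_lte(length(set$cores), 9L)
  expect_gt(length(set$cores), 0L)
  # every mismatch core overlaps the substituted position
  don_seq <- reg_both$records$sequence[
    match(don_name, reg_both$records$name)]
  overlap <- vapply(max(1, pos - 8):pos, function(i) {
    substr(don_seq, i, i + 8)
  }, character(1))
  expect_true(all(set$cores %in% overlap))
  expect_equal(set$class_origin[[set$cores[1]]], "I")
})

test_that("very strict binding removes essentially all mismatches", {
  reg <- tiny_registry()
  pair <- random_pair(reg, "p1", 12)
  strict <- derive_tcemm(pair, reg,
                         default_presentation_model(reg, q_bind = 1e-5,
                                                    seed = 2))
  loose <- derive_tcemm(pair, reg,
                        default_presentation_model(reg, q_bind = 0.5,
                                                   seed = 2))
  # threshold sits at the top of the calibration pool: at most a stray
  # core can clear it
  expect_lte(length(strict$cores), ceiling(0.01 * length(loose$cores)))
  expect_gt(length(loose$cores), 0L)
})

test_that("derivation matches the brute-force oracle on random pairs", {
  reg <- tiny_registry(n_alleles = 3L, n_sites = 10L, seed = 23)
  model <- default_presentation_model(reg, q_bind = 0.3, seed = 4)
  cache <- NULL
  for (k in 1:10) {
    pair <- random_pair(reg, paste0("p", k), 100 + k)
    set <- derive_tcemm(pair, reg, model)
    expect_equal(sort(set$cores), oracle_derive(pair, reg, model))
    expect_equal(set$pirche_score, length(set$cores))
    # every reported core has at least one presenter among recipient DRB1
    drb1 <- unique(pair$recipient$DRB1)
    for (core in set$cores) {
      expect_true(all(set$presentations[[core]] %in% drb1))
      expect_gte(length(set$presentations[[core]]), 1L)
    }
  }
})

test_that("raising q_bind never removes a mismatch core", {
  reg <- tiny_registry()
  pairs <- lapply(1:5, function(k) random_pair(reg, paste0("p", k), 40 + k))
  qs <- c(0.05, 0.2, 0.5, 0.9)
  sets <- lapply(qs, function(q) {
    model <- default_presentation_model(reg, q_bind = q, seed = 6)
    derive_tcemm_all(pairs, reg, model)
  })
  for (i in seq_along(pairs)) {
    for (j in 1:(length(qs) - 1)) {
      expect_true(all(sets[[j]][[i]]$cores %in% sets[[j + 1]][[i]]$cores))
    }
  }
})

test_that("swapping donor and recipient changes the mismatch set", {
  reg <- tiny_registry()
  model <- default_presentation_model(reg, q_bind = 0.5, seed = 2)
  pair <- random_pair(reg, "p", 71)
  fwd <- derive_tcemm(pair, reg, model)
  rev <- derive_tcemm(pair_genotype("p", pair$recipient, pair$donor),
                      reg, model)
  expect_false(setequal(fwd$cores, rev$cores))
})

test_that("the TcEMM matrix reflects per-pair sets exactly", {
  reg <- tiny_registry()
  model <- default_presentation_model(reg, q_bind = 0.3, seed = 4)
  pairs <- lapply(1:8, function(k) random_pair(reg, paste0("p", k), 60 + k))
  sets <- derive_tcemm_all(pairs, reg, model)
  mat <- build_tcemm_matrix(sets)

  expect_equal(mat$tcemm_ids,
               sort(unique(unlist(lapply(sets, `[[`, "cores")))))
  # column sums equal recomputed per-core pair counts
  recount <- vapply(mat$tcemm_ids, function(core) {
    sum(vapply(sets, function(s) core %in% s$cores, logical(1)))
  }, numeric(1))
  expect_equal(unname(mat$support), unname(recount))
  expect_equal(unname(mat$frequency), unname(recount) / 8)
  # total score equals number of nonzero entries
  expect_equal(sum(mat$scores), sum(mat$incidence != 0))
  # per-cell agreement
  for (k in c(1, 5)) {
    expect_setequal(mat$tcemm_ids[mat$incidence[k, ] != 0], sets[[k]]$cores)
  }
  expect_error(build_tcemm_matrix(sets[c(1, 1)]), "duplicate pair_id")
})

test_that("disjoint singleton sets give an identity-pattern matrix", {
  cores <- random_cores(2, 3)
  sets <- lapply(1:2, function(i) {
    structure(list(pair_id = paste0("p", i), cores = cores[i],
                   presentations = setNames(list("DRB1*01:01"), cores[i]),
                   class_origin = setNames(list("I"), cores[i]),
                   pirche_score = 1L), class = "tcemm_set")
  })
  mat <- build_tcemm_matrix(sets)
  dense <- as.matrix(mat$incidence)
  expect_equal(sort(colnames(dense)), sort(cores))
  expect_equal(unname(rowSums(dense)), c(1, 1))
  expect_equal(unname(colSums(dense)), c(1, 1))

  # a core present in every pair has frequency 1
  both <- lapply(sets, function(s) {
    s$cores <- c(s$cores, cores[1]); s$cores <- unique(s$cores)
    s$pirche_score <- length(s$cores)
    s
  })
  m2 <- build_tcemm_matrix(both)
  expect_equal(unname(m2$frequency[cores[1]]), 1)
})
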