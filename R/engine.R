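# TcEMM derivation engine: 15-mer / 9-mer-core enumeration, recipient
# self-repertoire, deterministic DRB1 presentation model, per-pair TcEMM
# sets and the population-level binary TcEMM matrix.
#
# A TcEMM is a 9-amino-acid core from a donor HLA protein that (i) is absent
# from the recipient's own HLA-derived core repertoire and (ii) is predicted
# to be presented by at least one recipient HLA-DRB1 allele. The per-pair
# PIRCHE-II-style score is, by default, the number of such distinct cores.

#' Enumerate 15-mer peptides of a protein
#'
#' Returns every contiguous 15-residue window of `sequence`, left to right.
#' Proteolytic processing of donor HLA proteins is modelled as exhaustive
#' 15-mer enumeration, the peptide length class II grooves typically
#' accommodate.
#'
#' @param sequence amino-acid string (an allele's protein sequence).
#' @return character vector of `L - 14` 15-mers (empty, with a warning, if
#'   `L < 15`).
#' @export
enumerate_15mers <- function(sequence) {
  if (nchar(sequence) < 15L) {
    warning("sequence shorter than 15 residues yields no 15-mers")
    return(character(0))
  }
  sliding_windows(sequence, 15L)
}

#' Enumerate the 9-mer cores of a 15-mer
#'
#' The 7 contiguous 9-residue windows of a 15-mer: the possible binding
#' cores the class II groove can register within that peptide.
#'
#' @param peptide15 a 15-residue string.
#' @return character vector of 7 9-mers.
#' @export
enumerate_cores <- function(peptide15) {
  if (nchar(peptide15) != 15L) {
    stop("expected a 15-mer, got length ", nchar(peptide15), call. = FALSE)
  }
  sliding_windows(peptide15, 9L)
}

# All distinct 9-mer windows of one protein. The union of the 9-mer cores of
# all 15-mers of a protein equals the set of all 9-mer windows of the
# protein, so windows are enumerated directly.
protein_cores <- function(sequence) unique(sliding_windows(sequence, 9L))

# Memoised per-allele core sets for a registry; keyed on allele name.
registry_core_cache <- function(registry) {
  cache <- new.env(parent = emptyenv())
  rec <- registry$records
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    i <- match(name, rec$name)
    if (is.na(i)) {
      stop("allele '", name, "' not found in registry version ",
           registry$version_tag, call. = FALSE)
    }
    cache[[name]] <- protein_cores(rec$sequence[i])
    cache[[name]]
  }
}

#' Pair genotype constructor
#'
#' @param pair_id unique pair identifier.
#' @param donor,recipient named lists mapping each locus (`A`, `B`, `C`,
#'   `DRB1`, `DQB1`) to a length-2 character vector of allele names
#'   (homozygotes repeat the allele).
#' @return A `pair_genotype` object.
#' @export
pair_genotype <- function(pair_id, donor, recipient) {
  for (side in list(donor, recipient)) {
    missing <- setdiff(HLA_LOCI, names(side))
    if (length(missing) > 0) {
      stop("genotype missing locus ", missing[1L], call. = FALSE)
    }
    if (any(vapply(side, length, integer(1)) != 2L)) {
      stop("each locus needs exactly two alleles", call. = FALSE)
    }
  }
  structure(list(pair_id = pair_id, donor = donor[HLA_LOCI],
                 recipient = recipient[HLA_LOCI]),
            class = "pair_genotype")
}

genotype_alleles <- function(side) unique(unlist(side, use.names = FALSE))

#' Recipient self core repertoire
#'
#' The union of all 9-mer windows of all recipient HLA proteins at the five
#' loci. By default no binding filter is applied: presence of a core
#' anywhere in the recipient's own HLA peptidome excludes the matching donor
#' core from being a mismatch.
#'
#' @param recipient named list locus -> length-2 allele-name vector.
#' @param registry an `hla_registry`.
#' @return character vector of distinct 9-mers.
#' @export
self_repertoire <- function(recipient, registry) {
  seqs <- registry_sequences(registry, genotype_alleles(recipient))
  unique(unlist(lapply(seqs, protein_cores), use.names = FALSE))
}

#' Deterministic DRB1 presentation model
#'
#' A pluggable stand-in for a trained MHC class II binding predictor. Every
#' DRB1 allele receives a 9 x 20 position-weight matrix drawn reproducibly
#' from a hash of the allele name and `seed`; a core's score is the sum of
#' the per-position weights of its residues. The presentation threshold per
#' allele is the empirical `(1 - q_bind)` quantile of scores over a shared
#' pool of 100,000 seeded random cores, so that a fraction `q_bind` of
#' random peptide cores is called presented.
#'
#' Weights are keyed by allele *name* plus seed, not by sequence, so the
#' same model object scores alleles consistently across registry versions
#' (as an external predictor's per-allele models would persist across
#' database releases).
#'
#' @param registry an `hla_registry` (DRB1 thresholds are precomputed for
#'   its DRB1 alleles; other DRB1 names are scored lazily).
#' @param q_bind target fraction of random cores called presented
#'   (0 < q_bind < 1).
#' @param seed integer seed for weights and the calibration pool.
#' @param n_calibration size of the random-core calibration pool.
#' @return A `presentation_model` object with functions `score(cores,
#'   presenter)` and `threshold(presenter)`; `presented(cores, presenter)`
#'   returns a logical vector.
#' @export
default_presentation_model <- function(registry, q_bind = 0.2, seed = 1L,
                                       n_calibration = 100000L) {
  stopifnot(q_bind > 0, q_bind < 1)
  calib <- withr::with_seed(seed, {
    matrix(sample.int(20L, n_calibration * 9L, replace = TRUE),
           ncol = 9L)
  })
  cache <- new.env(parent = emptyenv())
  allele_model <- function(presenter) {
    if (!is.null(cache[[presenter]])) return(cache[[presenter]])
    parsed <- parse_allele_name(presenter)
    if (parsed$locus != "DRB1") {
      stop("presenter '", presenter, "' is not a DRB1 allele", call. = FALSE)
    }
    w <- withr::with_seed(hash_string_seed(presenter, seed), {
      matrix(rnorm(9L * 20L), nrow = 9L, ncol = 20L)
    })
    scores <- score_index_matrix(calib, w)
    thr <- unname(quantile(scores, probs = 1 - q_bind, type = 7))
    cache[[presenter]] <- list(weights = w, threshold = thr)
    cache[[presenter]]
  }
  model <- structure(
    list(q_bind = q_bind, seed = seed,
         score = function(cores, presenter) {
           m <- allele_model(presenter)
           score_index_matrix(peptides_to_indices(cores, 9L), m$weights)
         },
         threshold = function(presenter) allele_model(presenter)$threshold,
         weights = function(presenter) allele_model(presenter)$weights,
         presented = function(cores, presenter) {
           m <- allele_model(presenter)
           score_index_matrix(peptides_to_indices(cores, 9L),
                              m$weights) >= m$threshold
         }),
    class = "presentation_model")
  # warm the cache for the registry's DRB1 alleles
  for (a in registry$records$name[registry$records$locus == "DRB1"]) {
    allele_model(a)
  }
  model
}

# Score an n x 9 index matrix against a 9 x 20 weight matrix
score_index_matrix <- function(idx, w) {
  if (nrow(idx) == 0L) return(numeric(0))
  acc <- numeric(nrow(idx))
  for (p in 1:9) acc <- acc + w[p, idx[, p]]
  acc
}

#' Derive the TcEMM set of one donor:recipient pair
#'
#' A core `c` is a TcEMM of the pair iff (i) `c` is a 9-mer core of some
#' 15-mer of some donor HLA protein (both haplotypes, all five loci),
#' (ii) `c` is absent from the recipient's self core repertoire, and
#' (iii) at least one recipient DRB1 allele presents `c` under `model`.
#'
#' @param pair a `pair_genotype`.
#' @param registry an `hla_registry`.
#' @param model a `presentation_model`.
#' @param self_repertoire_binding_filtered if `TRUE`, the self repertoire is
#'   restricted to self cores presented by recipient DRB1 before the
#'   subtraction (default `FALSE`: the self exclusion is a pure sequence-set
#'   condition).
#' @param core_cache optional memoised core lookup from
#'   `registry_core_cache(registry)`, reused across pairs for speed.
#' @return A `tcemm_set`: list with `pair_id`, `cores` (character),
#'   `presentations` (named list core -> presenting DRB1 alleles),
#'   `class_origin` (named list core -> subset of `c("I", "II")` giving the
#'   HLA class of the donor source loci) and `pirche_score` (number of
#'   distinct cores).
#' @export
derive_tcemm <- function(pair, registry, model,
                         self_repertoire_binding_filtered = FALSE,
                         core_cache = NULL) {
  get_cores <- core_cache %||% registry_core_cache(registry)
  locus_of <- registry_locus(registry,
                             unique(c(genotype_alleles(pair$donor),
                                      genotype_alleles(pair$recipient))))

  donor_alleles <- genotype_alleles(pair$donor)
  donor_core_list <- lapply(donor_alleles, get_cores)
  donor_cores <- unique(unlist(donor_core_list, use.names = FALSE))

  self <- unique(unlist(lapply(genotype_alleles(pair$recipient), get_cores),
                        use.names = FALSE))
  drb1 <- unique(unlist(pair$recipient$DRB1, use.names = FALSE))
  if (self_repertoire_binding_filtered && length(self) > 0) {
    pres_any <- Reduce(`|`, lapply(drb1, function(d) {
      model$presented(self, d)
    }))
    self <- self[pres_any]
  }

  candidates <- setdiff(donor_cores, self)
  presentations <- list()
  if (length(candidates) > 0) {
    pres_by <- lapply(drb1, function(d) model$presented(candidates, d))
    keep <- Reduce(`|`, pres_by)
    kept <- candidates[keep]
    presentations <- lapply(seq_along(kept), function(i) {
      j <- match(kept[i], candidates)
      drb1[vapply(pres_by, `[`, logical(1), j)]
    })
    names(presentations) <- kept
    candidates <- kept
  } else {
    candidates <- character(0)
  }

  class_origin <- list()
  if (length(candidates) > 0) {
    origin_class <- lapply(candidates, function(cr) {
      from <- donor_alleles[vapply(donor_core_list, function(cs) {
        cr %in% cs
      }, logical(1))]
      sort(unique(ifelse(locus_of[from] %in% CLASS1_LOCI, "I", "II")))
    })
    names(origin_class) <- candidates
    class_origin <- origin_class
  }

  structure(list(pair_id = pair$pair_id,
                 cores = candidates,
                 presentations = presentations,
                 class_origin = class_origin,
                 pirche_score = length(candidates)),
            class = "tcemm_set")
}

#' Derive TcEMM sets for many pairs
#'
#' Batch version of [derive_tcemm()] sharing one per-allele core cache.
#'
#' @inheritParams derive_tcemm
#' @param pairs list of `pair_genotype` objects.
#' @return list of `tcemm_set` objects.
#' @export
derive_tcemm_all <- function(pairs, registry, model,
                             self_repertoire_binding_filtered = FALSE) {
  cache <- registry_core_cache(registry)
  lapply(pairs, derive_tcemm, registry = registry, model = model,
         self_repertoire_binding_filtered = self_repertoire_binding_filtered,
         core_cache = cache)
}

#' PIRCHE-II-style mismatch score of a TcEMM set
#'
#' Default mode counts distinct presented non-self cores; mode
#' `"core_presenter"` counts (core, presenting DRB1 allele) combinations.
#'
#' @param set a `tcemm_set`.
#' @param mode `"core"` (default) or `"core_presenter"`.
#' @return nonnegative integer score.
#' @export
pirche_score <- function(set, mode = c("core", "core_presenter")) {
  mode <- match.arg(mode)
  if (mode == "core") return(length(set$cores))
  sum(vapply(set$presentations, length, integer(1)))
}

#' Build the population TcEMM matrix
#'
#' Assembles per-pair TcEMM sets into a sparse binary pairs-by-cores matrix
#' (the TcEMM expression matrix). Population-level TcEMM identity is the
#' 9-mer core string alone; a core's class origin is the union of origins
#' across pairs.
#'
#' @param tcemm_sets list of `tcemm_set` objects with unique `pair_id`s.
#' @return A `tcemm_matrix`: list with `incidence` (sparse logical Matrix,
#'   rows = pairs, columns = sorted distinct cores), `pair_ids`,
#'   `tcemm_ids`, `scores` (per-pair default score), `class_origin`
#'   (character vector per core: `"I"`, `"II"` or `"I+II"`), `support`
#'   (per-core pair count) and `frequency` (support / n pairs).
#' @export
build_tcemm_matrix <- function(tcemm_sets) {
  pair_ids <- vapply(tcemm_sets, `[[`, character(1), "pair_id")
  if (anyDuplicated(pair_ids)) {
    stop("duplicate pair_id: '", pair_ids[duplicated(pair_ids)][1L], "'",
         call. = FALSE)
  }
  all_cores <- sort(unique(unlist(lapply(tcemm_sets, `[[`, "cores"),
                                  use.names = FALSE)))
  n_per <- vapply(tcemm_sets, function(s) length(s$cores), integer(1))
  i <- rep(seq_along(tcemm_sets), n_per)
  j <- match(unlist(lapply(tcemm_sets, `[[`, "cores"), use.names = FALSE),
             all_cores)
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(pair_ids), length(all_cores)),
                              dimnames = list(pair_ids, all_cores))
  origin <- rep(NA_character_, length(all_cores))
  names(origin) <- all_cores
  olist <- setNames(vector("list", length(all_cores)), all_cores)
  for (s in tcemm_sets) {
    for (cr in s$cores) {
      olist[[cr]] <- union(olist[[cr]], s$class_origin[[cr]])
    }
  }
  origin <- vapply(olist, function(o) {
    paste(sort(o), collapse = "+")
  }, character(1))
  support <- Matrix::colSums(inc)
  structure(list(incidence = inc,
                 pair_ids = pair_ids,
                 tcemm_ids = all_cores,
                 scores = setNames(vapply(tcemm_sets, pirche_score,
                                          numeric(1)), pair_ids),
                 class_origin = origin,
                 support = support,
                 frequency = support / length(pair_ids)),
            class = "tcemm_matrix")
}

#' @export
print.tcemm_matrix <- function(x, ...) {
  cat("TcEMM matrix: ", length(x$pair_ids), " pairs x ",
      length(x$tcemm_ids), " distinct cores; median score ",
      median(x$scores), "\n", sep = "")
  invisible(x)
}

#' Write a TcEMM matrix as sparse triplets
#'
#' @param matrix a `tcemm_matrix`.
#' @param path output TSV path (columns pair_id, core, present).
#' @return `path`, invisibly.
#' @export
write_tcemm_matrix <- function(matrix, path) {
  trip <- Matrix::summary(methods::as(matrix$incidence, "TsparseMatrix"))
  out <- data.frame(pair_id = matrix$pair_ids[trip$i],
                    core = matrix$tcemm_ids[trip$j],
                    present = 1L)
  out <- out[order(out$pair_id, out$core), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
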