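# Registry version sensitivity: how TcEMM calls change when allele protein
# sequences are updated between two registry releases.

#' Compare TcEMM derivations under two registry versions
#'
#' Runs the TcEMM derivation for every pair under both registries (with the
#' same presentation model, whose per-allele weights are keyed by allele
#' name and seed so they persist across versions) and reports
#' population-level and per-pair differences.
#'
#' @param pairs list of `pair_genotype` objects.
#' @param registry_v1,registry_v2 two `hla_registry` objects resolving
#'   every allele used by `pairs`.
#' @param model a `presentation_model`.
#' @param self_repertoire_binding_filtered passed to [derive_tcemm()].
#' @return A `version_diff` list: `n_tcemm_only_v1`, `n_tcemm_only_v2`,
#'   `n_tcemm_population_diff` (their sum), `n_pairs_affected`,
#'   `fraction_pairs_affected`, `only_v1`, `only_v2` (core sets) and
#'   `pair_changes` (data frame: pair_id, n_gained, n_lost for affected
#'   pairs).
#' @export
diff_versions <- function(pairs, registry_v1, registry_v2, model,
                          self_repertoire_binding_filtered = FALSE) {
  used <- unique(unlist(lapply(pairs, function(p) {
    c(genotype_alleles(p$donor), genotype_alleles(p$recipient))
  }), use.names = FALSE))
  for (reg in list(registry_v1, registry_v2)) registry_sequences(reg, used)

  sets1 <- derive_tcemm_all(pairs, registry_v1, model,
                            self_repertoire_binding_filtered)
  sets2 <- derive_tcemm_all(pairs, registry_v2, model,
                            self_repertoire_binding_filtered)
  pop1 <- unique(unlist(lapply(sets1, `[[`, "cores"), use.names = FALSE))
  pop2 <- unique(unlist(lapply(sets2, `[[`, "cores"), use.names = FALSE))
  only1 <- setdiff(pop1, pop2)
  only2 <- setdiff(pop2, pop1)

  changes <- lapply(seq_along(pairs), function(i) {
    lost <- setdiff(sets1[[i]]$cores, sets2[[i]]$cores)
    gained <- setdiff(sets2[[i]]$cores, sets1[[i]]$cores)
    if (length(lost) == 0 && length(gained) == 0) return(NULL)
    data.frame(pair_id = pairs[[i]]$pair_id,
               n_lost = length(lost), n_gained = length(gained),
               stringsAsFactors = FALSE)
  })
  changes <- do.call(rbind, changes[!vapply(changes, is.null, logical(1))])
  if (is.null(changes)) {
    changes <- data.frame(pair_id = character(0), n_lost = integer(0),
                          n_gained = integer(0))
  }
  structure(list(version_v1 = registry_v1$version_tag,
                 version_v2 = registry_v2$version_tag,
                 n_tcemm_only_v1 = length(only1),
                 n_tcemm_only_v2 = length(only2),
                 n_tcemm_population_diff = length(only1) + length(only2),
                 n_pairs_affected = nrow(changes),
                 fraction_pairs_affected = nrow(changes) / length(pairs),
                 only_v1 = only1, only_v2 = only2,
                 pair_changes = changes),
            class = "version_diff")
}

#' @export
print.version_diff <- function(x, ...) {
  cat("Registry version diff ", x$version_v1, " -> ", x$version_v2, ":\n",
      "  population TcEMM symmetric difference: ",
      x$n_tcemm_population_diff, " (", x$n_tcemm_only_v1, " only in v1, ",
      x$n_tcemm_only_v2, " only in v2)\n",
      "  pairs affected: ", x$n_pairs_affected, " (",
      sprintf("%.2f%%", 100 * x$fraction_pairs_affected), ")\n", sep = "")
  invisible(x)
}
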