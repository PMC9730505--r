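# HLA allele registries: parsing of allele names, FASTA loading with
# validation, synthetic registry generation, and summaries.

HLA_LOCI <- c("A", "B", "C", "DRB1", "DQB1")
CLASS1_LOCI <- c("A", "B", "C")
CLASS2_LOCI <- c("DRB1", "DQB1")

#' Parse HLA allele names
#'
#' Parses two-field allele names of the form `"LOCUS*gg:pp"` (e.g.
#' `"DRB1*04:01"`) at the five supported loci A, B, C, DRB1 and DQB1.
#' Higher-field names and expression suffixes are rejected: the analysis
#' works at two-field (allele group : protein) resolution.
#'
#' @param text character vector of allele names.
#' @return A data frame with columns `locus`, `field1`, `field2` and `name`
#'   (the canonical re-formatted text form).
#' @examples
#' parse_allele_name(c("A*01:01", "DRB1*04:01"))
#' @seealso [format_allele_name()]
#' @export
parse_allele_name <- function(text) {
  if (length(text) == 0L || any(!nzchar(text))) {
    stop("allele name must be a non-empty string", call. = FALSE)
  }
  parts <- strsplit(text, "*", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed allele name (expected one '*'): '", text[bad][1L], "'",
         call. = FALSE)
  }
  locus <- vapply(parts, `[`, character(1), 1L)
  rest <- vapply(parts, `[`, character(1), 2L)
  if (any(!locus %in% HLA_LOCI)) {
    stop("unsupported locus '", locus[!locus %in% HLA_LOCI][1L],
         "' (supported: ", paste(HLA_LOCI, collapse = ", "), ")",
         call. = FALSE)
  }
  ok <- grepl("^[0-9]{2}:[0-9]{2}$", rest)
  if (any(!ok)) {
    stop("malformed allele fields (expected two two-digit fields): '",
         rest[!ok][1L], "'", call. = FALSE)
  }
  field1 <- substr(rest, 1L, 2L)
  field2 <- substr(rest, 4L, 5L)
  data.frame(locus = locus, field1 = field1, field2 = field2,
             name = paste0(locus, "*", field1, ":", field2),
             stringsAsFactors = FALSE)
}

#' Format parsed allele names
#'
#' Inverse of [parse_allele_name()]: renders `locus`, `field1`, `field2`
#' back to the canonical `"LOCUS*gg:pp"` text form.
#'
#' @param parsed data frame as returned by [parse_allele_name()].
#' @return character vector of canonical allele names.
#' @export
format_allele_name <- function(parsed) {
  paste0(parsed$locus, "*", parsed$field1, ":", parsed$field2)
}

new_registry <- function(version_tag, names, sequences) {
  parsed <- parse_allele_name(names)
  structure(
    list(version_tag = version_tag,
         records = data.frame(name = parsed$name, locus = parsed$locus,
                              sequence = sequences,
                              length = nchar(sequences),
                              stringsAsFactors = FALSE)),
    class = "hla_registry")
}

#' Load an HLA allele registry from FASTA
#'
#' Reads a protein FASTA file whose headers carry allele names (the first
#' whitespace-delimited token of each header, e.g. `>A*01:01 description`)
#' and validates every record: names must parse, be unique, and sequences
#' must use the 20 standard one-letter codes and be at least 15 residues
#' long (shorter proteins cannot yield a single 15-mer).
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param version_tag free-text version label for the registry (e.g.
#'   `"3.46"`), recorded for version-sensitivity analyses.
#' @return An `hla_registry` object.
#' @export
load_registry <- function(path, version_tag) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr) || !is_hdr[1L]) {
    stop("not a FASTA file (no '>' header found): ", path, call. = FALSE)
  }
  rec_id <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  names <- vapply(strsplit(headers, "[[:space:]]+"), `[`, character(1), 1L)
  seqs <- vapply(split(lines[!is_hdr], rec_id[!is_hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  if (length(seqs) != length(names)) {
    stop("FASTA record without sequence in ", path, call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("duplicate allele name in FASTA: '",
         names[duplicated(names)][1L], "'", call. = FALSE)
  }
  valid <- is_valid_protein(seqs)
  if (any(!valid)) {
    stop("sequence for '", names[!valid][1L],
         "' contains non-amino-acid characters", call. = FALSE)
  }
  short <- nchar(seqs) < 15L
  if (any(short)) {
    stop("sequence for '", names[short][1L],
         "' is shorter than 15 residues and cannot yield any 15-mer",
         call. = FALSE)
  }
  new_registry(version_tag, names, unname(seqs))
}

#' Write a registry to FASTA
#'
#' @param registry an `hla_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  rec <- registry$records
  writeLines(paste0(">", rec$name, "\n", rec$sequence), path)
  invisible(path)
}

#' Generate a synthetic HLA allele registry
#'
#' For each of the five loci, draws one random base protein (length uniform
#' in `base_length_range`) and a fixed set of polymorphic sites; each allele
#' is the base protein with substitutions at a random subset of those sites.
#' Alleles at one locus therefore differ only at the designated polymorphic
#' sites, mimicking how HLA polymorphism concentrates in a limited set of
#' residue positions. Fully deterministic given `seed`.
#'
#' @param n_alleles_per_locus number of alleles per locus (1--99).
#' @param n_polymorphic_sites number of polymorphic residue positions per
#'   locus.
#' @param seed integer seed.
#' @param version_tag version label (default `"synth-1"`).
#' @param base_length_range integer range for base protein lengths.
#' @return An `hla_registry` with `5 * n_alleles_per_locus` records named
#'   `LOCUS*01:01 ... LOCUS*01:nn`.
#' @export
synthesize_registry <- function(n_alleles_per_locus, n_polymorphic_sites,
                                seed, version_tag = "synth-1",
                                base_length_range = c(180L, 270L)) {
  stopifnot(n_alleles_per_locus >= 1, n_alleles_per_locus <= 99,
            n_polymorphic_sites >= 0)
  withr::with_seed(seed, {
    names <- character(0)
    seqs <- character(0)
    for (locus in HLA_LOCI) {
      L <- sample(base_length_range[1L]:base_length_range[2L], 1L)
      base <- sample(AMINO_ACIDS, L, replace = TRUE)
      sites <- if (n_polymorphic_sites > 0) {
        sample.int(L, min(n_polymorphic_sites, L))
      } else integer(0)
      for (i in seq_len(n_alleles_per_locus)) {
        allele <- base
        if (length(sites) > 0) {
          k <- sample(0:length(sites), 1L)
          sub_at <- if (k > 0) sample(sites, k) else integer(0)
          for (s in sub_at) {
            allele[s] <- sample(setdiff(AMINO_ACIDS, base[s]), 1L)
          }
        }
        names <- c(names, sprintf("%s*01:%02d", locus, i))
        seqs <- c(seqs, paste(allele, collapse = ""))
      }
    }
    new_registry(version_tag, names, seqs)
  })
}

#' Summarize a registry
#'
#' @param registry an `hla_registry`.
#' @return list with `version_tag`, `n_records` and per-locus counts,
#'   suitable for JSON serialization.
#' @export
registry_summary <- function(registry) {
  counts <- table(factor(registry$records$locus, levels = HLA_LOCI))
  list(version_tag = registry$version_tag,
       n_records = nrow(registry$records),
       per_locus = as.list(setNames(as.integer(counts), names(counts))))
}

#' @export
print.hla_registry <- function(x, ...) {
  s <- registry_summary(x)
  cat("HLA allele registry (version ", s$version_tag, "): ",
      s$n_records, " alleles\n", sep = "")
  cat("  per locus:",
      paste(names(s$per_locus), unlist(s$per_locus), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# Look up sequences for a character vector of allele names, with a clear
# error naming the first unresolvable allele.
registry_sequences <- function(registry, names) {
  idx <- match(names, registry$records$name)
  if (anyNA(idx)) {
    stop("allele '", names[is.na(idx)][1L],
         "' not found in registry version ", registry$version_tag,
         call. = FALSE)
  }
  setNames(registry$records$sequence[idx], names)
}

registry_locus <- function(registry, names) {
  idx <- match(names, registry$records$name)
  setNames(registry$records$locus[idx], names)
}

# Mutate one allele's sequence; used to construct controlled version edits.
#' Create a new registry version with an edited allele sequence
#'
#' Returns a copy of `registry` with `allele`'s residue at `position`
#' replaced by `new_residue`, under a new version tag. Used to construct
#' controlled registry-version differences for sensitivity analysis.
#'
#' @param registry an `hla_registry`.
#' @param allele allele name to edit.
#' @param position 1-based residue position.
#' @param new_residue replacement amino acid (one-letter code).
#' @param version_tag version label for the edited registry.
#' @return A new `hla_registry`.
#' @export
edit_registry_allele <- function(registry, allele, position, new_residue,
                                 version_tag) {
  stopifnot(new_residue %in% AMINO_ACIDS)
  rec <- registry$records
  i <- match(allele, rec$name)
  if (is.na(i)) stop("allele '", allele, "' not in registry", call. = FALSE)
  if (position < 1 || position > rec$length[i]) {
    stop("position out of range for ", allele, call. = FALSE)
  }
  substr(rec$sequence[i], position, position) <- new_residue
  out <- registry
  out$records <- rec
  out$version_tag <- version_tag
  out
}
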