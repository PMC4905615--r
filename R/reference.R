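# Germline reference: IMGT-gapped IGHV alleles organised as
# alleles -> genes -> subgroups (1-7) -> clans (I, II, III).

#' Map IGHV subgroup to clan
#'
#' Human IGHV subgroups fall into three clans: subgroups 1, 5 and 7 form
#' clan I; subgroups 2, 4 and 6 form clan II; subgroup 3 is clan III.
#'
#' @param subgroup Integer vector with values in 1..7.
#' @return Character vector of clan labels (`"I"`, `"II"`, `"III"`).
#' @examples
#' clan_of(1:7)
#' @export
clan_of <- function(subgroup) {
  subgroup <- as.integer(subgroup)
  if (any(is.na(subgroup)) || any(subgroup < 1L | subgroup > 7L)) {
    abort("subgroup must be an integer in 1..7")
  }
  map <- c("I", "II", "III", "II", "I", "II", "I")
  map[subgroup]
}

#' Extract the gene name from an IGHV allele name
#'
#' @param allele Character vector of allele names, e.g. `"IGHV4-34*01"`.
#' @return The gene part before the `*`, e.g. `"IGHV4-34"`.
#' @export
gene_of_allele <- function(allele) {
  sub("\\*.*$", "", allele)
}

# Subgroup digit parsed from an allele or gene name ("IGHV4-34" -> 4).
subgroup_of_name <- function(name) {
  m <- regmatches(name, regexpr("^IGHV([1-7])", name))
  out <- rep(NA_integer_, length(name))
  ok <- nchar(m) > 0
  out[ok] <- as.integer(substr(m[ok], 5, 5))
  out
}

# Translate an IMGT-gapped nucleotide string codon-wise: '...' -> '.',
# a full-base codon -> its amino acid ('*' for stop), anything partial
# or ambiguous -> 'X'.
translate_gapped <- function(nt_gapped) {
  ch <- seq_chars(nt_gapped)
  n_codon <- length(ch) %/% 3L
  if (n_codon == 0L) return("")
  code <- Biostrings::GENETIC_CODE
  aa <- vapply(seq_len(n_codon), function(i) {
    cod <- ch[(3L * i - 2L):(3L * i)]
    if (all(cod == ".")) return(".")
    if (all(cod %in% DNA_BASES)) return(unname(code[paste(cod, collapse = "")]))
    "X"
  }, character(1))
  paste(aa, collapse = "")
}

validate_reference_tbl <- function(alleles) {
  required <- c("allele", "gene", "subgroup", "functionality",
                "orphon", "partial_5prime", "nt_gapped")
  missing <- setdiff(required, names(alleles))
  if (length(missing) > 0) {
    abort(paste0("reference metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(alleles$allele)) {
    dup <- unique(alleles$allele[duplicated(alleles$allele)])
    abort(paste0("duplicate allele name(s) in reference: ",
                 paste(dup, collapse = ", ")))
  }
  bad_fun <- setdiff(unique(alleles$functionality), c("F", "P", "ORF"))
  if (length(bad_fun) > 0) {
    abort(paste0("functionality must be F, P or ORF; found: ",
                 paste(bad_fun, collapse = ", ")))
  }
  seqs <- toupper(alleles$nt_gapped)
  ok_chars <- !grepl("[^ACGT.]", seqs)
  if (!all(ok_chars)) {
    abort(paste0("allele sequence contains characters outside {A,C,G,T,.}: ",
                 paste(alleles$allele[!ok_chars], collapse = ", ")))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    abort("all reference alleles must share one gapped frame length")
  }
  parsed_sg <- subgroup_of_name(alleles$allele)
  if (any(is.na(parsed_sg))) {
    abort(paste0("allele name does not parse as IGHV<subgroup>...: ",
                 paste(alleles$allele[is.na(parsed_sg)], collapse = ", ")))
  }
  if (any(parsed_sg != alleles$subgroup)) {
    bad <- alleles$allele[parsed_sg != alleles$subgroup]
    abort(paste0("subgroup in metadata disagrees with allele name for: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(alleles)
}

#' Construct a germline reference from a tibble of alleles
#'
#' Validates allele naming, sequence alphabet (`A`, `C`, `G`, `T`, `.`;
#' IUPAC ambiguity codes are rejected), a common gapped frame length,
#' and the subgroup encoded in each allele name; computes the clan from
#' the subgroup and the gapped amino-acid translation from the
#' nucleotide sequence.
#'
#' @param alleles Data frame with columns `allele`, `gene`, `subgroup`,
#'   `functionality` (`"F"`, `"P"` or `"ORF"`), `orphon`,
#'   `partial_5prime`, `nt_gapped`.
#' @param version_label Free-text label recording the reference release.
#' @return An `ighv_reference`: a tibble (one row per allele, with
#'   computed `clan` and `aa_gapped` columns) carrying `frame_length`
#'   and `version_label` attributes.
#' @export
ighv_reference <- function(alleles, version_label = "unversioned") {
  alleles <- as_tibble(alleles)
  validate_reference_tbl(alleles)
  out <- alleles %>%
    mutate(
      subgroup = as.integer(.data$subgroup),
      orphon = as.logical(.data$orphon),
      partial_5prime = as.logical(.data$partial_5prime),
      nt_gapped = unname(toupper(.data$nt_gapped)),
      clan = clan_of(.data$subgroup),
      aa_gapped = map_chr(.data$nt_gapped, translate_gapped)
    ) %>%
    select("allele", "gene", "subgroup", "clan", "functionality",
           "orphon", "partial_5prime", "nt_gapped", "aa_gapped") %>%
    arrange(.data$allele)
  attr(out, "frame_length") <- nchar(out$nt_gapped[1])
  attr(out, "version_label") <- version_label
  class(out) <- c("ighv_reference", class(tibble()))
  out
}

frame_length <- function(ref) attr(ref, "frame_length")

#' Read a germline reference from FASTA plus metadata
#'
#' The FASTA carries IMGT-gapped nucleotide sequences (`.` gaps); the
#' TSV metadata table carries one row per allele with columns `allele`,
#' `gene`, `subgroup`, `functionality`, `orphon`, `partial_5prime`.
#' Clan is always computed from the subgroup, never read.
#'
#' @param fasta_path Path to the gapped FASTA file.
#' @param metadata_path Path to the TSV metadata file.
#' @param version_label Optional label for this reference release.
#' @return An [ighv_reference()] tibble.
#' @export
read_ighv_reference <- function(fasta_path, metadata_path,
                                version_label = "unversioned") {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate allele name(s) in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(ids, meta$allele)
  if (length(missing) > 0) {
    abort(paste0("allele(s) in FASTA have no metadata row: ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(meta$allele, ids)
  if (length(extra) > 0) {
    abort(paste0("metadata row(s) without FASTA sequence: ",
                 paste(extra, collapse = ", ")))
  }
  tbl <- meta %>%
    mutate(nt_gapped = as.character(seqs)[match(.data$allele, ids)])
  ighv_reference(tbl, version_label = version_label)
}

#' Write a germline reference back to FASTA plus metadata
#'
#' Emits the same FASTA + TSV pair that [read_ighv_reference()]
#' consumes, so a filtered reference can be re-exported.
#'
#' @param ref An [ighv_reference()].
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ighv_reference <- function(ref, fasta_path, metadata_path) {
  set <- Biostrings::BStringSet(setNames(ref$nt_gapped, ref$allele))
  Biostrings::writeXStringSet(set, fasta_path)
  ref %>%
    select("allele", "gene", "subgroup", "functionality",
           "orphon", "partial_5prime") %>%
    readr::write_tsv(metadata_path)
  invisible(c(fasta = fasta_path, metadata = metadata_path))
}

#' Filter a germline reference
#'
#' Drops orphon alleles and/or alleles whose 5' end is partial, the two
#' exclusions applied to the reference before any shared-mutation
#' analysis. Genes left with no alleles disappear from the reference.
#'
#' @param ref An [ighv_reference()].
#' @param drop_orphons Drop alleles flagged as orphons.
#' @param drop_partial_5prime Drop alleles flagged 5'-partial.
#' @return A filtered `ighv_reference`; the input is unchanged.
#' @export
filter_reference <- function(ref, drop_orphons = TRUE,
                             drop_partial_5prime = TRUE) {
  keep <- rep(TRUE, nrow(ref))
  if (drop_orphons) keep <- keep & !ref$orphon
  if (drop_partial_5prime) keep <- keep & !ref$partial_5prime
  out <- ref[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    inform("filter_reference: no alleles remain after filtering")
  }
  attr(out, "frame_length") <- attr(ref, "frame_length")
  attr(out, "version_label") <- attr(ref, "version_label")
  class(out) <- class(ref)
  out
}

# Character matrix of the reference: one row per allele, one column per
# gapped position.
reference_matrix <- function(ref) {
  m <- matrix(unlist(strsplit(ref$nt_gapped, "", fixed = TRUE)),
              nrow = nrow(ref), byrow = TRUE)
  rownames(m) <- ref$allele
  m
}

#' Conserved positions of a gene
#'
#' Gapped positions at which every allele of the gene carries the same
#' nucleotide (a base, not a gap). For a single-allele gene this is all
#' of its non-gap positions.
#'
#' @param ref An [ighv_reference()].
#' @param gene A gene name present in `ref`.
#' @return Sorted integer vector of 1-based gapped positions.
#' @export
conserved_positions <- function(ref, gene) {
  rows <- which(ref$gene == gene)
  if (length(rows) == 0) {
    abort(paste0("unknown gene: ", gene))
  }
  m <- reference_matrix(ref[rows, , drop = FALSE])
  same <- colSums(m != m[rep(1L, nrow(m)), , drop = FALSE]) == 0
  which(same & m[1, ] %in% DNA_BASES)
}
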