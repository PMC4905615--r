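# SH scan: classify every mutation of every patient sequence as shared
# (SH) with one or more other germline alleles, or non-SH (the
# introduced base occurs in no germline at that position).

#' Is a mutation shared with a given germline?
#'
#' A mutation is shared (SH) with a germline when the nucleotide
#' introduced by SHM is present in that germline at the exact same
#' gapped position. A gap in the germline at that position cannot
#' share.
#'
#' @param to_base Introduced base(s).
#' @param towg_nt_gapped Gapped sequence of the candidate towards
#'   germline.
#' @param nt_pos 1-based gapped position(s).
#' @return Logical vector.
#' @export
is_shared <- function(to_base, towg_nt_gapped, nt_pos) {
  ch <- seq_chars(towg_nt_gapped)
  ch[nt_pos] == to_base & ch[nt_pos] %in% DNA_BASES
}

#' Percent identity between two gapped sequences
#'
#' Computed over the positions where both sequences carry a base;
#' gaps and `N` count in neither numerator nor denominator.
#'
#' @param a,b Gapped sequence strings of equal length.
#' @return Percentage in `[0, 100]` (`NA` if no position is compared).
#' @export
pairwise_identity <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  if (length(ca) != length(cb)) {
    abort("pairwise_identity: sequences differ in length")
  }
  both <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(both)) return(NA_real_)
  100 * sum(ca[both] == cb[both]) / sum(both)
}

# Count of positions where both sequences carry a base and the bases
# differ, optionally restricted to a position subset. This is the
# per-allele "initial movement capability" (maxSH) ingredient.
dissimilarity_count <- function(a, b, positions = NULL) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  idx <- if (is.null(positions)) seq_along(ca) else positions
  ca <- ca[idx]
  cb <- cb[idx]
  sum(ca %in% DNA_BASES & cb %in% DNA_BASES & ca != cb)
}

#' Scan all sequences against all germlines for shared mutations
#'
#' The core of the analysis: every mutation of every patient sequence
#' (sAm) is compared with every germline allele other than the
#' assigned one (sBm). Each (mutation, allele) pair where the allele
#' carries the introduced base at that position yields one SH record;
#' a mutation shared with no allele is non-SH. With
#' `conserved_only = TRUE` only mutations at conserved positions of
#' the sBm gene (see [conserved_positions()]) are considered.
#'
#' @param rearr Filtered rearrangement tibble.
#' @param ref Filtered [ighv_reference()].
#' @param conserved_only Restrict to the conserved area of the sBm
#'   gene.
#' @param region_restriction Optional IMGT region name.
#' @return An object of class `sh_scan`: a list with tibbles
#'   `sh` (`sequence_id`, `nt_pos`, `from_base`, `to_base`,
#'   `codon_number`, `region`, `towg_allele`), `nonsh` (same minus
#'   `towg_allele`), `mutations` (all considered mutations), and
#'   `sequences` (the voter roster with per-sequence mutation count
#'   `m_i`), plus the scan settings.
#' @export
sh_scan <- function(rearr, ref, conserved_only = FALSE,
                    region_restriction = NULL) {
  if (anyDuplicated(rearr$sequence_id)) {
    abort(paste0("sh_scan: duplicate sequence_id(s); give each sequence ",
                 "a distinct identifier so every row is its own voter"))
  }
  muts <- call_mutations(rearr, ref, region_restriction)
  if (conserved_only && nrow(muts) > 0) {
    genes <- unique(gene_of_allele(rearr$v_call))
    cons <- setNames(map(genes, ~ conserved_positions(ref, .x)), genes)
    gene_per_mut <- gene_of_allele(
      rearr$v_call[match(muts$sequence_id, rearr$sequence_id)])
    keep <- map_lgl(seq_len(nrow(muts)),
                    ~ muts$nt_pos[.x] %in% cons[[gene_per_mut[.x]]])
    muts <- muts[keep, , drop = FALSE]
  }
  roster <- tibble(
    sequence_id = rearr$sequence_id,
    sbm_allele = rearr$v_call,
    subset = rearr$subset,
    gi_pct = rearr$v_identity,
    m_i = as.integer(
      table(factor(muts$sequence_id,
                   levels = rearr$sequence_id))[rearr$sequence_id])
  )
  empty_sh <- tibble(sequence_id = character(), nt_pos = integer(),
                     from_base = character(), to_base = character(),
                     codon_number = integer(), region = character(),
                     towg_allele = character())
  if (nrow(muts) == 0) {
    out <- list(sh = empty_sh, nonsh = muts, mutations = muts,
                sequences = roster, conserved_only = conserved_only,
                region_restriction = region_restriction)
    class(out) <- "sh_scan"
    return(out)
  }
  m <- reference_matrix(ref)
  sbm_idx <- match(rearr$v_call[match(muts$sequence_id,
                                      rearr$sequence_id)],
                   rownames(m))
  # alleles x mutations matrix: does allele carry to_base at nt_pos?
  bases_at <- m[, muts$nt_pos, drop = FALSE]
  share <- bases_at == matrix(muts$to_base, nrow = nrow(m),
                              ncol = nrow(muts), byrow = TRUE)
  share[cbind(sbm_idx, seq_len(nrow(muts)))] <- FALSE
  hits <- which(share, arr.ind = TRUE)
  sh <- muts[hits[, "col"], , drop = FALSE] %>%
    mutate(towg_allele = rownames(m)[hits[, "row"]]) %>%
    arrange(.data$sequence_id, .data$nt_pos, .data$towg_allele)
  nonsh <- muts[colSums(share) == 0, , drop = FALSE]
  out <- list(sh = if (nrow(sh) == 0) empty_sh else sh,
              nonsh = nonsh, mutations = muts, sequences = roster,
              conserved_only = conserved_only,
              region_restriction = region_restriction)
  class(out) <- "sh_scan"
  out
}

#' @export
print.sh_scan <- function(x, ...) {
  cat("<sh_scan>\n")
  cat("  sequences:", nrow(x$sequences), "\n")
  cat("  mutations:", nrow(x$mutations),
      if (x$conserved_only) "(conserved area only)" else "", "\n")
  cat("  SH records:", nrow(x$sh), " non-SH mutations:",
      nrow(x$nonsh), "\n")
  invisible(x)
}

# Five property columns with a step suffix, from an amino-acid vector.
props_with_suffix <- function(aa, suffix) {
  p <- aa_property_row(aa)
  setNames(p, paste0(names(p), "_", suffix))
}

#' Build the SH Position Dataset (SHPD)
#'
#' One row per (mutation, towards germline) SH record, with 34
#' columns: identifiers and context (patient, subset, sBm, germline
#' identity, TowG and its functionality, SH count for the
#' sequence/TowG pair, the mutation token and its position, codon and
#' region), the mutation-level flags (hotspot, transition,
#' replacement), the three amino acids at the mutated codon (sBm, sAm,
#' TowG), and the five IMGT amino-acid properties for each of the
#' three steps.
#'
#' @param scan An [sh_scan()] result.
#' @param rearr The rearrangement tibble the scan was run on.
#' @param ref The [ighv_reference()] used.
#' @param motifs Hotspot motifs for annotation.
#' @return Tibble with the 34-column SHPD schema.
#' @export
build_shpd <- function(scan, rearr, ref, motifs = shm_hotspot_motifs()) {
  ann <- annotate_mutations(scan$mutations, rearr, ref, motifs)
  sh <- scan$sh %>%
    inner_join(ann, by = c("sequence_id", "nt_pos", "from_base",
                           "to_base", "codon_number", "region")) %>%
    group_by(.data$sequence_id, .data$towg_allele) %>%
    mutate(sh_count = dplyr::n()) %>%
    ungroup()
  roster <- scan$sequences
  ridx <- match(sh$sequence_id, roster$sequence_id)
  towg_idx <- match(sh$towg_allele, ref$allele)
  towg_aa <- map2_chr_safe(sh$towg_allele, sh$codon_number, ref)
  out <- tibble(
    patient_id = sh$sequence_id,
    subset = roster$subset[ridx],
    sbm_allele = roster$sbm_allele[ridx],
    gi_pct = roster$gi_pct[ridx],
    towg_allele = sh$towg_allele,
    towg_functionality = ref$functionality[towg_idx],
    sh_count = sh$sh_count,
    mutation = paste0(tolower(sh$from_base), sh$nt_pos,
                      tolower(sh$to_base)),
    from_base = sh$from_base,
    to_base = sh$to_base,
    nt_pos = sh$nt_pos,
    codon_number = sh$codon_number,
    region = sh$region,
    in_hotspot = sh$in_hotspot,
    is_transition = sh$is_transition,
    is_replacement = sh$is_replacement,
    sbm_aa = sh$sbm_aa,
    sam_aa = sh$sam_aa,
    towg_aa = towg_aa
  )
  bind_cols(out,
            props_with_suffix(out$sbm_aa, "sbm"),
            props_with_suffix(out$sam_aa, "sam"),
            props_with_suffix(out$towg_aa, "towg"))
}

# TowG amino acid at a codon, from the allele's own gapped translation.
map2_chr_safe <- function(towg_allele, codon_number, ref) {
  aa_seqs <- ref$aa_gapped[match(towg_allele, ref$allele)]
  vapply(seq_along(towg_allele), function(i) {
    aa <- substr(aa_seqs[i], codon_number[i], codon_number[i])
    if (aa %in% c("", ".", "X")) NA_character_ else aa
  }, character(1))
}

#' Build the non-SH Position Dataset (nonSHPD)
#'
#' One row per non-SH mutation with the same identifier, flag and
#' amino-acid property columns as the SHPD minus everything
#' TowG-specific, plus `new_property_functionality`: the set of
#' functionality classes (F/P/ORF) of reference germlines whose amino
#' acid at that codon falls in the same chemical class as the new
#' (sAm) amino acid. This column is an interpretation of "where the
#' new property can be found" and is documented as such.
#'
#' @inheritParams build_shpd
#' @return Tibble with the nonSHPD schema.
#' @export
build_nonshpd <- function(scan, rearr, ref,
                          motifs = shm_hotspot_motifs()) {
  ann <- annotate_mutations(scan$mutations, rearr, ref, motifs)
  ns <- scan$nonsh %>%
    inner_join(ann, by = c("sequence_id", "nt_pos", "from_base",
                           "to_base", "codon_number", "region"))
  roster <- scan$sequences
  ridx <- match(ns$sequence_id, roster$sequence_id)
  props <- imgt_aa_properties()
  new_fun <- vapply(seq_len(nrow(ns)), function(i) {
    aa <- ns$sam_aa[i]
    if (is.na(aa)) return(NA_character_)
    cls <- props$chemical[match(aa, props$aa)]
    if (is.na(cls)) return(NA_character_)
    codon_aa <- substr(ref$aa_gapped, ns$codon_number[i],
                       ns$codon_number[i])
    same <- !is.na(match(codon_aa, props$aa)) &
      props$chemical[match(codon_aa, props$aa)] == cls
    found <- lex_sort(unique(ref$functionality[which(same)]))
    if (length(found) == 0) "" else paste(found, collapse = ",")
  }, character(1))
  out <- tibble(
    patient_id = ns$sequence_id,
    subset = roster$subset[ridx],
    sbm_allele = roster$sbm_allele[ridx],
    gi_pct = roster$gi_pct[ridx],
    mutation = paste0(tolower(ns$from_base), ns$nt_pos,
                      tolower(ns$to_base)),
    from_base = ns$from_base,
    to_base = ns$to_base,
    nt_pos = ns$nt_pos,
    codon_number = ns$codon_number,
    region = ns$region,
    in_hotspot = ns$in_hotspot,
    is_transition = ns$is_transition,
    is_replacement = ns$is_replacement,
    sbm_aa = ns$sbm_aa,
    sam_aa = ns$sam_aa,
    new_property_functionality = new_fun
  )
  bind_cols(out,
            props_with_suffix(out$sbm_aa, "sbm"),
            props_with_suffix(out$sam_aa, "sam"))
}

#' Build the Germlines-with-SH Dataset (GSHD)
#'
#' One row per (patient sequence, towards germline) pair: the sBm, the
#' sAm identifier, the identity of sBm and sAm, the TowG, the identity
#' of TowG and sBm, and the number of SH mutations shared with that
#' TowG, alongside the patient ID and subset. This is the table the
#' towards analysis votes are drawn from.
#'
#' @inheritParams build_shpd
#' @return Tibble with 8 columns: `patient_id`, `subset`,
#'   `sbm_allele`, `sam_id`, `identity_sbm_sam`, `towg_allele`,
#'   `identity_towg_sbm`, `sh_count`.
#' @export
build_gshd <- function(scan, rearr, ref) {
  roster <- scan$sequences
  pairs <- scan$sh %>%
    count(.data$sequence_id, .data$towg_allele, name = "sh_count")
  if (nrow(pairs) == 0) {
    return(tibble(patient_id = character(), subset = character(),
                  sbm_allele = character(), sam_id = character(),
                  identity_sbm_sam = double(), towg_allele = character(),
                  identity_towg_sbm = double(), sh_count = integer()))
  }
  ridx <- match(pairs$sequence_id, roster$sequence_id)
  rearr_idx <- match(pairs$sequence_id, rearr$sequence_id)
  sbm_seq <- ref$nt_gapped[match(roster$sbm_allele[ridx], ref$allele)]
  towg_seq <- ref$nt_gapped[match(pairs$towg_allele, ref$allele)]
  tibble(
    patient_id = pairs$sequence_id,
    subset = roster$subset[ridx],
    sbm_allele = roster$sbm_allele[ridx],
    sam_id = pairs$sequence_id,
    identity_sbm_sam = map_dbl(
      seq_len(nrow(pairs)),
      ~ pairwise_identity(sbm_seq[.x],
                          rearr$sequence_alignment[rearr_idx[.x]])),
    towg_allele = pairs$towg_allele,
    identity_towg_sbm = map_dbl(
      seq_len(nrow(pairs)),
      ~ pairwise_identity(towg_seq[.x], sbm_seq[.x])),
    sh_count = as.integer(pairs$sh_count)
  ) %>%
    arrange(.data$patient_id, .data$towg_allele)
}
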