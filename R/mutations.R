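# Mutation calling and annotation: nucleotide substitutions between a
# patient sequence (sAm) and its assigned germline (sBm), with
# hotspot / transition / replacement flags and IMGT amino-acid
# property classes for the codons involved.

#' IMGT amino-acid property classes
#'
#' One row per amino acid (plus the stop symbol `*`) with the five
#' property classifications used to describe mutated codons:
#' hydropathy (hydrophobic / neutral / hydrophilic), volume (five
#' classes from very_small to very_large), chemical class (aliphatic,
#' aromatic, sulfur, hydroxyl, basic, acidic, amide), physicochemical
#' polarity (polar / nonpolar), and charge (positive / negative /
#' uncharged). Stop codons carry chemical class `"stop"` and
#' `"undetermined"` for every other property.
#'
#' @return Tibble with columns `aa`, `hydropathy`, `volume`,
#'   `chemical`, `physicochemical`, `charge`.
#' @export
imgt_aa_properties <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  in_set <- function(set) ifelse(aa %in% set, TRUE, FALSE)
  hydropathy <- case_when(
    aa %in% c("A", "C", "I", "L", "M", "F", "W", "V") ~ "hydrophobic",
    aa %in% c("G", "H", "P", "S", "T", "Y") ~ "neutral",
    TRUE ~ "hydrophilic"
  )
  volume <- case_when(
    aa %in% c("A", "G", "S") ~ "very_small",
    aa %in% c("C", "D", "N", "P", "T") ~ "small",
    aa %in% c("E", "H", "Q", "V") ~ "medium",
    aa %in% c("I", "K", "L", "M", "R") ~ "large",
    TRUE ~ "very_large"
  )
  chemical <- case_when(
    aa %in% c("A", "G", "I", "L", "P", "V") ~ "aliphatic",
    aa %in% c("F", "W", "Y") ~ "aromatic",
    aa %in% c("C", "M") ~ "sulfur",
    aa %in% c("S", "T") ~ "hydroxyl",
    aa %in% c("R", "H", "K") ~ "basic",
    aa %in% c("D", "E") ~ "acidic",
    TRUE ~ "amide"
  )
  physicochemical <- case_when(
    aa %in% c("R", "N", "D", "C", "Q", "E", "H", "K", "S", "T", "Y") ~ "polar",
    TRUE ~ "nonpolar"
  )
  charge <- case_when(
    aa %in% c("R", "H", "K") ~ "positive",
    aa %in% c("D", "E") ~ "negative",
    TRUE ~ "uncharged"
  )
  bind_rows(
    tibble(aa, hydropathy, volume, chemical, physicochemical, charge),
    tibble(aa = "*", hydropathy = "undetermined", volume = "undetermined",
           chemical = "stop", physicochemical = "undetermined",
           charge = "undetermined")
  )
}

# Total lookup: any symbol outside the table (X, '.', NA) maps to
# "undetermined" across all five properties.
aa_property_row <- function(aa) {
  props <- imgt_aa_properties()
  if (length(aa) == 0) return(props[integer(0), -1])
  idx <- match(aa, props$aa)
  out <- props[ifelse(is.na(idx), 1L, idx), -1]
  und <- is.na(idx)
  if (any(und)) out[und, ] <- "undetermined"
  out
}

#' Default SHM hotspot motifs
#'
#' The canonical AID / polymerase-eta somatic hypermutation hotspot
#' motifs RGYW, WRCY, WA and TW, written with IUPAC wildcards
#' (R = A/G, Y = C/T, W = A/T).
#'
#' @return Character vector of motifs.
#' @export
shm_hotspot_motifs <- function() c("RGYW", "WRCY", "WA", "TW")

iupac_to_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", W = "[AT]", S = "[CG]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[seq_chars(toupper(motif))], collapse = "")
}

# Logical vector over the gapped frame: TRUE where the position falls
# inside a hotspot motif occurrence. Motifs are matched on the
# ungapped germline sequence (gaps are alignment bookkeeping, not
# chemistry) and match windows are mapped back to gapped coordinates.
hotspot_flags <- function(nt_gapped, motifs = shm_hotspot_motifs()) {
  ch <- seq_chars(nt_gapped)
  flags <- rep(FALSE, length(ch))
  idx <- which(ch %in% DNA_BASES)
  if (length(idx) == 0) return(flags)
  ungapped <- paste(ch[idx], collapse = "")
  for (motif in motifs) {
    m <- nchar(motif)
    # lookahead so overlapping occurrences are all found
    hits <- stringr::str_locate_all(
      ungapped, paste0("(?=", iupac_to_regex(motif), ")"))[[1]]
    for (s in hits[, 1]) flags[idx[s:(s + m - 1)]] <- TRUE
  }
  flags
}

# Codon string (3 characters) at codon number k of a gapped sequence.
codon_at <- function(ch, codon_number) {
  lo <- 3L * codon_number - 2L
  if (lo + 2L > length(ch)) return(NA_character_)
  paste(ch[lo:(lo + 2L)], collapse = "")
}

translate_codon <- function(codon) {
  if (is.na(codon)) return(NA_character_)
  ch <- seq_chars(codon)
  if (!all(ch %in% DNA_BASES)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Call nucleotide mutations against the assigned germline
#'
#' Compares each patient sequence with its assigned germline allele
#' (sBm) position by position over the shared gapped frame and emits
#' one mutation per position where both carry a base and the bases
#' differ. Positions where either side has a gap (`.`) or an ambiguity
#' (`N`) are skipped; insertions and deletions are out of scope. The
#' per-sequence mutation count is the M used by the towards scoring.
#'
#' @param rearr Rearrangement tibble.
#' @param ref An [ighv_reference()]; every `v_call` must resolve.
#' @param region_restriction Optional region name restricting calls to
#'   that IMGT span.
#' @return Tibble with one row per mutation: `sequence_id`, `nt_pos`,
#'   `from_base`, `to_base`, `codon_number`, `region`.
#' @export
call_mutations <- function(rearr, ref, region_restriction = NULL) {
  L <- frame_length(ref)
  span <- region_span(region_restriction)
  per_row <- function(i) {
    row <- rearr[i, ]
    sbm_row <- match(row$v_call, ref$allele)
    if (is.na(sbm_row)) {
      abort(paste0("v_call not in reference: ", row$v_call,
                   " (sequence ", row$sequence_id, ")"))
    }
    sam <- seq_chars(row$sequence_alignment)
    if (length(sam) != L) {
      abort(paste0("sequence_alignment length ", length(sam),
                   " differs from reference frame ", L,
                   " for ", row$sequence_id))
    }
    sbm <- seq_chars(ref$nt_gapped[sbm_row])
    diff <- which(sbm %in% DNA_BASES & sam %in% DNA_BASES & sbm != sam)
    if (!is.null(span)) diff <- diff[diff >= span[1] & diff <= span[2]]
    tibble(
      sequence_id = row$sequence_id,
      nt_pos = as.integer(diff),
      from_base = sbm[diff],
      to_base = sam[diff]
    )
  }
  out <- list_rbind(map(seq_len(nrow(rearr)), per_row))
  if (nrow(out) == 0) {
    out <- tibble(sequence_id = character(), nt_pos = integer(),
                  from_base = character(), to_base = character())
  }
  mutate(out,
         codon_number = codon_of(.data$nt_pos),
         region = region_of(.data$nt_pos))
}

#' Cross-check supplied mutation lists against the sequences
#'
#' When a rearrangement table carries a pre-computed `mutation_list`,
#' this recomputes the mutations from the gapped sequences and reports
#' every disagreement (a supplied mutation not derivable from the
#' sequences, or a derived mutation absent from the supplied list).
#'
#' @param rearr Rearrangement tibble with a `mutations` list-column.
#' @param ref An [ighv_reference()].
#' @return Tibble of mismatches: `sequence_id`, `nt_pos`, `from_base`,
#'   `to_base`, `status` (`"supplied_only"` / `"derived_only"`).
#' @export
verify_mutation_lists <- function(rearr, ref) {
  derived <- call_mutations(rearr, ref) %>%
    select("sequence_id", "nt_pos", "from_base", "to_base")
  supplied <- rearr %>%
    select("sequence_id", "mutations") %>%
    mutate(mutations = map(.data$mutations,
                           ~ .x %||% tibble(nt_pos = integer(),
                                            from_base = character(),
                                            to_base = character()))) %>%
    tidyr::unnest("mutations")
  sup_only <- dplyr::anti_join(
    supplied, derived, by = c("sequence_id", "nt_pos", "from_base", "to_base"))
  der_only <- dplyr::anti_join(
    derived, supplied, by = c("sequence_id", "nt_pos", "from_base", "to_base"))
  bind_rows(
    mutate(sup_only, status = "supplied_only"),
    mutate(der_only, status = "derived_only")
  )
}

#' Annotate mutations with hotspot, transition and replacement flags
#'
#' Adds to each called mutation: whether it is a transition
#' (A&#8596;G or C&#8596;T) or a transversion; the germline and patient
#' codons and amino acids at the mutated codon; whether the change is a
#' replacement (amino acid changes) or silent; and whether the mutated
#' position falls in an SHM hotspot motif matched on the germline
#' context. Codons not fully covered by bases yield `NA` amino acids
#' and an `NA` replacement flag.
#'
#' @param muts Mutation tibble from [call_mutations()].
#' @param rearr Rearrangement tibble the mutations came from.
#' @param ref An [ighv_reference()].
#' @param motifs Hotspot motif set, by default [shm_hotspot_motifs()].
#' @return `muts` with columns `is_transition`, `sbm_codon`,
#'   `sam_codon`, `sbm_aa`, `sam_aa`, `is_replacement`, `in_hotspot`
#'   appended.
#' @export
annotate_mutations <- function(muts, rearr, ref,
                               motifs = shm_hotspot_motifs()) {
  if (nrow(muts) == 0) {
    return(mutate(muts, is_transition = logical(), sbm_codon = character(),
                  sam_codon = character(), sbm_aa = character(),
                  sam_aa = character(), is_replacement = logical(),
                  in_hotspot = logical()))
  }
  seq_idx <- match(muts$sequence_id, rearr$sequence_id)
  if (anyNA(seq_idx)) {
    abort("annotate_mutations: mutation refers to unknown sequence_id")
  }
  sbm_alleles <- rearr$v_call[seq_idx]
  # per-allele caches: character split and hotspot flags
  uniq_alleles <- unique(sbm_alleles)
  sbm_chars <- setNames(
    map(uniq_alleles, ~ seq_chars(ref$nt_gapped[match(.x, ref$allele)])),
    uniq_alleles)
  hot <- setNames(
    map(uniq_alleles,
        ~ hotspot_flags(ref$nt_gapped[match(.x, ref$allele)], motifs)),
    uniq_alleles)
  sam_chars_all <- map(rearr$sequence_alignment[seq_idx], seq_chars)

  ann <- pmap(
    list(seq_len(nrow(muts)), sbm_alleles, sam_chars_all),
    function(i, sbm_allele, sam_ch) {
      sbm_ch <- sbm_chars[[sbm_allele]]
      cod <- muts$codon_number[i]
      sbm_codon <- codon_at(sbm_ch, cod)
      sam_codon <- codon_at(sam_ch, cod)
      sbm_aa <- translate_codon(sbm_codon)
      sam_aa <- translate_codon(sam_codon)
      tibble(
        is_transition = paste0(muts$from_base[i], muts$to_base[i]) %in%
          c("AG", "GA", "CT", "TC"),
        sbm_codon = sbm_codon %||% NA_character_,
        sam_codon = sam_codon %||% NA_character_,
        sbm_aa = sbm_aa,
        sam_aa = sam_aa,
        is_replacement = if (is.na(sbm_aa) || is.na(sam_aa)) NA
          else sbm_aa != sam_aa,
        in_hotspot = hot[[sbm_allele]][muts$nt_pos[i]]
      )
    }
  ) %>% list_rbind()
  bind_rows_cols <- bind_cols(muts, ann)
  bind_rows_cols
}
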