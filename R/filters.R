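# Data quality filters (exclude unqualified sequences) and subgroup
# selection filters (direct the analysis to a subset/gene/identity
# range/region of interest).

#' IMGT region delimitation table
#'
#' Nucleotide spans of the V-domain regions in the IMGT-gapped frame:
#' FR1 1-78, CDR1 79-114, FR2 115-165, CDR2 166-195, FR3 196-312.
#'
#' @return Tibble with columns `region`, `start`, `end`.
#' @export
imgt_regions <- function() {
  tibble(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
    start = c(1L, 79L, 115L, 166L, 196L),
    end = c(78L, 114L, 165L, 195L, 312L)
  )
}

#' Region of a gapped nucleotide position
#'
#' @param nt_pos Integer vector of 1-based gapped positions.
#' @param regions Delimitation table, by default [imgt_regions()].
#' @return Character vector of region labels (`NA` outside the table).
#' @export
region_of <- function(nt_pos, regions = imgt_regions()) {
  idx <- findInterval(nt_pos, regions$start)
  out <- rep(NA_character_, length(nt_pos))
  ok <- idx >= 1 & nt_pos <= regions$end[pmax(idx, 1L)]
  out[ok] <- regions$region[idx[ok]]
  out
}

region_span <- function(region_restriction, regions = imgt_regions()) {
  if (is.null(region_restriction) || identical(region_restriction, "whole")) {
    return(NULL)
  }
  row <- regions[regions$region == region_restriction, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown region restriction: ", region_restriction))
  }
  c(row$start, row$end)
}

#' Filtering configuration
#'
#' Bundles the data-quality switches and the subgroup-selection
#' criteria applied to integrated rearrangement records.
#'
#' @param require_productive Drop unproductive rearrangements.
#' @param reject_ambiguities Drop sequences containing `N` in the
#'   analysed frame.
#' @param require_complete_cdr1_upstream Drop sequences with missing
#'   coverage anywhere in FR1+CDR1 (gapped positions 1-114) at
#'   positions where the assigned germline itself carries a base.
#' @param subset_whitelist Optional character vector of subset labels
#'   to keep.
#' @param gene_whitelist Optional character vector of IGHV gene names;
#'   the gene is extracted from the assigned allele (`v_call`).
#' @param gi_pct_range Optional `c(low, high)` germline-identity
#'   window, inclusive, in percent.
#' @param region_restriction Optional region (`"FR1"`, `"CDR1"`,
#'   `"FR2"`, `"CDR2"`, `"FR3"`, or `"whole"`) to which downstream
#'   mutation analysis is restricted.
#' @return A `filter_config` list.
#' @export
filter_config <- function(require_productive = TRUE,
                          reject_ambiguities = TRUE,
                          require_complete_cdr1_upstream = TRUE,
                          subset_whitelist = NULL,
                          gene_whitelist = NULL,
                          gi_pct_range = NULL,
                          region_restriction = NULL) {
  if (!is.null(gi_pct_range)) {
    if (length(gi_pct_range) != 2 || any(is.na(gi_pct_range)) ||
        gi_pct_range[1] > gi_pct_range[2] ||
        gi_pct_range[1] < 0 || gi_pct_range[2] > 100) {
      abort("gi_pct_range must be c(low, high) with 0 <= low <= high <= 100")
    }
  }
  if (!is.null(region_restriction)) region_span(region_restriction)
  structure(
    list(
      require_productive = isTRUE(require_productive),
      reject_ambiguities = isTRUE(reject_ambiguities),
      require_complete_cdr1_upstream = isTRUE(require_complete_cdr1_upstream),
      subset_whitelist = subset_whitelist,
      gene_whitelist = gene_whitelist,
      gi_pct_range = gi_pct_range,
      region_restriction = region_restriction
    ),
    class = "filter_config"
  )
}

#' Apply data quality filters
#'
#' Excludes unqualified sequences: unproductive rearrangements,
#' sequences with ambiguities (`N`) in the analysed frame, sequences
#' whose assigned germline allele cannot be resolved in the reference,
#' and sequences with incomplete FR1+CDR1 coverage. Each rejected
#' record is attributed to the first matching reason, in that fixed
#' order, so the tally is deterministic.
#'
#' @param rearr Integrated rearrangement tibble.
#' @param ref An [ighv_reference()] (used to resolve `v_call` and to
#'   tell true germline gaps from missing patient coverage).
#' @param cfg A [filter_config()].
#' @return The kept records, with a `rejections` attribute (named
#'   integer tally; see [filter_report()]).
#' @export
apply_quality_filters <- function(rearr, ref, cfg = filter_config()) {
  reasons <- c("unproductive", "ambiguity", "unresolved_germline",
               "incomplete_cdr1_upstream")
  tally <- setNames(integer(length(reasons)), reasons)
  span <- region_span(cfg$region_restriction)
  L <- frame_length(ref)
  cdr1_end <- min(114L, L)
  reason_of <- function(i) {
    row <- rearr[i, ]
    ch <- seq_chars(row$sequence_alignment)
    if (length(ch) != L) {
      abort(paste0("sequence_alignment length differs from reference frame ",
                   "for ", row$sequence_id))
    }
    if (cfg$require_productive && !row$productive) return("unproductive")
    if (cfg$reject_ambiguities) {
      idx <- if (is.null(span)) seq_len(L) else span[1]:span[2]
      if (any(ch[idx] == "N")) return("ambiguity")
    }
    sbm_row <- match(row$v_call, ref$allele)
    if (is.na(sbm_row)) return("unresolved_germline")
    if (cfg$require_complete_cdr1_upstream) {
      sbm_ch <- seq_chars(ref$nt_gapped[sbm_row])
      idx <- seq_len(cdr1_end)
      if (any(sbm_ch[idx] %in% DNA_BASES & ch[idx] == ".")) {
        return("incomplete_cdr1_upstream")
      }
    }
    NA_character_
  }
  verdict <- vapply(seq_len(nrow(rearr)), reason_of, character(1))
  for (r in reasons) tally[r] <- sum(verdict == r, na.rm = TRUE)
  kept <- rearr[is.na(verdict), , drop = FALSE]
  attr(kept, "rejections") <- tally
  kept
}

#' Rejection tally from the last quality-filter pass
#'
#' @param x The tibble returned by [apply_quality_filters()].
#' @return Named integer vector of rejection counts per reason.
#' @export
filter_report <- function(x) {
  attr(x, "rejections") %||% integer(0)
}

#' Apply subgroup selection filters
#'
#' Restricts quality-filtered records to the configured stereotyped
#' subsets, IGHV genes, and germline-identity range. Criteria that are
#' not configured are no-ops; configured criteria are combined as a
#' conjunction.
#'
#' @param rearr Quality-filtered rearrangement tibble.
#' @param cfg A [filter_config()].
#' @return The selected records.
#' @export
select_subgroup <- function(rearr, cfg = filter_config()) {
  keep <- rep(TRUE, nrow(rearr))
  if (!is.null(cfg$subset_whitelist)) {
    if (!any(rearr$subset %in% cfg$subset_whitelist)) {
      warn(paste0("select_subgroup: no record carries subset label(s) ",
                  paste(cfg$subset_whitelist, collapse = ", ")))
    }
    keep <- keep & !is.na(rearr$subset) &
      rearr$subset %in% cfg$subset_whitelist
  }
  if (!is.null(cfg$gene_whitelist)) {
    keep <- keep & gene_of_allele(rearr$v_call) %in% cfg$gene_whitelist
  }
  if (!is.null(cfg$gi_pct_range)) {
    keep <- keep & rearr$v_identity >= cfg$gi_pct_range[1] &
      rearr$v_identity <= cfg$gi_pct_range[2]
  }
  rearr[keep, , drop = FALSE]
}
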